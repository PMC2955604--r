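#' Hybrid model specification
#'
#' Defines the structure of a hybrid semi-parametric DDE model
#' `dc/dt = K (psi * rho(X, w)) - D(t) c + u(t)` (external-dilution
#' mode) or `dc/dt = K (psi * rho) + b - mu c` (growth-dilution mode,
#' with `mu` a designated component of the kinetic rate vector).
#' `rho` is the three-layer network of [mlp_forward()] fed with the
#' time-lagged input vector defined by a [lag_spec()]; `psi` is the
#' parametric kinetic factor (identically 1 when no mechanistic
#' knowledge is available, in which case the rates reduce to the network
#' outputs exactly).
#'
#' @param state_names character vector of state variable names (length m).
#' @param K stoichiometric matrix, m rows x q columns (q = number of
#'   kinetic rates = network outputs).
#' @param lags a [lag_spec()]; its state entries must reference
#'   `state_names`, its exogenous entries must reference `names(exog)`.
#' @param exog named list of exogenous input signals; each element is a
#'   function `f(t)` or the string `"data"` (signal taken from the
#'   dataset run's exogenous record, linearly interpolated).
#' @param psi parametric factor: `"one"`, `list(type = "state", index =
#'   i)` (every rate multiplied by state `i`, e.g. biomass-specific
#'   rates), or `list(type = "custom", fn = function(c, t), jac =
#'   function(c, t))` with `jac` returning the q x m derivative.
#' @param dilution `list(type = "none")`, `list(type = "constant",
#'   value = d)`, `list(type = "data", column = "D")`, or `list(type =
#'   "growth", mu_index = k, b = <m-vector>)` for the growth-dilution
#'   variant (transport term `b` defaults to zero).
#' @param feed volumetric feed term: `list(type = "none")`,
#'   `list(type = "constant", value = <m-vector>)`, or `list(type =
#'   "dilution_sf", sf = <m-vector>)` giving `u(t) = D(t) * sf`.
#' @param hidden hidden-layer width of the network.
#' @param input_tanh,output_scale passed to [mlp_params()]; by default
#'   no input is tanh-squashed and outputs are unscaled.
#' @param x0 default initial state for simulation (named); dataset runs
#'   carry their own initial conditions.
#' @return an object of class `ddehm_spec`.
#' @export
hybrid_spec <- function(state_names, K, lags, exog = list(),
                        psi = "one",
                        dilution = list(type = "none"),
                        feed = list(type = "none"),
                        hidden = 5L,
                        input_tanh = NULL, output_scale = NULL,
                        x0 = NULL) {
  K <- as.matrix(K)
  m <- length(state_names)
  if (nrow(K) != m) stop("K must have one row per state")
  q <- ncol(K)
  stopifnot(inherits(lags, "lag_spec"))
  layout <- lag_layout(lags, state_names, names(exog))  # validates references
  d_in <- length(layout)
  if (identical(psi, "one")) psi <- list(type = "one")
  if (psi$type == "state" && (psi$index < 1 || psi$index > m))
    stop("psi state index out of range")
  if (dilution$type == "growth") {
    if (is.null(dilution$b)) dilution$b <- rep(0, m)
    if (dilution$mu_index < 1 || dilution$mu_index > q)
      stop("growth-rate index out of range")
  }
  if (feed$type == "dilution_sf" && dilution$type == "none")
    stop("feed type 'dilution_sf' requires a dilution term")
  if (is.null(input_tanh)) input_tanh <- rep(FALSE, d_in)
  if (length(input_tanh) != d_in) stop("input_tanh length must equal input dim")
  structure(list(state_names = state_names, K = K, q = q,
                 lags = lags, exog = exog, psi = psi,
                 dilution = dilution, feed = feed,
                 hidden = as.integer(hidden),
                 input_tanh = input_tanh,
                 output_scale = if (is.null(output_scale)) rep(1, q) else output_scale,
                 x0 = x0),
            class = "ddehm_spec")
}

#' @export
print.ddehm_spec <- function(x, ...) {
  cat("Hybrid DDE model spec\n")
  cat("  states:", paste(x$state_names, collapse = ", "), "\n")
  cat(sprintf("  kinetic rates: %d (ANN %d-%d-%d)\n", x$q,
              lag_input_dim(x$lags), x$hidden, x$q))
  cat("  psi:", x$psi$type, " dilution:", x$dilution$type,
      " feed:", x$feed$type, "\n")
  invisible(x)
}

#' Initialize network parameters matching a model spec
#'
#' @param spec a [hybrid_spec()].
#' @param seed integer seed for [mlp_init()].
#' @return an [mlp_params()] with dimensions, input-tanh flags and
#'   output scales taken from the spec.
#' @export
spec_init_params <- function(spec, seed) {
  mlp_init(seed, lag_input_dim(spec$lags), spec$hidden, spec$q,
           input_tanh = spec$input_tanh, output_scale = spec$output_scale)
}

# --- internal evaluation helpers -------------------------------------------

psi_eval <- function(spec, cvec, t) {
  switch(spec$psi$type,
         one = rep(1, spec$q),
         state = rep(cvec[spec$psi$index], spec$q),
         custom = spec$psi$fn(cvec, t))
}

# q x m Jacobian of psi w.r.t. the instantaneous state.
psi_jac <- function(spec, cvec, t) {
  switch(spec$psi$type,
         one = matrix(0, spec$q, length(cvec)),
         state = {
           J <- matrix(0, spec$q, length(cvec))
           J[, spec$psi$index] <- 1
           J
         },
         custom = spec$psi$jac(cvec, t))
}

# Resolve exogenous signal functions for a dataset run (or free-standing).
make_exog_fns <- function(spec, run = NULL) {
  if (length(spec$exog) == 0) return(list())
  fns <- vector("list", length(spec$exog))
  names(fns) <- names(spec$exog)
  for (nm in names(spec$exog)) {
    e <- spec$exog[[nm]]
    if (is.function(e)) fns[[nm]] <- e
    else if (identical(e, "data")) {
      if (is.null(run) || is.null(run$exog) || !(nm %in% colnames(run$exog)))
        stop("exogenous signal '", nm, "' must be supplied by the dataset run")
      fns[[nm]] <- stats::approxfun(run$time, run$exog[, nm], rule = 2)
    } else stop("invalid exogenous entry '", nm, "'")
  }
  fns
}

# Dilution rate function D(t) (external mode); NULL in growth mode.
make_dilution_fn <- function(spec, run = NULL) {
  d <- spec$dilution
  switch(d$type,
         none = function(t) 0,
         constant = function(t) d$value,
         data = {
           if (is.null(run) || !(d$column %in% colnames(run$exog)))
             stop("dilution column '", d$column, "' missing from run record")
           stats::approxfun(run$time, run$exog[, d$column], rule = 2)
         },
         growth = NULL)
}

make_feed_fn <- function(spec, D_fn) {
  m <- length(spec$state_names)
  f <- spec$feed
  switch(f$type,
         none = function(t) numeric(m),
         constant = function(t) f$value,
         dilution_sf = function(t) D_fn(t) * f$sf)
}

#' Kinetic rate vector of a hybrid model
#'
#' Assembles the lagged input vector `X` from the history, evaluates the
#' network and multiplies by the parametric factor element-wise:
#' `r = psi(c, t) * rho(X, w)`. With `psi == "one"` the rates equal the
#' network outputs.
#'
#' @param t time.
#' @param buf a [history_buffer()] covering the required lags (with
#'   pre-history clamping).
#' @param spec a [hybrid_spec()].
#' @param p an [mlp_params()].
#' @param exog_fns resolved exogenous signal functions (see
#'   [hybrid_rhs()]); defaults to the spec's function-valued entries.
#' @param current optional current state vector (defaults to the buffer
#'   head).
#' @return numeric rate vector of length q.
#' @export
kinetic_rates <- function(t, buf, spec, p, exog_fns = NULL, current = NULL) {
  if (is.null(exog_fns)) exog_fns <- make_exog_fns(spec)
  if (is.null(current)) current <- evaluate_delayed(buf, t, 0)
  X <- assemble_input_vector(buf, exog_fns, t, spec$lags, spec$state_names,
                             current = current)
  psi_eval(spec, current, t) * mlp_forward(p, X)
}

#' Hybrid model right-hand side
#'
#' Evaluates `dc/dt = K r - D(t) c + u(t)` (external mode) or
#' `dc/dt = K r + b - mu c` (growth mode), with
#' `r = psi * rho(X, w)` from [kinetic_rates()].
#'
#' @inheritParams kinetic_rates
#' @param cvec current state vector.
#' @param D_fn,u_fn resolved dilution and feed functions (built by the
#'   integrators via the spec; supply to override).
#' @return numeric derivative vector of length m.
#' @export
hybrid_rhs <- function(t, cvec, buf, spec, p, exog_fns = NULL,
                       D_fn = NULL, u_fn = NULL) {
  if (is.null(exog_fns)) exog_fns <- make_exog_fns(spec)
  if (is.null(D_fn)) D_fn <- make_dilution_fn(spec)
  if (is.null(u_fn)) u_fn <- make_feed_fn(spec, D_fn)
  r <- kinetic_rates(t, buf, spec, p, exog_fns, current = cvec)
  if (spec$dilution$type == "growth") {
    mu <- r[spec$dilution$mu_index]
    drop(spec$K %*% r) + spec$dilution$b - mu * cvec
  } else {
    drop(spec$K %*% r) - D_fn(t) * cvec + u_fn(t)
  }
}
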