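# DDE integration: fixed-step averaged-rate scheme (Heun predictor-
# corrector with stored delayed values) and an embedded Runge-Kutta 2(3)
# pair with cubic Hermite continuous extension. Both serve the hybrid
# model; the fixed-step scheme also carries the forward sensitivity
# augmentation used for training gradients.

# ---- shared helpers --------------------------------------------------------

# Flatten a lag layout into parallel vectors for fast stepping.
layout_arrays <- function(spec) {
  lay <- lag_layout(spec$lags, spec$state_names, names(spec$exog))
  list(type = vapply(lay, function(e) if (e$type == "state") 1L else 2L, 0L),
       index = vapply(lay, function(e) e$index, 0L),
       offset = vapply(lay, function(e) e$offset, 0))
}

solver_context <- function(spec, p, run = NULL, x0 = NULL) {
  if (is.null(x0)) {
    x0 <- if (!is.null(run)) run$x0 else spec$x0
    if (is.null(x0)) stop("no initial state: supply x0 or a dataset run")
  }
  x0 <- as.numeric(x0)
  if (length(x0) != length(spec$state_names)) stop("x0 length mismatch")
  D_fn <- make_dilution_fn(spec, run)
  list(x0 = x0,
       exog_fns = make_exog_fns(spec, run),
       D_fn = D_fn,
       u_fn = make_feed_fn(spec, D_fn),
       lay = layout_arrays(spec),
       growth = spec$dilution$type == "growth")
}

# Generic fixed-step Heun DDE core. rhs(t, x, lookup) with
# lookup(tq) -> state vector (pre-history clamped to x0).
heun_dde_core <- function(rhs, x0, t0, t_end, h, min_offset = Inf) {
  if (h <= 0) stop("step size must be positive")
  if (h > min_offset + 1e-12)
    stop("step size h = ", h, " exceeds the smallest lag offset (", min_offset,
         "); delayed values would not be in the past buffer")
  n_steps <- max(1L, as.integer(ceiling((t_end - t0) / h - 1e-9)))
  h <- (t_end - t0) / n_steps
  m <- length(x0)
  states <- matrix(NA_real_, n_steps + 1L, m)
  states[1L, ] <- x0
  times <- t0 + h * (0:n_steps)
  k_done <- 0L
  lookup <- function(tq) {
    if (tq <= t0) return(x0)
    pos <- (tq - t0) / h
    i <- floor(pos + 1e-9)
    if (i >= k_done) return(states[k_done + 1L, ])
    a <- pos - i
    if (a < 1e-12) states[i + 1L, ]
    else (1 - a) * states[i + 1L, ] + a * states[i + 2L, ]
  }
  for (k in seq_len(n_steps)) {
    tk <- times[k]
    xk <- states[k, ]
    r1 <- rhs(tk, xk, lookup)
    xp <- xk + h * r1
    r2 <- rhs(tk + h, xp, lookup)
    xn <- xk + (h / 2) * (r1 + r2)
    if (!all(is.finite(xn)))
      stop("integration diverged (non-finite state) at t = ", tk + h)
    states[k + 1L, ] <- xn
    k_done <- k
  }
  list(time = times, states = states, h = h)
}

hybrid_rhs_ctx <- function(spec, p, ctx) {
  lay <- ctx$lay
  n_in <- length(lay$type)
  K <- spec$K
  mu_i <- spec$dilution$mu_index
  b <- spec$dilution$b
  function(t, x, lookup) {
    X <- numeric(n_in)
    for (e in seq_len(n_in)) {
      if (lay$type[e] == 1L) {
        X[e] <- if (lay$offset[e] == 0) x[lay$index[e]]
        else lookup(t - lay$offset[e])[lay$index[e]]
      } else {
        f <- ctx$exog_fns[[lay$index[e]]]
        X[e] <- f(max(t - lay$offset[e], ctx$t0_clamp))
      }
    }
    r <- psi_eval(spec, x, t) * mlp_forward(p, X)
    if (ctx$growth) drop(K %*% r) + b - r[mu_i] * x
    else drop(K %*% r) - ctx$D_fn(t) * x + ctx$u_fn(t)
  }
}

# ---- fixed-step integrator -------------------------------------------------

#' Integrate a hybrid DDE model with the fixed-step averaged-rate scheme
#'
#' Advances the model with a Heun predictor-corrector: the kinetic rates
#' are evaluated at both ends of each step and averaged, which realises
#' the averaged-rate refinement of the linear (first-order) approximation.
#' Delayed values are served from the stored solution with linear
#' interpolation; queries before the initial time clamp to the initial
#' state. The step must not exceed the smallest positive lag offset.
#'
#' @param spec a [hybrid_spec()].
#' @param p an [mlp_params()].
#' @param t_out strictly increasing output times; integration runs from
#'   `t_out[1]` to `t_out[length(t_out)]`.
#' @param h step size (same time units as the data; guidance for the
#'   fed-batch case study is 0.05-0.1 h).
#' @param run optional dataset run supplying initial conditions and
#'   data-borne exogenous signals.
#' @param x0 optional initial state (overrides the run's).
#' @param engine `"auto"` uses the compiled fast path when the spec fits
#'   the standard form, `"r"` forces the reference implementation.
#' @return a [ddehm_traj()] sampled at `t_out`.
#' @export
dde_solve_fixed <- function(spec, p, t_out, h, run = NULL, x0 = NULL,
                            engine = c("auto", "r", "cpp")) {
  engine <- match.arg(engine)
  ctx <- solver_context(spec, p, run, x0)
  t0 <- t_out[1]
  ctx$t0_clamp <- t0
  if (t_out[length(t_out)] <= t0) {      # degenerate horizon
    conc <- matrix(ctx$x0, length(t_out), length(ctx$x0), byrow = TRUE)
    colnames(conc) <- spec$state_names
    return(ddehm_traj(t_out, conc))
  }
  off <- ctx$lay$offset
  min_off <- if (any(off > 0)) min(off[off > 0]) else Inf
  use_cpp <- engine != "r" && cpp_eligible(spec)
  if (use_cpp) {
    sol <- cpp_solve(spec, p, ctx, t0, t_out[length(t_out)], h, min_off,
                     want_sens = FALSE)
  } else {
    rhs <- hybrid_rhs_ctx(spec, p, ctx)
    sol <- heun_dde_core(rhs, ctx$x0, t0, t_out[length(t_out)], h, min_off)
  }
  conc <- traj_sample(sol$time, sol$states, t_out)
  colnames(conc) <- spec$state_names
  ddehm_traj(t_out, conc)
}

# ---- fixed-step integrator with forward sensitivities ----------------------

# Shared per-step sensitivity terms. Returns dS/dt (m x n_w) given the
# assembled input vector X, current state x, current sensitivity S and a
# function sens_lookup(tq) -> m x n_w delayed sensitivity (zero before t0).
sens_rhs_terms <- function(spec, p, t, x, X, S, sens_lookup, lay, D, ctx) {
  q <- spec$q
  nw <- ncol(S)
  rho <- mlp_forward(p, X)
  psi <- psi_eval(spec, x, t)
  Jx <- mlp_jac_inputs(p, X)
  Jw <- mlp_jac_weights(p, X)
  acc <- matrix(0, q, nw)
  for (e in seq_along(lay$type)) {
    if (lay$type[e] != 1L) next
    Sd <- if (lay$offset[e] == 0) S else sens_lookup(t - lay$offset[e])
    acc <- acc + Jx[, e] %*% Sd[lay$index[e], , drop = FALSE]
  }
  G <- psi * acc + rho * (psi_jac(spec, x, t) %*% S) + psi * Jw
  if (ctx$growth) {
    mu_i <- spec$dilution$mu_index
    r <- psi * rho
    spec$K %*% G - r[mu_i] * S - x %*% G[mu_i, , drop = FALSE]
  } else {
    spec$K %*% G - D * S
  }
}

#' Integrate a hybrid DDE model together with its sensitivity equations
#'
#' Augments the state with the forward sensitivities `dc/dw` of every
#' state with respect to every network parameter and advances both with
#' the fixed-step averaged-rate scheme. Sensitivities are zero at the
#' initial time (initial states do not depend on the parameters) and
#' delayed sensitivity queries before the initial time clamp to zero.
#'
#' @inheritParams dde_solve_fixed
#' @return list with elements `traj` (a [ddehm_traj()] at `t_out`) and
#'   `sens`, an array `length(t_out) x m x n_w` of sensitivities.
#' @export
dde_solve_sens <- function(spec, p, t_out, h, run = NULL, x0 = NULL,
                           engine = c("auto", "r", "cpp")) {
  engine <- match.arg(engine)
  ctx <- solver_context(spec, p, run, x0)
  t0 <- t_out[1]
  ctx$t0_clamp <- t0
  lay <- ctx$lay
  off <- lay$offset
  min_off <- if (any(off > 0)) min(off[off > 0]) else Inf
  m <- length(ctx$x0)
  nw <- n_weights(p)
  if (t_out[length(t_out)] <= t0) {      # degenerate horizon
    conc <- matrix(ctx$x0, length(t_out), m, byrow = TRUE)
    colnames(conc) <- spec$state_names
    return(list(traj = ddehm_traj(t_out, conc),
                sens = array(0, dim = c(length(t_out), m, nw))))
  }
  if (engine != "r" && cpp_eligible(spec)) {
    sol <- cpp_solve(spec, p, ctx, t0, t_out[length(t_out)], h, min_off,
                     want_sens = TRUE)
    times <- sol$time; states <- sol$states; Sflat <- sol$sens
  } else {
    sol <- heun_sens_core(spec, p, ctx, t0, t_out[length(t_out)], h, min_off)
    times <- sol$time; states <- sol$states; Sflat <- sol$sens
  }
  conc <- traj_sample(times, states, t_out)
  colnames(conc) <- spec$state_names
  Ss <- traj_sample(times, Sflat, t_out)
  sens <- array(Ss, dim = c(length(t_out), m, nw))
  list(traj = ddehm_traj(t_out, conc), sens = sens)
}

heun_sens_core <- function(spec, p, ctx, t0, t_end, h, min_off) {
  if (h > min_off + 1e-12) stop("step size exceeds the smallest lag offset")
  n_steps <- max(1L, as.integer(ceiling((t_end - t0) / h - 1e-9)))
  h <- (t_end - t0) / n_steps
  m <- length(ctx$x0)
  nw <- n_weights(p)
  lay <- ctx$lay
  n_in <- length(lay$type)
  states <- matrix(NA_real_, n_steps + 1L, m)
  states[1L, ] <- ctx$x0
  Sflat <- matrix(0, n_steps + 1L, m * nw)
  times <- t0 + h * (0:n_steps)
  k_done <- 0L
  zeroS <- matrix(0, m, nw)
  lookup <- function(tq) {
    if (tq <= t0) return(ctx$x0)
    pos <- (tq - t0) / h
    i <- floor(pos + 1e-9)
    if (i >= k_done) return(states[k_done + 1L, ])
    a <- pos - i
    if (a < 1e-12) states[i + 1L, ]
    else (1 - a) * states[i + 1L, ] + a * states[i + 2L, ]
  }
  sens_lookup <- function(tq) {
    if (tq <= t0) return(zeroS)
    pos <- (tq - t0) / h
    i <- floor(pos + 1e-9)
    v <- if (i >= k_done) Sflat[k_done + 1L, ]
    else {
      a <- pos - i
      if (a < 1e-12) Sflat[i + 1L, ]
      else (1 - a) * Sflat[i + 1L, ] + a * Sflat[i + 2L, ]
    }
    matrix(v, m, nw)
  }
  eval_both <- function(t, x, S) {
    X <- numeric(n_in)
    for (e in seq_len(n_in)) {
      if (lay$type[e] == 1L) {
        X[e] <- if (lay$offset[e] == 0) x[lay$index[e]]
        else lookup(t - lay$offset[e])[lay$index[e]]
      } else {
        f <- ctx$exog_fns[[lay$index[e]]]
        X[e] <- f(max(t - lay$offset[e], t0))
      }
    }
    D <- if (ctx$growth) 0 else ctx$D_fn(t)
    r <- psi_eval(spec, x, t) * mlp_forward(p, X)
    dx <- if (ctx$growth) drop(spec$K %*% r) + spec$dilution$b -
      r[spec$dilution$mu_index] * x
    else drop(spec$K %*% r) - D * x + ctx$u_fn(t)
    dS <- sens_rhs_terms(spec, p, t, x, X, S, sens_lookup, lay, D, ctx)
    list(dx = dx, dS = dS)
  }
  for (k in seq_len(n_steps)) {
    tk <- times[k]
    xk <- states[k, ]
    Sk <- matrix(Sflat[k, ], m, nw)
    e1 <- eval_both(tk, xk, Sk)
    xp <- xk + h * e1$dx
    Sp <- Sk + h * e1$dS
    e2 <- eval_both(tk + h, xp, Sp)
    xn <- xk + (h / 2) * (e1$dx + e2$dx)
    Sn <- Sk + (h / 2) * (e1$dS + e2$dS)
    if (!all(is.finite(xn)))
      stop("integration diverged (non-finite state) at t = ", tk + h)
    states[k + 1L, ] <- xn
    Sflat[k + 1L, ] <- as.numeric(Sn)
    k_done <- k
  }
  list(time = times, states = states, sens = Sflat)
}

# ---- adaptive embedded RK2(3) integrator -----------------------------------

#' Integrate a hybrid DDE model with an adaptive Runge-Kutta 2(3) pair
#'
#' Embedded Bogacki-Shampine 2(3) pair with a cubic Hermite continuous
#' extension; delayed values are evaluated on the continuous extension.
#' The step size never exceeds the smallest positive lag offset, and the
#' mesh is forced onto the derivative-discontinuity points `t0 + k*tau`
#' propagated by constant pre-history (method-of-steps handling).
#'
#' @inheritParams dde_solve_fixed
#' @param rel_tol,abs_tol positive local error tolerances.
#' @return a [ddehm_traj()] sampled at `t_out`.
#' @export
dde_solve_adaptive <- function(spec, p, t_out, rel_tol = 1e-6, abs_tol = 1e-8,
                               run = NULL, x0 = NULL) {
  stopifnot(rel_tol > 0, abs_tol > 0)
  ctx <- solver_context(spec, p, run, x0)
  t0 <- t_out[1]
  ctx$t0_clamp <- t0
  rhs <- hybrid_rhs_ctx(spec, p, ctx)
  off <- ctx$lay$offset
  sol <- rk23_dde_core(rhs, ctx$x0, t0, t_out[length(t_out)],
                       rel_tol, abs_tol, off[off > 0])
  conc <- sol$dense(t_out)
  colnames(conc) <- spec$state_names
  out <- ddehm_traj(t_out, conc)
  attr(out, "mesh") <- sol$time   # accepted solver mesh (diagnostics)
  out
}

# Generic adaptive core: rhs(t, x, lookup); offsets drive the step cap
# and the discontinuity mesh. Returns a dense evaluator.
rk23_dde_core <- function(rhs, x0, t0, t_end, rel_tol, abs_tol,
                          offsets = numeric()) {
  m <- length(x0)
  cap <- 4096L
  ts <- numeric(cap); ys <- matrix(NA_real_, cap, m); fs <- matrix(NA_real_, cap, m)
  n <- 1L
  ts[1L] <- t0; ys[1L, ] <- x0
  min_off <- if (length(offsets)) min(offsets) else Inf
  disc <- sort(unique(as.numeric(outer(offsets, 1:3))))
  disc <- t0 + disc[disc > 0 & t0 + disc < t_end - 1e-12]
  lookup <- function(tq) {
    if (tq <= t0) return(x0)
    if (tq >= ts[n]) return(ys[n, ])
    i <- findInterval(tq, ts[seq_len(n)])
    hermite_eval(ts[i], ts[i + 1L], ys[i, ], ys[i + 1L, ], fs[i, ], fs[i + 1L, ], tq)
  }
  f1 <- rhs(t0, x0, lookup)
  fs[1L, ] <- f1
  h <- min(min_off, (t_end - t0) / 10, 1e-2 * (t_end - t0) + 1e-8)
  t <- t0; y <- x0
  while (t < t_end - 1e-12 * max(1, abs(t_end))) {
    h <- min(h, min_off, t_end - t)
    nxt <- disc[disc > t + 1e-12]
    if (length(nxt) && t + h > nxt[1] - 1e-12) h <- nxt[1] - t
    if (h < 1e-12 * max(1, abs(t)))
      stop("step size underflow (stiffness) at t = ", t)
    k1 <- f1
    k2 <- rhs(t + h / 2, y + (h / 2) * k1, lookup)
    k3 <- rhs(t + 3 * h / 4, y + (3 * h / 4) * k2, lookup)
    y1 <- y + h * (2 * k1 + 3 * k2 + 4 * k3) / 9
    k4 <- rhs(t + h, y1, lookup)
    errv <- h * (-5 * k1 / 72 + k2 / 12 + k3 / 9 - k4 / 8)
    sc <- abs_tol + rel_tol * pmax(abs(y), abs(y1))
    err <- sqrt(mean((errv / sc)^2))
    if (!is.finite(err)) err <- 2
    if (err <= 1) {
      t <- t + h; y <- y1; f1 <- k4
      if (n == nrow(ys)) {
        ts <- c(ts, numeric(n)); ys <- rbind(ys, ys * NA); fs <- rbind(fs, fs * NA)
      }
      n <- n + 1L
      ts[n] <- t; ys[n, ] <- y; fs[n, ] <- f1
      if (!all(is.finite(y)))
        stop("integration diverged (non-finite state) at t = ", t)
    }
    fac <- if (err > 0) 0.9 * err^(-1 / 3) else 5
    h <- h * min(5, max(0.2, fac))
  }
  ts <- ts[seq_len(n)]; ys <- ys[seq_len(n), , drop = FALSE]
  fs <- fs[seq_len(n), , drop = FALSE]
  dense <- function(t_q) {
    out <- matrix(NA_real_, length(t_q), m)
    for (ii in seq_along(t_q)) {
      tq <- t_q[ii]
      if (tq <= t0) { out[ii, ] <- x0; next }
      if (tq >= ts[n]) { out[ii, ] <- ys[n, ]; next }
      i <- findInterval(tq, ts)
      out[ii, ] <- hermite_eval(ts[i], ts[i + 1L], ys[i, ], ys[i + 1L, ],
                                fs[i, ], fs[i + 1L, ], tq)
    }
    out
  }
  list(time = ts, states = ys, derivs = fs, dense = dense)
}

hermite_eval <- function(ta, tb, ya, yb, fa, fb, tq) {
  hseg <- tb - ta
  s <- (tq - ta) / hseg
  h00 <- (1 + 2 * s) * (1 - s)^2
  h10 <- s * (1 - s)^2
  h01 <- s^2 * (3 - 2 * s)
  h11 <- s^2 * (s - 1)
  h00 * ya + h10 * hseg * fa + h01 * yb + h11 * hseg * fb
}
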