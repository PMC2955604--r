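# Parameter identification: weighted least squares with analytic
# gradients from the forward sensitivity solve, Levenberg-Marquardt
# steps, validation-tracked early stopping and random multistarts,
# plus the MSE/BIC performance criteria.

# Predicted state matrices at every run's measurement times.
eval_runs <- function(spec, p, dataset, h, engine = "auto") {
  lapply(dataset$runs, function(r)
    dde_solve_fixed(spec, p, r$time, h, run = r, engine = engine)$conc)
}

# Residual-only evaluation of the weighted objective; +Inf on
# integration divergence (the step is rejected, not fatal).
eval_objective <- function(spec, p, dataset, h, weight_mode = "sd",
                           engine = "auto") {
  pw <- if (weight_mode == "sd") 1 else 2
  d <- dataset_dims(dataset)
  tryCatch({
    preds <- eval_runs(spec, p, dataset, h, engine)
    E <- 0
    for (k in seq_along(dataset$runs)) {
      r <- dataset$runs[[k]]
      E <- E + sum(sweep((r$conc - preds[[k]])^2, 2, r$sigma^pw, "/"))
    }
    E / (d["P"] * d["n"])
  }, error = function(e) Inf)
}

#' Weighted least-squares objective
#'
#' `E = 1/(P n) sum_l sum_i (c_m - c)^2 / c_sigma_i`, summed over all
#' samples of all runs; `P` is the total sample count and `n` the state
#' count. The printed weighting divides by the standard deviation;
#' `weight_mode = "var"` switches to variance weighting.
#'
#' @param spec a [hybrid_spec()].
#' @param p an [mlp_params()].
#' @param dataset a [ddehm_dataset()].
#' @param h fixed integration step (defaults to a tenth of the smallest
#'   sampling interval).
#' @param weight_mode `"sd"` (default) or `"var"`.
#' @return objective value E (+Inf if the integration diverges).
#' @export
objective_e <- function(spec, p, dataset, h = NULL,
                        weight_mode = c("sd", "var")) {
  if (is.null(h)) h <- default_step(dataset)
  unname(eval_objective(spec, p, dataset, h, match.arg(weight_mode)))
}

#' Mean squared error of a hybrid model on a dataset
#'
#' Unweighted mean squared residual `MSE = 1/(P n) sum sum (c_m - c)^2`
#' over all samples; invariant to the measurement standard deviations.
#'
#' @inheritParams objective_e
#' @return MSE value.
#' @export
model_mse <- function(spec, p, dataset, h = NULL) {
  if (is.null(h)) h <- default_step(dataset)
  d <- dataset_dims(dataset)
  preds <- eval_runs(spec, p, dataset, h)
  sse <- 0
  for (k in seq_along(dataset$runs))
    sse <- sse + sum((dataset$runs[[k]]$conc - preds[[k]])^2)
  unname(sse / (d["P"] * d["n"]))
}

# BIC from a sum of squared (unweighted) residuals.
bic_from_sse <- function(sse, n, P, n_w) {
  sse <- max(sse, 1e-300)  # SSE -> 0 guard: finite, very large BIC
  unname(-(n * P / 2) * log(sse) - (n_w / 2) * log(n * P / (2 * pi)))
}

#' Bayesian information criterion of a hybrid model on a dataset
#'
#' `BIC = -(n P / 2) ln(SSE) - (n_w / 2) ln(n P / (2 pi))` with `SSE`
#' the sum of squared residuals over the dataset and `n_w` the total
#' parameter count; larger is better, and model selection maximises the
#' validation-set BIC.
#'
#' @inheritParams objective_e
#' @param n_w parameter count; defaults to [n_weights()] of `p`.
#' @return BIC value.
#' @export
model_bic <- function(spec, p, dataset, h = NULL, n_w = NULL) {
  if (is.null(h)) h <- default_step(dataset)
  if (is.null(n_w)) n_w <- n_weights(p)
  d <- dataset_dims(dataset)
  mse <- model_mse(spec, p, dataset, h)
  bic_from_sse(mse * d["P"] * d["n"], d["n"], d["P"], n_w)
}

default_step <- function(dataset) {
  min(vapply(dataset$runs, function(r) min(diff(r$time)), 0)) / 10
}

#' Training control options
#'
#' @param h fixed integration step for training solves (default: a
#'   tenth of the smallest data sampling interval).
#' @param maxit maximum number of accepted Levenberg-Marquardt
#'   iterations.
#' @param criterion validation early-stopping / selection criterion:
#'   `"bic"` (maximised, default) or `"mse"` (minimised).
#' @param weight_mode objective weighting, see [objective_e()].
#' @param lambda0 initial LM damping.
#' @param max_step largest accepted parameter step (Euclidean norm);
#'   steps beyond it raise the damping instead. Guards against early
#'   Gauss-Newton overshoot that saturates the hidden layer.
#' @param ftol relative objective improvement below which progress
#'   counts as stalled.
#' @param stall number of consecutive stalled accepted steps that stops
#'   the iteration.
#' @param patience accepted steps without a new best validation value
#'   before the iteration stops (the returned parameters are the best
#'   validation iterate regardless).
#' @param max_reject maximum consecutive rejected steps.
#' @param engine integration engine (see [dde_solve_fixed()]).
#' @return list of class `ddehm_control`.
#' @export
ddehm_control <- function(h = NULL, maxit = 60L, criterion = c("bic", "mse"),
                          weight_mode = c("sd", "var"), lambda0 = 1,
                          max_step = 3, ftol = 1e-9, stall = 10L,
                          patience = 30L, max_reject = 15L, engine = "auto") {
  structure(list(h = h, maxit = as.integer(maxit),
                 criterion = match.arg(criterion),
                 weight_mode = match.arg(weight_mode),
                 lambda0 = lambda0, max_step = max_step,
                 ftol = ftol, stall = as.integer(stall),
                 patience = as.integer(patience),
                 max_reject = as.integer(max_reject), engine = engine),
            class = "ddehm_control")
}

valid_score <- function(spec, p, valid, h, criterion, weight_mode) {
  if (criterion == "bic") {
    v <- tryCatch(model_bic(spec, p, valid, h), error = function(e) -Inf)
    if (!is.finite(v)) v <- -Inf
    v                       # maximised
  } else {
    v <- tryCatch(model_mse(spec, p, valid, h), error = function(e) Inf)
    -v                      # negated MSE, so "larger is better" uniformly
  }
}

#' Fit a hybrid model once from a seeded random initialization
#'
#' Levenberg-Marquardt minimisation of the weighted least-squares
#' objective on the training runs, with the residual Jacobian supplied
#' analytically by the forward sensitivity solve (never by finite
#' differences). After every accepted step the validation criterion is
#' evaluated; the returned parameters are the ones with the best
#' validation value (early stopping), not the final iterate. Steps that
#' make the integration diverge are treated as infinite objective and
#' rejected.
#'
#' @param spec a [hybrid_spec()].
#' @param train,valid training and validation [ddehm_dataset()]s
#'   (disjoint).
#' @param seed integer seed for the weight initialization.
#' @param control a [ddehm_control()].
#' @return list of class `ddehm_fit` with elements `params` (best
#'   validation iterate), `final_params`, `seed`, `best_iter`,
#'   `n_iter`, `E_train`, `valid_score`, `history` (per-iteration
#'   train E and validation criterion), `converged`.
#' @export
fit_once <- function(spec, train, valid, seed, control = ddehm_control()) {
  h <- control$h
  if (is.null(h)) h <- default_step(train)
  p <- spec_init_params(spec, seed)
  w <- flatten_params(p)
  nw <- length(w)
  rj <- tryCatch(residuals_and_jacobian(spec, p, train, h,
                                        control$weight_mode, control$engine),
                 error = function(e) NULL)
  if (is.null(rj) || !all(is.finite(rj$residuals)))
    stop("initial integration failed for seed ", seed)
  E <- rj$E
  lambda <- control$lambda0
  vs <- valid_score(spec, p, valid, h, control$criterion, control$weight_mode)
  best <- list(w = w, score = vs, iter = 0L)
  hist <- list(data.frame(iter = 0L, E_train = E, valid = vs,
                          lambda = lambda, accepted = TRUE))
  n_acc <- 0L
  stalled <- 0L
  converged <- FALSE
  while (n_acc < control$maxit) {
    JtJ <- crossprod(rj$jacobian)
    Jtr <- crossprod(rj$jacobian, rj$residuals)
    dd <- pmax(diag(JtJ), 1e-12)
    rejected <- 0L
    repeat {
      step <- tryCatch(
        solve(JtJ + lambda * diag(dd, nw), -Jtr),
        error = function(e) NULL)
      if (!is.null(step) && sqrt(sum(step^2)) > control$max_step)
        step <- NULL                      # overshoot guard: raise damping
      E_new <- Inf
      if (!is.null(step)) {
        w_new <- w + drop(step)
        p_new <- unflatten_params(p, w_new)
        E_new <- eval_objective(spec, p_new, train, h, control$weight_mode,
                                control$engine)
      }
      if (is.finite(E_new) && E_new < E) {
        rel <- (E - E_new) / max(E, 1e-300)
        w <- w_new; p <- p_new; E <- E_new
        lambda <- max(lambda / 3, 1e-12)
        n_acc <- n_acc + 1L
        vs <- valid_score(spec, p, valid, h, control$criterion,
                          control$weight_mode)
        if (vs > best$score) best <- list(w = w, score = vs, iter = n_acc)
        hist[[length(hist) + 1L]] <- data.frame(
          iter = n_acc, E_train = E, valid = vs, lambda = lambda,
          accepted = TRUE)
        stalled <- if (rel < control$ftol) stalled + 1L else 0L
        break
      }
      lambda <- lambda * 4
      rejected <- rejected + 1L
      if (rejected >= control$max_reject) { converged <- TRUE; break }
    }
    if (converged || stalled >= control$stall ||
        n_acc - best$iter >= control$patience) { converged <- TRUE; break }
    rj <- tryCatch(residuals_and_jacobian(spec, p, train, h,
                                          control$weight_mode, control$engine),
                   error = function(e) NULL)
    if (is.null(rj) || !all(is.finite(rj$residuals))) break
  }
  structure(list(params = unflatten_params(p, best$w),
                 final_params = p,
                 seed = seed, best_iter = best$iter, n_iter = n_acc,
                 E_train = E, valid_score = best$score,
                 history = do.call(rbind, hist), converged = converged,
                 h = h),
            class = "ddehm_fit")
}

#' Fit a hybrid model with random multistarts
#'
#' Runs [fit_once()] from `restarts` random initializations whose seeds
#' are derived from `seed` through a named substream, and returns the
#' restart with the best validation criterion (ties broken by the lower
#' restart index). The outcome is independent of execution order.
#'
#' @inheritParams fit_once
#' @param restarts number of random initializations (>= 1).
#' @param seed master seed.
#' @return list of class `ddehm_multistart`: `best` (a `ddehm_fit`),
#'   `restart_log` (data frame), `seed`.
#' @export
fit_multistart <- function(spec, train, valid, restarts = 5, seed = 1,
                           control = ddehm_control()) {
  stopifnot(restarts >= 1)
  fits <- vector("list", restarts)
  for (k in seq_len(restarts)) {
    sk <- derive_seed(seed, "restart", k)
    fits[[k]] <- tryCatch(fit_once(spec, train, valid, sk, control),
                          error = function(e) e)
  }
  ok <- !vapply(fits, inherits, TRUE, "error")
  if (!any(ok)) stop("all restarts failed: ",
                     conditionMessage(fits[[1]]))
  scores <- vapply(fits, function(f)
    if (inherits(f, "error")) -Inf else f$valid_score, 0)
  best_k <- which.max(scores)          # which.max takes the first maximum
  log <- data.frame(
    restart = seq_len(restarts),
    seed = vapply(seq_len(restarts), function(k) derive_seed(seed, "restart", k), 0L),
    ok = ok,
    valid_score = scores,
    E_train = vapply(fits, function(f)
      if (inherits(f, "error")) NA_real_ else f$E_train, 0),
    best_iter = vapply(fits, function(f)
      if (inherits(f, "error")) NA_integer_ else f$best_iter, 0L))
  structure(list(best = fits[[best_k]], best_restart = best_k,
                 restart_log = log, seed = seed),
            class = "ddehm_multistart")
}
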