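# Forward sensitivity equations for the hybrid DDE and their mapping to
# objective gradients. The sensitivity state is dc/dw (m states x n_w
# parameters); its dynamics collect (i) the chain-rule flow of the
# network and parametric factor through every (instantaneous and
# delayed) state entry of the input vector, (ii) the direct derivative
# of the rates w.r.t. the parameters, and (iii) the dilution coupling.

#' Right-hand side of the sensitivity equations
#'
#' Evaluates `d/dt (dc/dw)` for a hybrid model at one time point, given
#' lookup functions for delayed states and delayed sensitivities.
#' Delayed sensitivity queries before the initial time must return zero
#' (pre-history states are parameter-independent); `sens_lookup` built
#' by the integrators enforces this clamping.
#'
#' @param t time.
#' @param cvec current state vector (length m).
#' @param sens current sensitivity matrix (m x n_w).
#' @param state_lookup function `f(tq)` returning the (clamped) state
#'   vector at a past time.
#' @param sens_lookup function `f(tq)` returning the (zero-clamped)
#'   sensitivity matrix at a past time.
#' @param spec a [hybrid_spec()].
#' @param p an [mlp_params()].
#' @param run optional dataset run for data-borne exogenous signals.
#' @param t0 initial time used for exogenous clamping (defaults to
#'   `-Inf`, i.e. no clamping).
#' @return matrix m x n_w with the sensitivity time derivative.
#' @export
sensitivity_rhs <- function(t, cvec, sens, state_lookup, sens_lookup,
                            spec, p, run = NULL, t0 = -Inf) {
  ctx <- solver_context(spec, p, run, x0 = cvec)
  ctx$t0_clamp <- t0
  lay <- ctx$lay
  X <- numeric(length(lay$type))
  for (e in seq_along(lay$type)) {
    if (lay$type[e] == 1L) {
      X[e] <- if (lay$offset[e] == 0) cvec[lay$index[e]]
      else state_lookup(t - lay$offset[e])[lay$index[e]]
    } else {
      f <- ctx$exog_fns[[lay$index[e]]]
      X[e] <- f(max(t - lay$offset[e], t0))
    }
  }
  D <- if (ctx$growth) 0 else ctx$D_fn(t)
  sens_rhs_terms(spec, p, t, cvec, X, sens, sens_lookup, lay, D, ctx)
}

# Residuals, analytic Jacobian and gradient of the weighted
# least-squares objective for one or more dataset runs. Residual
# rho_{l,i} = (c_m - c) / sqrt(c_sigma_i^pow * P * n) so that
# sum(res^2) = E; the Jacobian row is -dc/dw with the same scaling.
residuals_and_jacobian <- function(spec, p, dataset, h,
                                   weight_mode = c("sd", "var"),
                                   engine = "auto") {
  weight_mode <- match.arg(weight_mode)
  pw <- if (weight_mode == "sd") 1 else 2
  runs <- dataset$runs
  m <- length(spec$state_names)
  P <- sum(vapply(runs, function(r) length(r$time), 0))
  nw <- n_weights(p)
  res <- numeric(0)
  J <- matrix(0, 0, nw)
  for (r in runs) {
    sol <- dde_solve_sens(spec, p, r$time, h, run = r, engine = engine)
    wts <- 1 / sqrt(r$sigma^pw * P * m)      # per-state scaling
    for (i in seq_len(m)) {
      res <- c(res, (r$conc[, i] - sol$traj$conc[, i]) * wts[i])
      J <- rbind(J, -sol$sens[, i, ] * wts[i])
    }
  }
  list(residuals = res, jacobian = J, E = sum(res^2))
}

#' Objective gradient from the sensitivity solve
#'
#' Integrates the model and its forward sensitivities over every run of
#' a dataset, forms the weighted residual vector and per-residual
#' Jacobian, and returns the analytic gradient `2 J' res` of the
#' weighted least-squares objective.
#'
#' @param spec a [hybrid_spec()].
#' @param p an [mlp_params()].
#' @param dataset a [ddehm_dataset()].
#' @param h fixed integration step.
#' @param weight_mode `"sd"` divides squared residuals by the standard
#'   deviation (the default weighting), `"var"` by the variance.
#' @return list with `residuals`, `jacobian` (one row per residual),
#'   `gradient` (length n_w) and the objective value `E`.
#' @export
objective_gradient <- function(spec, p, dataset, h,
                               weight_mode = c("sd", "var")) {
  rj <- residuals_and_jacobian(spec, p, dataset, h, match.arg(weight_mode))
  rj$gradient <- drop(2 * crossprod(rj$jacobian, rj$residuals))
  rj
}
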