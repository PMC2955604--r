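#' Fit a hybrid delay differential equation model
#'
#' Main fitting interface. Identifies the network parameters of a
#' hybrid model specification from time-series data by weighted least
#' squares with analytic sensitivity-equation gradients, random
#' multistarts and validation-based early stopping.
#'
#' `data` may be a list with `train` and `valid` datasets, or a single
#' [ddehm_dataset()], in which case whole runs are assigned so that
#' training receives about two thirds of the data points
#' ([split_dataset()]).
#'
#' @param spec a [hybrid_spec()] (e.g. [tfa_spec()], [pichia_spec()]).
#' @param data training data; see Details.
#' @param restarts number of random initializations.
#' @param seed master seed (all restart seeds derive from it).
#' @param control a [ddehm_control()].
#' @return an object of class `ddehm` with components `spec`, `params`
#'   (fitted [mlp_params()]), `fit` (best restart), `multistart`
#'   (restart log), `train`, `valid`, `criteria` (E/MSE/BIC per split)
#'   and `control`. Supports `print`, `summary`, `coef`, `predict`,
#'   `residuals`, `plot` and `simulate`.
#' @seealso [ddehm_grid()] for structure selection over hidden nodes
#'   and delay sets.
#' @examples
#' \donttest{
#' study <- make_case_study("tfa", master_seed = 1)
#' spec <- tfa_spec("1C", hidden = 5, lags = 120)
#' fit <- ddehm(spec, list(train = study$train, valid = study$valid),
#'              restarts = 2, seed = 1)
#' print(fit)
#' model_mse(spec, fit$params, study$test)
#' }
#' @export
ddehm <- function(spec, data, restarts = 5, seed = 1,
                  control = ddehm_control()) {
  if (inherits(data, "ddehm_dataset")) data <- split_dataset(data)
  train <- data$train; valid <- data$valid
  if (is.null(train) || is.null(valid))
    stop("data must provide train and valid datasets")
  ms <- fit_multistart(spec, train, valid, restarts, seed, control)
  p <- ms$best$params
  h <- ms$best$h
  crit <- function(ds) c(E = objective_e(spec, p, ds, h, control$weight_mode),
                         MSE = model_mse(spec, p, ds, h),
                         BIC = model_bic(spec, p, ds, h))
  structure(list(spec = spec, params = p, fit = ms$best,
                 multistart = ms$restart_log, best_restart = ms$best_restart,
                 train = train, valid = valid,
                 criteria = list(train = crit(train), valid = crit(valid)),
                 control = control, seed = seed, h = h),
            class = "ddehm")
}

#' Evaluate a fitted model on a further dataset
#'
#' @param object a fitted [ddehm()] model.
#' @param dataset a [ddehm_dataset()] (e.g. the test split).
#' @return named vector with E, MSE and BIC on the dataset.
#' @export
evaluate_fit <- function(object, dataset) {
  stopifnot(inherits(object, "ddehm"))
  c(E = objective_e(object$spec, object$params, dataset, object$h,
                    object$control$weight_mode),
    MSE = model_mse(object$spec, object$params, dataset, object$h),
    BIC = model_bic(object$spec, object$params, dataset, object$h))
}

#' @export
print.ddehm <- function(x, ...) {
  sp <- x$spec
  cat("Hybrid DDE model fit\n")
  cat(sprintf("  ANN %d-%d-%d (%d parameters), %d restart(s), seed %d\n",
              lag_input_dim(sp$lags), sp$hidden, sp$q,
              n_weights(x$params), nrow(x$multistart), x$seed))
  cat(sprintf("  best restart %d, early stop at iteration %d of %d\n",
              x$best_restart, x$fit$best_iter, x$fit$n_iter))
  for (s in names(x$criteria))
    cat(sprintf("  %-5s E = %.5g  MSE = %.5g  BIC = %.1f\n", s,
                x$criteria[[s]]["E"], x$criteria[[s]]["MSE"],
                x$criteria[[s]]["BIC"]))
  invisible(x)
}

#' @export
summary.ddehm <- function(object, ...) {
  print(object)
  cat("\nRestart log:\n")
  print(object$multistart, row.names = FALSE)
  invisible(object)
}

#' @export
coef.ddehm <- function(object, ...) flatten_params(object$params)

#' Predict trajectories of a fitted hybrid model
#'
#' Integrates the fitted model from each run's initial conditions and
#' exogenous records and samples the solution at the run's measurement
#' times (or at `times` if given).
#'
#' @param object a fitted [ddehm()] model.
#' @param newdata a [ddehm_dataset()]; defaults to the training data.
#' @param times optional common output time grid.
#' @param ... unused.
#' @return list of [ddehm_traj()], one per run.
#' @export
predict.ddehm <- function(object, newdata = NULL, times = NULL, ...) {
  if (is.null(newdata)) newdata <- object$train
  lapply(newdata$runs, function(r) {
    t_out <- if (is.null(times)) r$time else times
    dde_solve_fixed(object$spec, object$params, t_out, object$h, run = r,
                    engine = object$control$engine)
  })
}

#' @export
residuals.ddehm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$train
  preds <- predict(object, newdata)
  lapply(seq_along(newdata$runs), function(k)
    newdata$runs[[k]]$conc - preds[[k]]$conc)
}

#' @export
plot.ddehm <- function(x, newdata = NULL, which = 1L, ...) {
  if (is.null(newdata)) newdata <- x$train
  preds <- predict(x, newdata)
  m <- length(x$spec$state_names)
  old <- graphics::par(mfrow = c(m, 1), mar = c(3.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  for (i in seq_len(m)) {
    ylim <- range(unlist(lapply(seq_along(newdata$runs), function(k)
      c(newdata$runs[[k]]$conc[, i], preds[[k]]$conc[, i]))))
    first <- TRUE
    for (k in seq_along(newdata$runs)) {
      r <- newdata$runs[[k]]
      if (first) {
        graphics::plot(r$time, r$conc[, i], col = "grey40", pch = 1,
                       cex = 0.5, ylim = ylim, xlab = "time",
                       ylab = x$spec$state_names[i], ...)
        first <- FALSE
      } else graphics::points(r$time, r$conc[, i], col = "grey40",
                              pch = 1, cex = 0.5)
      graphics::lines(preds[[k]]$time, preds[[k]]$conc[, i], col = k + 1)
    }
  }
  invisible(x)
}

#' Simulate noisy replicates from a fitted hybrid model
#'
#' Integrates the fitted model over each run of `newdata` and corrupts
#' the predictions with Gaussian noise at the run's recorded standard
#' deviations, giving parametric-bootstrap style replicate datasets.
#'
#' @param object a fitted [ddehm()] model.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param newdata a [ddehm_dataset()]; defaults to the training data.
#' @param ... unused.
#' @return list of `nsim` [ddehm_dataset()]s.
#' @export
simulate.ddehm <- function(object, nsim = 1, seed = 1, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$train
  preds <- predict(object, newdata)
  lapply(seq_len(nsim), function(s) {
    runs <- lapply(seq_along(newdata$runs), function(k) {
      r <- newdata$runs[[k]]
      with_seed(derive_seed(seed, "simulate", s * 1000L + k), {
        noisy <- preds[[k]]$conc +
          matrix(stats::rnorm(length(r$conc)), nrow(r$conc)) *
          rep(r$sigma, each = nrow(r$conc))
        ddehm_run(r$time, noisy, sigma = r$sigma, exog = r$exog,
                  x0 = r$x0, role = r$role)
      })
    })
    ddehm_dataset(runs, newdata$state_names, newdata$exog_names)
  })
}
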