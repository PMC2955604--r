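#' Trajectory container
#'
#' Solution of a (delay) differential system on a time grid: times,
#' state matrix and optionally the kinetic-rate matrix and assembled
#' network input vectors for diagnostics. Times are strictly
#' increasing, the first row equals the initial state, and all values
#' are finite (integrators raise a divergence error rather than
#' propagate NaN).
#'
#' @param time numeric vector of strictly increasing times.
#' @param conc state matrix, one row per time, named columns.
#' @param rates optional kinetic-rate matrix (rows matching `time`).
#' @param inputs optional matrix of assembled input vectors.
#' @return object of class `ddehm_traj`.
#' @export
ddehm_traj <- function(time, conc, rates = NULL, inputs = NULL) {
  conc <- as.matrix(conc)
  if (length(time) != nrow(conc)) stop("time/state length mismatch")
  if (any(diff(time) <= 0)) stop("trajectory times must be strictly increasing")
  if (!all(is.finite(conc))) stop("trajectory contains non-finite states")
  structure(list(time = time, conc = conc, rates = rates, inputs = inputs),
            class = "ddehm_traj")
}

#' @export
print.ddehm_traj <- function(x, ...) {
  cat(sprintf("Trajectory: %d time points on [%g, %g], states: %s\n",
              length(x$time), x$time[1], x$time[length(x$time)],
              paste(colnames(x$conc), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.ddehm_traj <- function(x, ...) {
  d <- data.frame(time = x$time)
  cbind(d, as.data.frame(x$conc))
}

#' @export
plot.ddehm_traj <- function(x, which = NULL, ...) {
  cols <- if (is.null(which)) seq_len(ncol(x$conc)) else which
  old <- graphics::par(mfrow = c(length(cols), 1), mar = c(3.5, 4, 1, 1))
  on.exit(graphics::par(old))
  for (j in cols) {
    graphics::plot(x$time, x$conc[, j], type = "l",
                   xlab = "time", ylab = colnames(x$conc)[j], ...)
  }
  invisible(x)
}

# Sample a trajectory (linear interpolation) at requested times.
traj_sample <- function(time, conc, t_out) {
  out <- matrix(NA_real_, length(t_out), ncol(conc))
  colnames(out) <- colnames(conc)
  for (j in seq_len(ncol(conc)))
    out[, j] <- stats::approx(time, conc[, j], xout = t_out, rule = 2)$y
  out
}
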