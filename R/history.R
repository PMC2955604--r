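#' History buffer for delayed state lookups
#'
#' Stores the trajectory computed so far as (time, state) records and
#' answers queries for past values. Queries before the initial time
#' return the initial state exactly (pre-history clamping): lagged
#' values are assumed equal to `c(t0)` for all `t - k*tau < t0`.
#' Between stored points the value is linearly interpolated, matching
#' the fixed-step integration scheme.
#'
#' @param t0 initial time.
#' @param x0 initial state vector (named or not).
#' @param capacity initial storage capacity (grows as needed).
#' @return an object of class `history_buffer` (environment-backed).
#' @export
history_buffer <- function(t0, x0, capacity = 1024L) {
  x0 <- as.numeric(x0)
  e <- new.env(parent = emptyenv())
  e$times <- numeric(capacity)
  e$states <- matrix(NA_real_, capacity, length(x0))
  e$times[1L] <- t0
  e$states[1L, ] <- x0
  e$n <- 1L
  e$t0 <- t0
  e$x0 <- x0
  class(e) <- "history_buffer"
  e
}

#' Append a record to a history buffer
#'
#' Times must be strictly increasing.
#'
#' @param buf a [history_buffer()].
#' @param t time of the new record (must exceed the last stored time).
#' @param x state vector.
#' @export
history_append <- function(buf, t, x) {
  stopifnot(inherits(buf, "history_buffer"))
  if (t <= buf$times[buf$n]) stop("history times must be strictly increasing")
  if (buf$n == length(buf$times)) {
    buf$times <- c(buf$times, numeric(length(buf$times)))
    buf$states <- rbind(buf$states,
                        matrix(NA_real_, nrow(buf$states), ncol(buf$states)))
  }
  buf$n <- buf$n + 1L
  buf$times[buf$n] <- t
  buf$states[buf$n, ] <- as.numeric(x)
  invisible(buf)
}

#' Evaluate a delayed state value
#'
#' Returns the state at `t - offset`. If `t - offset < t0` the initial
#' state `c(t0)` is returned exactly; otherwise the buffered trajectory
#' is linearly interpolated. Querying beyond the stored range (forward
#' extrapolation) is a contract violation and raises an error.
#'
#' @param buf a [history_buffer()].
#' @param t current time (`t >= t0`).
#' @param offset non-negative lag offset.
#' @return state vector at `t - offset` (clamped to `c(t0)` before `t0`).
#' @export
evaluate_delayed <- function(buf, t, offset = 0) {
  stopifnot(inherits(buf, "history_buffer"))
  if (offset < 0) stop("lag offset must be non-negative")
  tq <- t - offset
  if (tq <= buf$t0) return(buf$x0)
  n <- buf$n
  tl <- buf$times[n]
  if (tq > tl + 1e-9 * max(1, abs(tl)))
    stop("delayed query at t = ", tq, " is beyond the buffered range (", tl, ")")
  if (tq >= tl) return(buf$states[n, ])
  i <- findInterval(tq, buf$times[seq_len(n)])
  t1 <- buf$times[i]; t2 <- buf$times[i + 1L]
  a <- (tq - t1) / (t2 - t1)
  (1 - a) * buf$states[i, ] + a * buf$states[i + 1L, ]
}

#' Assemble the time-lagged input vector
#'
#' Concatenates instantaneous and lagged values of the state variables
#' and exogenous inputs into the input vector of the nonparametric
#' kinetic term, in the fixed ordering: all lags of state 1, then state
#' 2, ..., then exogenous inputs in declared order, each with offsets
#' increasing. Pre-history queries clamp to the initial values for both
#' states and exogenous inputs.
#'
#' @param buf a [history_buffer()] covering `[t0, t]`.
#' @param exog_fns named list of exogenous signal functions `f(t)`; their
#'   names define the declared exogenous ordering.
#' @param t evaluation time.
#' @param spec a [lag_spec()].
#' @param state_names character vector naming the buffered state columns.
#' @param current optional current state vector; when supplied, offset-0
#'   state entries are taken from it instead of the buffer head (used by
#'   integrators mid-step).
#' @return numeric input vector of length [lag_input_dim()].
#' @export
assemble_input_vector <- function(buf, exog_fns, t, spec, state_names,
                                  current = NULL) {
  layout <- lag_layout(spec, state_names, names(exog_fns))
  out <- numeric(length(layout))
  for (k in seq_along(layout)) {
    it <- layout[[k]]
    if (it$type == "state") {
      out[k] <- if (it$offset == 0 && !is.null(current)) current[it$index]
      else evaluate_delayed(buf, t, it$offset)[it$index]
    } else {
      f <- exog_fns[[it$index]]
      out[k] <- f(max(t - it$offset, buf$t0))
    }
  }
  out
}
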