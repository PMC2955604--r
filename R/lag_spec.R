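#' Discrete lag specification for hybrid model inputs
#'
#' A `lag_spec` describes, for every state variable and every exogenous
#' input signal, which past values enter the input vector of the
#' nonparametric kinetic term. Each entry is either a regular series
#' (lag interval `tau` and lag count `n`, giving offsets
#' `0, tau, 2*tau, ..., n*tau`) or an explicit vector of absolute lag
#' `offsets` (the instantaneous value, offset 0, is always included and
#' need not be listed).
#'
#' With all lag counts zero the input vector reduces to instantaneous
#' values only, i.e. the model degenerates to a standard (non-delayed)
#' hybrid model.
#'
#' @param states named list; one entry per state variable, each a list
#'   with fields `tau` and `n`, or a list with field `offsets`. States
#'   not listed contribute their instantaneous value only when
#'   `implicit_states` is supplied.
#' @param exog named list with the same entry structure for exogenous
#'   inputs (may be empty).
#' @return an object of class `lag_spec`.
#' @examples
#' sp <- lag_spec(states = list(x = list(tau = 120, n = 1)))
#' lag_times(sp, "x")        # 0 120
#' lag_input_dim(sp)         # 2
#' @export
lag_spec <- function(states = list(), exog = list()) {
  norm <- function(entries, kind) {
    if (length(entries) == 0) return(list())
    if (is.null(names(entries)) || any(names(entries) == ""))
      stop("all ", kind, " lag entries must be named")
    lapply(entries, function(e) {
      if (!is.null(e$offsets)) {
        off <- sort(unique(c(0, as.numeric(e$offsets))))
        if (any(off < 0)) stop("lag offsets must be non-negative")
        return(list(offsets = off))
      }
      n <- if (is.null(e$n)) 0L else as.integer(e$n)
      tau <- if (is.null(e$tau)) 0 else as.numeric(e$tau)
      if (n < 0) stop("lag count must be non-negative")
      if (n > 0 && tau <= 0) stop("lag interval tau must be > 0 when n > 0")
      list(tau = tau, n = n)
    })
  }
  structure(list(states = norm(states, "state"), exog = norm(exog, "exogenous")),
            class = "lag_spec")
}

#' Lag offsets of one variable
#'
#' Returns the ordered lag offsets `[0, tau, 2*tau, ..., n*tau]` (or the
#' explicit offset vector) used for a variable.
#'
#' @param spec a [lag_spec()].
#' @param variable variable name (state or exogenous).
#' @return numeric vector of non-negative offsets in increasing order.
#' @export
lag_times <- function(spec, variable) {
  stopifnot(inherits(spec, "lag_spec"))
  e <- spec$states[[variable]]
  if (is.null(e)) e <- spec$exog[[variable]]
  if (is.null(e)) stop("unknown variable in lag spec: ", variable)
  if (!is.null(e$offsets)) e$offsets else c(0, e$tau * seq_len(e$n))
}

#' Total input dimension implied by a lag specification
#'
#' Equals the width of the neural network input layer:
#' `sum_i (N_i + 1) + sum_j (M_j + 1)`.
#'
#' @param spec a [lag_spec()].
#' @return integer input dimension.
#' @export
lag_input_dim <- function(spec) {
  stopifnot(inherits(spec, "lag_spec"))
  n <- 0L
  for (e in c(spec$states, spec$exog))
    n <- n + (if (!is.null(e$offsets)) length(e$offsets) else e$n + 1L)
  n
}

#' @export
print.lag_spec <- function(x, ...) {
  fmt <- function(e, nm) {
    off <- lag_times(x, nm)
    sprintf("  %s: offsets {%s}", nm, paste(off, collapse = ", "))
  }
  cat("Lag specification (input dim ", lag_input_dim(x), ")\n", sep = "")
  for (nm in names(x$states)) cat(fmt(x$states[[nm]], nm), "[state]\n")
  for (nm in names(x$exog)) cat(fmt(x$exog[[nm]], nm), "[exogenous]\n")
  invisible(x)
}

# Flat description of the input vector layout: one row per input-vector
# entry, in the fixed ordering "all lags of state 1, state 2, ...,
# then exogenous inputs in declared order, lags in increasing offset".
# Used by the input assembler, the sensitivity RHS and the C++ fast path.
lag_layout <- function(spec, state_names, exog_names = character()) {
  rows <- list()
  for (nm in names(spec$states)) {
    i <- match(nm, state_names)
    if (is.na(i)) stop("lag spec references unknown state: ", nm)
    for (off in lag_times(spec, nm))
      rows[[length(rows) + 1L]] <- list(type = "state", index = i, offset = off)
  }
  for (nm in names(spec$exog)) {
    j <- match(nm, exog_names)
    if (is.na(j)) stop("lag spec references unknown exogenous input: ", nm)
    for (off in lag_times(spec, nm))
      rows[[length(rows) + 1L]] <- list(type = "exog", index = j, offset = off)
  }
  rows
}

#' Serialize / restore a lag specification
#'
#' `lag_spec_to_json()` writes the spec as JSON (map variable name ->
#' `{tau, n}` or `{offsets}`); `lag_spec_from_json()` restores it.
#' Round-tripping reproduces identical input vectors on the same history.
#'
#' @param spec a [lag_spec()].
#' @param txt JSON string produced by `lag_spec_to_json`.
#' @return `lag_spec_to_json`: a JSON string; `lag_spec_from_json`: a
#'   [lag_spec()].
#' @export
lag_spec_to_json <- function(spec) {
  stopifnot(inherits(spec, "lag_spec"))
  jsonlite::toJSON(list(states = spec$states, exog = spec$exog),
                   auto_unbox = TRUE, digits = I(17))
}

#' @rdname lag_spec_to_json
#' @export
lag_spec_from_json <- function(txt) {
  x <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
  as_entries <- function(l) lapply(l, function(e) {
    if (!is.null(e$offsets)) list(offsets = as.numeric(e$offsets))
    else list(tau = as.numeric(e$tau), n = as.integer(e$n))
  })
  lag_spec(states = as_entries(x$states), exog = as_entries(x$exog))
}
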