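# Structure selection: grid search over hidden-node counts and delay
# sets, selection by validation BIC, and the delay-scan report that
# turns the grid into a system-delay identification strategy.

delay_label <- function(d) {
  if (is.list(d) && !is.null(d$tau)) {
    if (d$n == 0) "0" else sprintf("%dx%g", d$n, d$tau)
  } else {
    d <- as.numeric(d); d <- d[d > 0]
    if (!length(d)) "0" else paste(d, collapse = ", ")
  }
}

delay_value <- function(d) {
  if (is.list(d) && !is.null(d$tau)) { if (d$n == 0) 0 else d$tau }
  else {
    d <- as.numeric(d); d <- d[d > 0]
    if (!length(d)) 0 else if (length(d) == 1L) d else NA_real_
  }
}

#' Grid search over hidden nodes and delay sets
#'
#' Fits one hybrid model per grid point (hidden-node count x delay set)
#' with [fit_multistart()] and records MSE and BIC on the training,
#' validation and (optionally) test splits — the selection table of the
#' delay-scan strategy. Grid points fail individually (recorded, not
#' fatal), every grid point draws its seeds from its own derived
#' substream, and results are independent of execution order.
#'
#' @param builder function `f(hidden, delay_set)` returning a
#'   [hybrid_spec()]; see [tfa_builder()].
#' @param nodes integer vector of hidden-node counts.
#' @param delay_sets list of delay sets; each element is a numeric
#'   vector of absolute lag offsets (`0` or `numeric(0)` = no delay) or
#'   a list `list(tau =, n =)` for a regular lag series.
#' @param train,valid,test datasets ([ddehm_dataset()]); `test` may be
#'   NULL.
#' @param restarts random initializations per grid point.
#' @param seed master seed.
#' @param control a [ddehm_control()].
#' @param verbose print one line per grid point.
#' @return object of class `ddehm_scan`: `table` (one row per grid
#'   point), `fits` (fitted parameters per row), plus the call
#'   ingredients.
#' @export
ddehm_grid <- function(builder, nodes, delay_sets, train, valid, test = NULL,
                       restarts = 5, seed = 1, control = ddehm_control(),
                       verbose = FALSE) {
  stopifnot(length(nodes) >= 1, length(delay_sets) >= 1)
  grid <- expand.grid(i_node = seq_along(nodes),
                      i_delay = seq_along(delay_sets))
  rows <- vector("list", nrow(grid))
  fits <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    nn <- nodes[grid$i_node[g]]
    dset <- delay_sets[[grid$i_delay[g]]]
    gseed <- derive_seed(seed, "grid", g)
    res <- tryCatch({
      spec <- builder(nn, dset)
      ms <- fit_multistart(spec, train, valid, restarts, gseed, control)
      p <- ms$best$params
      h <- ms$best$h
      crit <- function(ds) if (is.null(ds)) c(MSE = NA_real_, BIC = NA_real_)
      else c(MSE = model_mse(spec, p, ds, h),
             BIC = model_bic(spec, p, ds, h))
      ct <- crit(train); cv <- crit(valid); cs <- crit(test)
      fits[[g]] <- list(params = p, spec = spec, h = h)
      data.frame(nn = nn, delay = delay_label(dset),
                 tau = delay_value(dset), n_w = n_weights(p),
                 bic_train = ct["BIC"], bic_valid = cv["BIC"],
                 bic_test = cs["BIC"], mse_train = ct["MSE"],
                 mse_valid = cv["MSE"], mse_test = cs["MSE"],
                 seed = gseed, best_restart = ms$best_restart,
                 ok = TRUE, error = "", row.names = NULL)
    }, error = function(e) {
      data.frame(nn = nn, delay = delay_label(dset),
                 tau = delay_value(dset), n_w = NA_integer_,
                 bic_train = NA_real_, bic_valid = NA_real_,
                 bic_test = NA_real_, mse_train = NA_real_,
                 mse_valid = NA_real_, mse_test = NA_real_,
                 seed = gseed, best_restart = NA_integer_,
                 ok = FALSE, error = conditionMessage(e), row.names = NULL)
    })
    rows[[g]] <- res
    if (verbose)
      message(sprintf("grid %d/%d: nn=%d delay={%s} bic_valid=%.1f",
                      g, nrow(grid), nn, res$delay, res$bic_valid))
  }
  structure(list(table = do.call(rbind, rows), fits = fits,
                 nodes = nodes, delay_sets = delay_sets, seed = seed,
                 restarts = restarts),
            class = "ddehm_scan")
}

#' Convenience spec builder for the TF autoactivation case study
#'
#' Returns a `builder(hidden, delay_set)` closure for [ddehm_grid()]
#' that instantiates [tfa_spec()] structures.
#'
#' @param structure,k_deg,r_bas,t_ref,t_scale passed to [tfa_spec()].
#' @return function of `(hidden, delay_set)`.
#' @export
tfa_builder <- function(structure = "1C", k_deg = 1, r_bas = 0.4 / 7,
                        t_ref = 200, t_scale = 120) {
  function(hidden, delay_set) {
    lags <- if (is.list(delay_set) && !is.null(delay_set$tau)) delay_set
    else as.numeric(delay_set)
    tfa_spec(structure, hidden = hidden, lags = lags, k_deg = k_deg,
             r_bas = r_bas, t_ref = t_ref, t_scale = t_scale)
  }
}

#' Select the best row of a selection table
#'
#' The selected model maximises the validation-set BIC; ties are broken
#' by the smaller parameter count, then the earlier row.
#'
#' @param scan a `ddehm_scan` (or its `table`).
#' @return the selected row (single-row data frame, with attribute
#'   `"row"` giving its index).
#' @export
select_best <- function(scan) {
  tab <- if (inherits(scan, "ddehm_scan")) scan$table else scan
  if (is.null(tab) || !nrow(tab)) stop("empty selection table")
  ok <- which(tab$ok & is.finite(tab$bic_valid))
  if (!length(ok)) stop("no successful grid points")
  o <- ok[order(-tab$bic_valid[ok], tab$n_w[ok], ok)]
  out <- tab[o[1L], , drop = FALSE]
  attr(out, "row") <- o[1L]
  out
}

#' Delay-scan report: identify the system delay from the grid
#'
#' Summarises the selection table into a per-delay curve of best
#' validation BIC and reports its argmax as the identified system
#' delay. Flags whether the no-delay model is dominated, whether the
#' argmax sits on the grid edge, whether the curve is indeterminate
#' (all equal), and marks strayed rows deviating more than 3 MAD from
#' the per-delay trend.
#'
#' @param scan a `ddehm_scan` (or its `table`); must span at least two
#'   delay values. Only single-delay rows (including no delay) enter
#'   the curve.
#' @return list of class `ddehm_delay_scan` with `curve` (delay, best
#'   validation BIC, best nn), `estimate`, `no_delay_dominated`,
#'   `grid_edge`, `indeterminate`, `strays` (row indices).
#' @export
delay_scan_report <- function(scan) {
  tab <- if (inherits(scan, "ddehm_scan")) scan$table else scan
  rows <- which(tab$ok & !is.na(tab$tau) & is.finite(tab$bic_valid))
  taus <- sort(unique(tab$tau[rows]))
  if (length(taus) < 2) stop("delay scan needs at least two delay values")
  curve <- do.call(rbind, lapply(taus, function(tv) {
    rr <- rows[tab$tau[rows] == tv]
    b <- which.max(tab$bic_valid[rr])
    data.frame(tau = tv, bic_valid = tab$bic_valid[rr[b]],
               nn = tab$nn[rr[b]])
  }))
  spread <- diff(range(curve$bic_valid))
  indeterminate <- spread <= 1e-9 * max(1, abs(curve$bic_valid[1]))
  est <- if (indeterminate) NA_real_ else curve$tau[which.max(curve$bic_valid)]
  grid_edge <- !indeterminate &&
    (est == min(curve$tau) || est == max(curve$tau))
  nd <- curve$bic_valid[curve$tau == 0]
  no_delay_dominated <- length(nd) == 1 && any(curve$bic_valid > nd)
  # strayed rows: validation BIC > 3 MAD from the per-delay median
  strays <- integer(0)
  for (tv in taus) {
    rr <- rows[tab$tau[rows] == tv]
    if (length(rr) < 3) next
    md <- stats::median(tab$bic_valid[rr])
    s <- stats::mad(tab$bic_valid[rr])
    if (s > 0) strays <- c(strays, rr[abs(tab$bic_valid[rr] - md) > 3 * s])
  }
  structure(list(curve = curve, estimate = est,
                 no_delay_dominated = isTRUE(no_delay_dominated),
                 grid_edge = grid_edge, indeterminate = indeterminate,
                 strays = strays),
            class = "ddehm_delay_scan")
}

#' @export
print.ddehm_delay_scan <- function(x, ...) {
  cat("Delay scan (best validation BIC per delay):\n")
  print(x$curve, row.names = FALSE)
  if (x$indeterminate) cat("identified delay: indeterminate (flat curve)\n")
  else cat(sprintf("identified delay: %g%s\n", x$estimate,
                   if (x$grid_edge) " [grid edge]" else ""))
  cat("no-delay model dominated:", x$no_delay_dominated, "\n")
  if (length(x$strays)) cat("strayed rows:", x$strays, "\n")
  invisible(x)
}

#' @export
print.ddehm_scan <- function(x, ...) {
  cat(sprintf("Selection table: %d grid point(s), %d restart(s) each\n",
              nrow(x$table), x$restarts))
  print(x$table[, c("nn", "delay", "bic_train", "bic_valid", "bic_test",
                    "mse_train", "mse_valid", "mse_test")],
        row.names = FALSE, digits = 5)
  invisible(x)
}

#' @export
plot.ddehm_scan <- function(x, ...) {
  tab <- x$table[x$table$ok & !is.na(x$table$tau), ]
  if (!nrow(tab)) stop("nothing to plot")
  nns <- sort(unique(tab$nn))
  graphics::plot(range(tab$tau), range(tab$bic_valid), type = "n",
                 xlab = "input delay", ylab = "validation BIC", ...)
  for (k in seq_along(nns)) {
    d <- tab[tab$nn == nns[k], ]
    d <- d[order(d$tau), ]
    graphics::lines(d$tau, d$bic_valid, col = k, type = "b", pch = 19)
  }
  graphics::legend("bottomright", legend = paste("nn =", nns),
                   col = seq_along(nns), lty = 1, pch = 19, cex = 0.8)
  invisible(x)
}
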