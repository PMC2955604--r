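# Bridge between hybrid specs and the compiled fixed-step integrator.
# Standard-form specs (psi one/state, standard dilution and feed terms)
# run on the C++ path; anything else falls back to the R reference
# implementation, which is tested for equality against this path.

cpp_eligible <- function(spec) {
  (spec$psi$type %in% c("one", "state")) &&
    (spec$dilution$type %in% c("none", "constant", "data", "growth")) &&
    (spec$feed$type %in% c("none", "constant", "dilution_sf"))
}

cpp_solve <- function(spec, p, ctx, t0, t_end, h, min_off, want_sens) {
  if (h <= 0) stop("step size must be positive")
  if (h > min_off + 1e-12)
    stop("step size h = ", h, " exceeds the smallest lag offset (", min_off,
         "); delayed values would not be in the past buffer")
  n_steps <- max(1L, as.integer(ceiling((t_end - t0) / h - 1e-9)))
  h_eff <- (t_end - t0) / n_steps
  tg <- t0 + h_eff * (0:n_steps)
  lay <- ctx$lay
  n_exog <- length(ctx$exog_fns)
  exog_grid <- matrix(0, n_steps + 1L, max(1L, n_exog))
  if (n_exog > 0)
    for (j in seq_len(n_exog))
      exog_grid[, j] <- vapply(tg, ctx$exog_fns[[j]], 0)
  d <- spec$dilution
  d_mode <- switch(d$type, none = 0L, constant = 1L, data = 2L, growth = 0L)
  d_const <- if (d$type == "constant") d$value else 0
  d_grid <- if (d$type == "data") vapply(tg, ctx$D_fn, 0) else numeric(1)
  f <- spec$feed
  u_mode <- switch(f$type, none = 0L, constant = 1L, dilution_sf = 2L)
  m <- length(ctx$x0)
  u_const <- if (f$type == "constant") rep_len(f$value, m) else numeric(m)
  u_sf <- if (f$type == "dilution_sf") rep_len(f$sf, m) else numeric(m)
  growth <- as.integer(ctx$growth)
  mu_index <- if (ctx$growth) spec$dilution$mu_index else 1L
  b_growth <- if (ctx$growth) rep_len(spec$dilution$b, m) else numeric(m)
  out <- integrate_hybrid_cpp(
    ctx$x0, t0, h_eff, n_steps, spec$K,
    if (spec$psi$type == "state") 1L else 0L,
    if (spec$psi$type == "state") spec$psi$index else 1L,
    p$w1, p$b1, p$w2, p$b2,
    as.integer(p$input_tanh), p$output_scale,
    lay$type, lay$index, lay$offset,
    exog_grid, d_mode, d_const, d_grid,
    u_mode, u_const, u_sf,
    growth, mu_index, b_growth,
    want_sens)
  list(time = drop(out$time), states = out$states,
       sens = if (want_sens) out$sens else NULL, h = h_eff)
}
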