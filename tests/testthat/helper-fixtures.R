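# Shared fixtures. Everything is generated in code; expensive objects
# are built lazily and cached for the session.

# A "linear" network: tanh operated in its linear range (one hidden
# unit per input, tiny input weights, large output weights) so that
# rho(X) = sum(coef * X) + intercept to ~1e-12 relative. Lets the
# hybrid machinery realise exactly known linear (D)DEs in tests.
linear_net <- function(coef, intercept = 0, input_tanh = NULL) {
  k <- length(coef)
  eps <- 1e-6
  mlp_params(w1 = diag(eps, k, k), b1 = rep(0, k),
             w2 = matrix(coef / eps, 1, k), b2 = intercept,
             input_tanh = input_tanh)
}

# Spec realising dx/dt = a * x(t - lag) (+ b * x(t)) through the hybrid
# machinery, via the linear net.
linear_delay_spec <- function(lag, hidden_coef_delayed = -1,
                              coef_inst = 0) {
  sp <- if (lag > 0)
    lag_spec(states = list(x = list(offsets = lag)))
  else lag_spec(states = list(x = list(tau = 0, n = 0)))
  hybrid_spec(state_names = "x", K = matrix(1, 1, 1), lags = sp,
              hidden = if (lag > 0) 2L else 1L)
}

linear_delay_net <- function(lag, coef_delayed = -1, coef_inst = 0) {
  if (lag > 0) linear_net(c(coef_inst, coef_delayed))
  else linear_net(coef_inst)
}

# Cached TF-A case study (the default study conditions).
tfa_study <- local({
  cache <- NULL
  function(master_seed = 1) {
    if (is.null(cache) || !identical(attr(cache, "seed"), master_seed)) {
      cache <<- make_case_study("tfa", master_seed = master_seed)
      attr(cache, "seed") <<- master_seed
    }
    cache
  }
})

# Small, quick TF-A study on a short horizon for optimisation tests.
tfa_study_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_case_study(
        "tfa",
        config = list(t_grid = seq(0, 700, 10)),
        master_seed = 42)
    cache
  }
})

expect_rel_equal <- function(object, expected, tol) {
  testthat::expect_lt(max(abs(object - expected)) /
                        max(abs(expected), 1e-300), tol)
}
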