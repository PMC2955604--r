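# Closed-form oracles for the integrators. The linear delayed decay
# dx/dt = -x(t-1) with history 1 has, by the method of steps,
# x(t) = 1 - t on [0, 1] and x(t) = 1 - t + (t-1)^2/2 on [1, 2].
lin_decay_exact <- function(t) {
  ifelse(t <= 1, 1 - t, 1 - t + (t - 1)^2 / 2)
}

lin_decay_spec <- function() {
  hybrid_spec("x", K = matrix(1), hidden = 2,
              lags = lag_spec(states = list(x = list(offsets = 1))))
}
lin_decay_net <- function() linear_net(c(0, -1))  # rho = -x(t-1)

test_that("fixed-step scheme matches method-of-steps closed forms", {
  sp <- lin_decay_spec(); p <- lin_decay_net()
  t_out <- seq(0, 2, 0.1)
  tr <- dde_solve_fixed(sp, p, t_out, h = 0.01, x0 = 1)
  expect_lt(max(abs(tr$conc[, 1] - lin_decay_exact(t_out))), 1e-4)  # O(h^2)
  expect_lt(abs(tr$conc[t_out == 1, 1]), 1e-4)                      # x(1) = 0
  # pure ODE (no delayed entries): dx/dt = -x, x(1) = exp(-1)
  spo <- hybrid_spec("x", K = matrix(1), hidden = 1,
                     lags = lag_spec(states = list(x = list(tau = 0, n = 0))))
  po <- linear_net(-1)
  tro <- dde_solve_fixed(spo, po, seq(0, 1, 0.1), h = 0.01, x0 = 1)
  expect_equal(unname(tro$conc[11, 1]), exp(-1), tolerance = 1e-4)
  # zero rates, zero dilution: trajectory constant at c(t0) exactly
  pz <- unflatten_params(p, rep(0, n_weights(p)))
  trz <- dde_solve_fixed(sp, pz, seq(0, 5, 1), h = 0.5, x0 = 3)
  expect_identical(max(abs(trz$conc - 3)), 0)
})

test_that("averaged-rate stepping is exact on the piecewise-polynomial oracle", {
  # on each method-of-steps interval the delayed term is (piecewise)
  # linear in t, which the averaged-rate (trapezoidal) update integrates
  # exactly when outputs align with the step grid
  sp <- lin_decay_spec(); p <- lin_decay_net()
  t_out <- seq(0, 2, 0.5)
  tr <- dde_solve_fixed(sp, p, t_out, h = 0.05, x0 = 1)
  expect_lt(max(abs(tr$conc[, 1] - lin_decay_exact(t_out))), 1e-11)
})

test_that("fixed-step global error shows second-order step halving", {
  # nonlinear-in-t right-hand side: dx/dt = -x, error measured at t = 1
  spo <- hybrid_spec("x", K = matrix(1), hidden = 1,
                     lags = lag_spec(states = list(x = list(tau = 0, n = 0))))
  po <- linear_net(-1)
  err <- sapply(c(0.1, 0.05, 0.025), function(h) {
    tr <- dde_solve_fixed(spo, po, c(0, 1), h = h, x0 = 1)
    abs(tr$conc[2, 1] - exp(-1))
  })
  expect_gt(err[1] / err[2], 3)   # ~4x per halving
  expect_gt(err[2] / err[3], 3)
})

test_that("step size above the smallest delay is rejected", {
  sp <- lin_decay_spec(); p <- lin_decay_net()
  expect_error(dde_solve_fixed(sp, p, seq(0, 2, 0.5), h = 1.5, x0 = 1),
               "exceeds the smallest lag offset")
})

test_that("divergence raises an error naming the time", {
  # dx/dt = 30 x realised via psi = x and a constant network output
  spo <- hybrid_spec("x", K = matrix(1), hidden = 1,
                     lags = lag_spec(states = list(x = list(tau = 0, n = 0))),
                     psi = list(type = "state", index = 1L))
  pexp <- mlp_params(w1 = matrix(0, 1, 1), b1 = 0, w2 = matrix(0, 1, 1),
                     b2 = 30)
  expect_error(dde_solve_fixed(spo, pexp, seq(0, 100, 1), h = 0.5, x0 = 1),
               "diverged")
})

test_that("adaptive RK2(3) meets the same oracles within tolerance", {
  sp <- lin_decay_spec(); p <- lin_decay_net()
  t_out <- seq(0, 2, 0.1)
  tr <- dde_solve_adaptive(sp, p, t_out, rel_tol = 1e-7, abs_tol = 1e-9, x0 = 1)
  expect_lt(max(abs(tr$conc[, 1] - lin_decay_exact(t_out))), 1e-5)
  # halving the tolerances moves the endpoint by less than the previous
  # error level (convergence contract)
  e1 <- dde_solve_adaptive(sp, p, t_out, 1e-6, 1e-8, x0 = 1)$conc[21, 1]
  e2 <- dde_solve_adaptive(sp, p, t_out, 5e-7, 5e-9, x0 = 1)$conc[21, 1]
  expect_lt(abs(e1 - e2), abs(e1 - lin_decay_exact(2)) + 1e-8)
})

test_that("adaptive mesh lands on propagated discontinuities t0 + k tau", {
  sp <- lin_decay_spec(); p <- lin_decay_net()
  tr <- dde_solve_adaptive(sp, p, seq(0, 3, 0.5), x0 = 1)
  mesh <- attr(tr, "mesh")
  for (k in 1:2)
    expect_lt(min(abs(mesh - k)), 1e-9)  # hit exactly by construction
})

test_that("adaptive and fixed-step integrators agree on the TF hybrid model", {
  spec <- tfa_spec("1C", hidden = 4, lags = 120)
  p <- spec_init_params(spec, 3)
  t_out <- seq(0, 600, 20)
  a <- dde_solve_adaptive(spec, p, t_out, rel_tol = 1e-8, abs_tol = 1e-10,
                          x0 = 0.1)
  f <- dde_solve_fixed(spec, p, t_out, h = 0.01 * 120, x0 = 0.1)
  expect_lt(max(abs(a$conc - f$conc)) / max(abs(a$conc)), 1e-3)
})

test_that("compiled and reference implementations are identical", {
  spec <- tfa_spec("1C", hidden = 4, lags = 120)
  p <- spec_init_params(spec, 9)
  t_out <- seq(0, 500, 25)
  fc <- dde_solve_fixed(spec, p, t_out, h = 1, x0 = 0.1, engine = "cpp")
  fr <- dde_solve_fixed(spec, p, t_out, h = 1, x0 = 0.1, engine = "r")
  expect_lt(max(abs(fc$conc - fr$conc)), 1e-14)
  sc <- dde_solve_sens(spec, p, t_out, h = 1, x0 = 0.1, engine = "cpp")
  sr <- dde_solve_sens(spec, p, t_out, h = 1, x0 = 0.1, engine = "r")
  expect_lt(max(abs(sc$traj$conc - sr$traj$conc)), 1e-14)
  expect_lt(max(abs(sc$sens - sr$sens)), 1e-13)
})

test_that("sensitivities start at zero and match a scalar closed form", {
  # dx/dt = w2 * g(w1 x) with w1 = 1e-6, w2 = -1e6 ~ -x; the sensitivity
  # to w2 is dx/da * da/dw2 = (-t e^{-t}) * (-w1) = t e^{-t} * 1e-6.
  spo <- hybrid_spec("x", K = matrix(1), hidden = 1,
                     lags = lag_spec(states = list(x = list(tau = 0, n = 0))))
  po <- linear_net(-1)
  sol <- dde_solve_sens(spo, po, seq(0, 1, 0.1), h = 0.002, x0 = 1)
  expect_true(all(sol$sens[1, , ] == 0))
  i_w2 <- 3L   # flattening order: w1, b1, w2, b2
  expect_equal(sol$sens[11, 1, i_w2], 1e-6 * exp(-1), tolerance = 1e-4)
})

test_that("hybrid sensitivities match finite differences of the full solve", {
  spec <- tfa_spec("1C", hidden = 3, lags = 120)
  p <- spec_init_params(spec, 7)
  t_out <- seq(0, 500, 50)
  sol <- dde_solve_sens(spec, p, t_out, h = 1, x0 = 0.1)
  w <- flatten_params(p)
  worst <- 0
  for (j in seq_along(w)) {
    d <- 1e-5 * max(1, abs(w[j]))
    wp <- w; wp[j] <- w[j] + d
    wm <- w; wm[j] <- w[j] - d
    xp <- dde_solve_fixed(spec, unflatten_params(p, wp), t_out, 1,
                          x0 = 0.1)$conc[, 1]
    xm <- dde_solve_fixed(spec, unflatten_params(p, wm), t_out, 1,
                          x0 = 0.1)$conc[, 1]
    fd <- (xp - xm) / (2 * d)
    worst <- max(worst, max(abs(sol$sens[, 1, j] - fd)) / max(1, max(abs(fd))))
  }
  expect_lt(worst, 1e-4)
})

test_that("trajectory container enforces its invariants", {
  expect_error(ddehm_traj(c(0, 1, 1), matrix(0, 3, 1)), "increasing")
  expect_error(ddehm_traj(c(0, 1), matrix(c(1, NaN), 2, 1)), "non-finite")
  tr <- ddehm_traj(c(0, 1), matrix(c(1, 2), 2, 1,
                                   dimnames = list(NULL, "x")))
  expect_identical(as.data.frame(tr)$x, c(1, 2))
})
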