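make_buf <- function(t0 = 0, x0 = 1) {
  buf <- history_buffer(t0, x0)
  for (t in seq(t0 + 5, t0 + 300, 5)) history_append(buf, t, x0 + t / 100)
  buf
}

test_that("kinetic rates reduce to the network output when psi is one", {
  sp <- hybrid_spec("x", K = matrix(1), hidden = 3,
                    lags = lag_spec(states = list(x = list(tau = 50, n = 1))))
  p <- spec_init_params(sp, 4)
  buf <- make_buf()
  X <- assemble_input_vector(buf, list(), 200, sp$lags, "x")
  expect_equal(kinetic_rates(200, buf, sp, p), mlp_forward(p, X))
  # zero network: rates vanish for any psi
  pz <- unflatten_params(p, rep(0, n_weights(p)))
  expect_identical(kinetic_rates(200, buf, sp, pz), 0)
})

test_that("parametric Monod factor multiplies the network element-wise", {
  Km <- 2
  sp <- hybrid_spec("S", K = matrix(-1), hidden = 1,
                    lags = lag_spec(states = list(S = list(tau = 0, n = 0))),
                    psi = list(type = "custom",
                               fn = function(cv, t) cv[1] / (Km + cv[1]),
                               jac = function(cv, t)
                                 matrix(Km / (Km + cv[1])^2, 1, 1)))
  # network configured as the constant 1
  p1 <- mlp_params(w1 = matrix(0, 1, 1), b1 = 0, w2 = matrix(0, 1, 1), b2 = 1)
  buf <- history_buffer(0, Km)   # S = Km -> Monod factor = 1/2
  expect_equal(kinetic_rates(0, buf, sp, p1), 0.5)
})

test_that("the balance is linear in the rates and matches hand cases", {
  sp3 <- hybrid_spec(c("a", "b", "c"), K = matrix(rnorm(9, 0, 1), 3, 3),
                     hidden = 2,
                     lags = lag_spec(states = list(a = list(tau = 0, n = 0))),
                     dilution = list(type = "constant", value = 0.3))
  buf <- history_buffer(0, c(1, 2, 3))
  # r = 0, u = 0: pure washout dc/dt = -D c
  pz <- spec_init_params(sp3, 1)
  pz <- unflatten_params(pz, rep(0, n_weights(pz)))
  expect_equal(hybrid_rhs(0, c(1, 2, 3), buf, sp3, pz), -0.3 * c(1, 2, 3))
  # D = 0, K = I: dc/dt = r
  spI <- hybrid_spec(c("a", "b", "c"), K = diag(3), hidden = 2,
                     lags = lag_spec(states = list(a = list(tau = 0, n = 0))))
  p <- spec_init_params(spI, 2)
  r <- kinetic_rates(0, buf, spI, p)
  expect_equal(hybrid_rhs(0, c(1, 2, 3), buf, spI, p), r)
  # superposition in the rates: constant-output networks with b2 = r
  pk <- function(r3) mlp_params(w1 = matrix(0, 2, 1), b1 = c(0, 0),
                                w2 = matrix(0, 3, 2), b2 = r3)
  r1 <- c(0.2, -1, 0.5); r2 <- c(1, 2, -0.3)
  f <- function(r3) hybrid_rhs(0, c(1, 2, 3), buf, sp3, pk(r3)) -
    hybrid_rhs(0, c(1, 2, 3), buf, sp3, pk(c(0, 0, 0)))
  expect_equal(f(r1 + r2), f(r1) + f(r2), tolerance = 1e-12)
})

test_that("growth-dilution mode subtracts mu times the state and adds transport", {
  # two states, two rates; rate 2 is the growth rate
  sp <- hybrid_spec(c("m", "n"), K = rbind(c(1, 0), c(0, 1)), hidden = 1,
                    lags = lag_spec(states = list(m = list(tau = 0, n = 0))),
                    dilution = list(type = "growth", mu_index = 2L,
                                    b = c(0.1, -0.2)))
  p <- mlp_params(w1 = matrix(0, 1, 1), b1 = 0, w2 = matrix(0, 2, 1),
                  b2 = c(0.5, 0.25))    # r = (0.5, mu = 0.25)
  buf <- history_buffer(0, c(2, 4))
  expect_equal(hybrid_rhs(0, c(2, 4), buf, sp, p),
               c(0.5, 0.25) + c(0.1, -0.2) - 0.25 * c(2, 4))
})

test_that("TF structure 1B with a zero network is inert", {
  sp <- tfa_spec("1B", hidden = 3, lags = 120)
  p <- spec_init_params(sp, 1)
  p <- unflatten_params(p, rep(0, n_weights(p)))
  tr <- dde_solve_fixed(sp, p, seq(0, 400, 20), h = 1, x0 = 0.5)
  expect_equal(max(abs(tr$conc - 0.5)), 0)
})

test_that("TF structure 1C with a zero network relaxes to R_bas/k_deg", {
  kd <- 0.02; rb <- 0.1
  sp <- tfa_spec("1C", hidden = 3, lags = 120, k_deg = kd, r_bas = rb)
  p <- spec_init_params(sp, 1)
  p <- unflatten_params(p, rep(0, n_weights(p)))
  t_out <- seq(0, 300, 10)
  tr <- dde_solve_fixed(sp, p, t_out, h = 0.25, x0 = 1)
  exact <- rb / kd + (1 - rb / kd) * exp(-kd * t_out)
  expect_lt(max(abs(tr$conc[, 1] - exact)), 1e-5)
})

test_that("TF structure 1C input width is lags plus the squashed time input", {
  sp <- tfa_spec("1C", hidden = 5, lags = 120)
  expect_identical(lag_input_dim(sp$lags), 3L)       # x(t), x(t-120), time
  expect_identical(sp$input_tanh, c(FALSE, FALSE, TRUE))
  sp0 <- tfa_spec("1C", hidden = 5, lags = 0)
  expect_identical(lag_input_dim(sp0$lags), 2L)      # x(t), time
})

test_that("Pichia structure wires S-lags in, specific rates out", {
  sp <- pichia_spec(hidden = 4, lags = list(tau = 2.5, n = 4))
  expect_identical(lag_input_dim(sp$lags), 5L)       # S(t) + 4 lags
  # stoichiometric bookkeeping: mu (output 2) feeds only the biomass row,
  # rS (output 1) drains substrate, rP (output 3) builds product
  expect_equal(sp$K, rbind(c(0, 1, 0), c(-1, 0, 0), c(0, 0, 1)))
  expect_identical(sp$psi$type, "state")
  expect_identical(sp$psi$index, 1L)
  # zero network and no feed: all states constant
  p <- spec_init_params(sp, 3)
  p <- unflatten_params(p, rep(0, n_weights(p)))
  n <- 41
  run <- ddehm_run(seq(0, 40, 1),
                   matrix(rep(c(3, 0.8, 0.1), each = n), ncol = 3,
                          dimnames = list(NULL, c("X", "S", "P"))),
                   sigma = c(X = .1, S = .1, P = .1),
                   exog = cbind(F = numeric(n), D = numeric(n),
                                V = rep(5, n)))
  tr <- dde_solve_fixed(sp, p, run$time, h = 0.1, run = run)
  expect_equal(max(abs(sweep(tr$conc, 2, c(3, 0.8, 0.1)))), 0)
})

test_that("a delay-free lag spec reproduces a reference ODE solution", {
  spec0 <- tfa_spec("1C", hidden = 4, lags = 0)
  p0 <- spec_init_params(spec0, 3)
  t_out <- seq(0, 600, 20)
  rhs_ode <- function(t, y, parms) {
    X <- c(y[1], tanh((t - 200) / 120))
    list(drop(p0$w2 %*% tanh(p0$w1 %*% X + p0$b1)) + p0$b2 - y[1] + 0.4 / 7)
  }
  od <- deSolve::ode(c(x = 0.1), t_out, rhs_ode, NULL,
                     rtol = 1e-10, atol = 1e-12)
  ad <- dde_solve_adaptive(spec0, p0, t_out, rel_tol = 1e-9, abs_tol = 1e-11,
                           x0 = 0.1)
  expect_lt(max(abs(ad$conc[, 1] - od[, 2])), 1e-6)
})
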