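test_that("non-delayed system started at its fixed point stays there", {
  tp <- tfa_params(tau = 0)
  x_star <- ddehm:::tfa_steady_state(tp, "low")
  # vector-field residual at the fixed point
  f <- tp$kf_low * x_star^2 / (x_star^2 + tp$Kd) - tp$k_deg * x_star + tp$r_bas
  expect_lt(abs(f), 1e-8)
  tp$x0 <- x_star
  tr <- simulate_tfa(tp, seq(0, 150, 10))   # before the induction step
  expect_lt(max(abs(tr$conc[, 1] - x_star)), 1e-8)
})

test_that("induction forces a jump; the delayed run shows the staircase", {
  t_grid <- seq(0, 1000, 10)
  tr_d <- simulate_tfa(tfa_params(), t_grid)
  tr_0 <- simulate_tfa(tfa_params(tau = 0), t_grid)
  x_d <- tr_d$conc[, 1]; x_0 <- tr_0$conc[, 1]
  # both transition to the same upper state
  expect_gt(tail(x_d, 1) / x_d[1], 10)
  expect_equal(tail(x_d, 1), tail(x_0, 1), tolerance = 1e-2)
  # staircase signature: within the transition window the delayed run
  # alternates between plateaus and bursts (speed ratio across adjacent
  # 120 min treads), the non-delayed run decays monotonically
  win <- t_grid >= 210 & t_grid <= 830
  rate_d <- diff(x_d)[win[-1]]
  tread <- floor(((t_grid[-1])[win[-1]] - 210) / 120)
  burst <- tapply(rate_d, tread, max)
  plateau <- tapply(rate_d, tread, min)
  expect_gte(sum(burst > 5 * pmax(plateau, 1e-12)), 3)  # >= 3 distinct stairs
  # the non-delayed transition has a single speed maximum (smooth sigmoid)
  rate_0 <- diff(x_0)
  peaks_0 <- sum(diff(sign(diff(rate_0))) < 0 & abs(rate_0[-c(1, 2)]) > 1e-4)
  expect_lte(peaks_0, 1)
  # delayed transition takes longer (10% -> 90% of the jump)
  rise <- function(x) {
    lo <- x[1] + 0.1 * (tail(x, 1) - x[1])
    hi <- x[1] + 0.9 * (tail(x, 1) - x[1])
    t_grid[min(which(x >= hi))] - t_grid[min(which(x >= lo))]
  }
  expect_gt(rise(x_d), rise(x_0))
})

test_that("raising the basal rate raises the low steady state", {
  tp1 <- tfa_params()
  tp2 <- tfa_params(r_bas = 0.8)   # doubled basal rate (raw units)
  expect_gt(ddehm:::tfa_steady_state(tp2, "low"),
            ddehm:::tfa_steady_state(tp1, "low"))
})

test_that("delayed TF simulation agrees with an independent DDE solver", {
  tp <- tfa_params()
  t_grid <- seq(0, 800, 10)
  tr <- simulate_tfa(tp, t_grid, h = 0.1)
  dd <- deSolve::dede(
    c(x = tp$x0), t_grid,
    function(t, y, parms) {
      xd <- if (t < tp$tau) tp$x0 else deSolve::lagvalue(t - tp$tau)
      kf <- if (t < tp$t_step) tp$kf_low else tp$kf_high
      list(kf * xd^2 / (xd^2 + tp$Kd) - tp$k_deg * y + tp$r_bas)
    }, NULL)
  expect_lt(max(abs(tr$conc[, 1] - dd[, 2])) / max(dd[, 2]), 5e-3)
})

test_that("fed-batch simulation respects its balances", {
  pp <- pichia_params()
  tr <- simulate_pichia(pp, t_end = 80, step = 0.25)
  # volume only grows through feeding (A4)
  expect_true(all(diff(tr$conc[, "V"]) >= -1e-12))
  # biomass grows, substrate is regulated towards the set point
  expect_gt(tail(tr$conc[, "X"], 1), 5 * pp$X0)
  expect_lt(abs(tail(tr$conc[, "S"], 1) - pp$S_set), 0.05)
  # delayed signal approaches the (settled) substrate level
  expect_lt(abs(tail(tr$conc[, "W"], 1) - tail(tr$conc[, "S"], 1)), 1e-3)
  # substrate mass balance: V S - V0 S0 = int(F SF - rS X V) within 0.5%
  VS <- tr$conc[, "V"] * tr$conc[, "S"]
  flux <- tr$exog[, "F"] * pp$SF - tr$rates[, "rS"] * tr$conc[, "X"] * tr$conc[, "V"]
  dt <- diff(tr$time)
  integral <- cumsum(c(0, dt * (head(flux, -1) + tail(flux, -1)) / 2))
  expect_lt(max(abs((VS - VS[1]) - integral)) / max(VS), 5e-3)
  # F == 0 whenever the controller demands removal (never negative)
  expect_true(all(tr$exog[, "F"] >= 0))
})

test_that("volume stays constant while the feed is shut", {
  # start above the set point with a tiny inoculum: the controller
  # demand is negative, so F clamps to zero and V is constant (A4)
  pp <- pichia_params(X0 = 0.01, S0 = 3, S_set = 1, W0 = 3, Z0 = 3)
  tr <- simulate_pichia(pp, t_end = 5, step = 0.1)
  expect_lt(max(tr$exog[, "F"]), 1e-12)
  expect_lt(max(abs(tr$conc[, "V"] - pp$V0)), 1e-8)
})

test_that("linear chain matches the Erlang-2 convolution", {
  beta <- 2.5
  # constant signal: kernel normalisation gives W = s0
  expect_equal(distributed_delay_oracle(function(t) 3.7, beta, t = 40,
                                        t0 = -100), 3.7, tolerance = 1e-9)
  # unit step at t = 0 with empty pre-history: closed-form step response
  Sstep <- function(t) as.numeric(t > 0)
  for (t in c(1, 2.5, 5, 12)) {
    expect_equal(distributed_delay_oracle(Sstep, beta, t, t0 = 0),
                 1 - (1 + t / beta) * exp(-t / beta), tolerance = 1e-3)
  }
  # sinusoidal forcing: chain ODE vs quadrature; the chain starts at the
  # clamped-history steady state, matching the oracle's t0 clamping
  S_sin <- function(t) 1 + 0.5 * sin(t / 3)
  chain <- deSolve::ode(c(W = S_sin(0), Z = S_sin(0)), seq(0, 40, 0.1),
                        function(t, y, parms)
                          list(c((y[2] - y[1]) / beta,
                                 (S_sin(t) - y[2]) / beta)), NULL,
                        rtol = 1e-10, atol = 1e-12)
  for (t in c(10, 25, 40)) {
    Wq <- distributed_delay_oracle(S_sin, beta, t, t0 = 0)
    Wc <- chain[chain[, 1] == t, "W"]
    expect_lt(abs(Wq - Wc) / abs(Wc), 1e-3)
  }
})

test_that("white-noise corruption is calibrated and reproducible", {
  n <- 10000
  tr <- ddehm_traj(seq_len(n), matrix(2, n, 1, dimnames = list(NULL, "x")))
  r0 <- add_noise(tr, relative_sd = 0, seed = 1)
  expect_identical(r0$conc, tr$conc)
  r1 <- add_noise(tr, relative_sd = 0.05, seed = 1)
  r1b <- add_noise(tr, relative_sd = 0.05, seed = 1)
  expect_identical(r1$conc, r1b$conc)
  expect_false(identical(r1$conc, add_noise(tr, 0.05, seed = 2)$conc))
  # empirical relative sd within 3 standard errors of the target
  rel <- (r1$conc[, 1] - 2) / 2
  se <- 0.05 / sqrt(2 * (n - 1))
  expect_lt(abs(sd(rel) - 0.05), 3 * se)
  # recorded per-variable sigma matches the injected noise scale
  expect_equal(unname(r1$sigma["x"]), 0.05 * 2, tolerance = 1e-12)
})

test_that("packaged case study has the documented layout and reproduces", {
  study <- tfa_study()
  # six noisy datasets from three clean trajectories, two per role
  expect_identical(length(study$clean), 3L)
  for (role in c("train", "valid", "test"))
    expect_identical(length(study[[role]]$runs), 2L)
  cleans <- unlist(lapply(c("train", "valid", "test"), function(rr)
    vapply(study[[rr]]$runs, function(r) r$config$clean_run, 0)))
  expect_setequal(unique(cleans), 1:3)
  # dataset invariants: positive sigma, strictly increasing times
  for (role in c("train", "valid", "test"))
    for (r in study[[role]]$runs) {
      expect_true(all(r$sigma > 0))
      expect_true(all(diff(r$time) > 0))
    }
  # regeneration from the same master seed is byte-identical on disk
  d1 <- file.path(tempdir(), "study_a"); d2 <- file.path(tempdir(), "study_b")
  write_dataset(make_case_study("tfa", master_seed = 9)$train, d1,
                overwrite = TRUE)
  write_dataset(make_case_study("tfa", master_seed = 9)$train, d2,
                overwrite = TRUE)
  for (fn in list.files(d1)) {
    expect_identical(readLines(file.path(d1, fn)),
                     readLines(file.path(d2, fn)))
  }
})
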