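# Synthetic-data generators for the two case studies: a delayed
# transcription-factor autoactivation loop (discrete delay) and a
# fed-batch Pichia pastoris culture whose growth and product formation
# lag methanol uptake through an Erlang-2 distributed delay realised by
# the linear chain trick. Plus white-noise corruption and train/valid/
# test packaging.

#' Parameters of the delayed TF autoactivation model
#'
#' The transcription factor x activates its own synthesis through a
#' positive-feedback Hill term driven by the nuclear concentration a
#' translocation delay tau ago:
#' `dx/dt = kf(t) x(t-tau)^2 / (x(t-tau)^2 + Kd) - k_deg x + R_bas`,
#' with the cytosol synthesis capacity `kf` stepping from `kf_low` to
#' `kf_high` at `t_step` (induction), which forces the bistable system
#' to jump to its upper state. With `tau > 0` the jump proceeds as a
#' staircase with treads one delay long.
#'
#' Constants are the classic values of this model expressed in rescaled
#' concentration units (`conc_scale` applies the model's exact scaling
#' symmetry `{kf*s, Kd*s^2, k_deg, R_bas*s}`), so that simulated
#' concentrations are of order one; `conc_scale = 1` recovers the raw
#' constants.
#'
#' @param kf_low,kf_high synthesis capacity before/after the step
#'   (concentration/min, raw units).
#' @param t_step induction time (min).
#' @param Kd Hill half-saturation (squared concentration, raw units).
#' @param k_deg first-order degradation rate (1/min).
#' @param r_bas basal synthesis rate (concentration/min, raw units).
#' @param tau translocation delay (min); 0 gives the non-delayed model.
#' @param x0 initial (and pre-history) concentration, scaled units;
#'   default is near the low steady state.
#' @param conc_scale unit rescaling factor applied to the raw constants.
#' @return object of class `tfa_params`.
#' @export
tfa_params <- function(kf_low = 6, kf_high = 20, t_step = 200,
                       Kd = 10, k_deg = 1, r_bas = 0.4,
                       tau = 120, x0 = NULL, conc_scale = 1 / 7) {
  stopifnot(kf_low > 0, kf_high > 0, Kd > 0, k_deg > 0, r_bas > 0, tau >= 0)
  s <- conc_scale
  p <- list(kf_low = kf_low * s, kf_high = kf_high * s, t_step = t_step,
            Kd = Kd * s^2, k_deg = k_deg, r_bas = r_bas * s, tau = tau,
            conc_scale = s)
  if (is.null(x0)) x0 <- tfa_steady_state(p, regime = "low")
  p$x0 <- x0
  structure(p, class = "tfa_params")
}

# Low-regime fixed point of the non-delayed vector field (Newton from
# the basal level); used for default initial conditions.
tfa_steady_state <- function(p, regime = c("low", "high")) {
  regime <- match.arg(regime)
  kf <- if (regime == "low") p$kf_low else p$kf_high
  f <- function(x) kf * x^2 / (x^2 + p$Kd) - p$k_deg * x + p$r_bas
  x <- if (regime == "low") p$r_bas / p$k_deg else kf / p$k_deg
  for (i in 1:100) {
    fx <- f(x)
    dfx <- kf * 2 * x * p$Kd / (x^2 + p$Kd)^2 - p$k_deg
    step <- fx / dfx
    x <- x - step
    if (abs(step) < 1e-14 * max(1, abs(x))) break
  }
  x
}

#' Simulate the delayed TF autoactivation model
#'
#' Integrates the single delayed balance with the fixed-step
#' averaged-rate scheme (pre-history equal to the initial value) and
#' samples the clean trajectory on `t_grid`. The synthesis rate is also
#' recorded for kinetic-rate diagnostics.
#'
#' @param params a [tfa_params()].
#' @param t_grid strictly increasing sampling times covering the
#'   induction step.
#' @param h integration step (min); default 0.25, well below the delay.
#' @return a [ddehm_traj()] with state column `x` and a `rates` matrix
#'   holding the delayed synthesis rate.
#' @export
simulate_tfa <- function(params, t_grid, h = 0.25) {
  stopifnot(inherits(params, "tfa_params"))
  p <- params
  t0 <- t_grid[1]
  rhs <- function(t, x, lookup) {
    xd <- if (p$tau > 0) lookup(t - p$tau)[1] else x[1]
    kf <- if (t < p$t_step) p$kf_low else p$kf_high
    kf * xd^2 / (xd^2 + p$Kd) - p$k_deg * x[1] + p$r_bas
  }
  sol <- heun_dde_core(rhs, p$x0, t0, t_grid[length(t_grid)], h,
                       min_offset = if (p$tau > 0) p$tau else Inf)
  conc <- traj_sample(sol$time, sol$states, t_grid)
  colnames(conc) <- "x"
  # synthesis rate along the sampled trajectory
  rate <- vapply(seq_along(t_grid), function(i) {
    t <- t_grid[i]
    tq <- t - p$tau
    xd <- if (tq <= t0) p$x0 else conc[max(which(t_grid <= tq)), 1]
    xd <- if (p$tau > 0) xd else conc[i, 1]
    kf <- if (t < p$t_step) p$kf_low else p$kf_high
    kf * xd^2 / (xd^2 + p$Kd)
  }, 0)
  ddehm_traj(t_grid, conc, rates = matrix(rate, ncol = 1,
                                          dimnames = list(NULL, "synthesis")))
}

#' Parameters of the fed-batch Pichia pastoris model
#'
#' Reactor balances for biomass X, methanol S, product P and volume V
#' under closed-loop feeding, with the specific growth and product
#' synthesis rates driven by the delayed substrate signal W obtained
#' from S through an Erlang-2 (quadratic) distributed delay kernel,
#' realised as the two-stage linear chain `dW/dt = (Z - W)/beta`,
#' `dZ/dt = (S - Z)/beta`. The kernel mean delay is `2*beta`.
#'
#' @param rS_max maximal specific methanol uptake rate (g/g/h).
#' @param Ks substrate affinity constant (g/L).
#' @param KB1 growth gain on the delayed substrate signal (1/h).
#' @param KB2 maintenance coefficient (1/h per unit m_ATP).
#' @param m_ATP maintenance demand (dimensionless factor).
#' @param Kp1 growth-associated product yield (g/g).
#' @param Kp2 non-growth-associated product formation rate (1/h).
#' @param beta delay kernel scale (h); mean delay `2*beta` = 5 h.
#' @param SF feed methanol concentration (g/L).
#' @param S_set substrate set point of the feed controller (g/L).
#' @param tau_set controller relaxation time (h).
#' @param X0,S0,P0,V0 initial biomass, substrate, product, volume.
#' @param W0,Z0 initial chain states (default `S0`: chain pre-loaded at
#'   the initial substrate level).
#' @return object of class `pichia_params`.
#' @export
pichia_params <- function(rS_max = 0.12, Ks = 0.1, KB1 = 0.05, KB2 = 0.004,
                          m_ATP = 1, Kp1 = 0.04, Kp2 = 2e-4,
                          beta = 2.5, SF = 300, S_set = 1, tau_set = 2,
                          X0 = 2, S0 = 0.5, P0 = 0, V0 = 5,
                          W0 = S0, Z0 = S0) {
  stopifnot(rS_max > 0, Ks > 0, KB1 > 0, beta > 0, SF > S_set, tau_set > 0,
            X0 > 0, V0 > 0)
  structure(as.list(environment()), class = "pichia_params")
}

# Specific rates of the truth model.
pichia_rates <- function(p, S, W) {
  rS <- p$rS_max * S / (p$Ks + S)
  mu <- p$KB1 * W / (p$Ks + W) - p$KB2 * p$m_ATP
  rP <- p$Kp1 * mu + p$Kp2
  list(rS = rS, mu = mu, rP = rP)
}

# Closed-loop feed rate (never negative).
pichia_feed <- function(p, S, X, V) {
  max(0, V / (p$SF - S) * (p$rS_max * S / (p$Ks + S) * X +
                             (p$S_set - S) / p$tau_set))
}

#' Simulate the fed-batch Pichia pastoris model
#'
#' Integrates the reactor balances with the linear-chain delayed
#' substrate signal (a plain ODE system after the chain substitution;
#' solved with `deSolve::ode`, lsoda) and records the feed rate F and
#' dilution rate D = F/V as exogenous signals, plus the specific rates.
#'
#' @param params a [pichia_params()].
#' @param t_end culture duration (h).
#' @param step output sampling interval (h).
#' @return a [ddehm_traj()] with columns X, S, P, V, W, Z, exogenous
#'   record in `$exog` (F, D) and specific rates in `$rates`.
#' @export
simulate_pichia <- function(params, t_end = 100, step = 0.5) {
  stopifnot(inherits(params, "pichia_params"))
  p <- params
  deriv <- function(t, y, parms) {
    X <- y[1]; S <- max(y[2], 0); P <- y[3]; V <- y[4]; W <- y[5]; Z <- y[6]
    rr <- pichia_rates(p, S, W)
    F <- pichia_feed(p, S, X, V)
    D <- F / V
    list(c(X * rr$mu - D * X,
           -rr$rS * X - D * (S - p$SF),
           rr$rP * X - D * P,
           F,
           (Z - W) / p$beta,
           (S - Z) / p$beta))
  }
  y0 <- c(X = p$X0, S = p$S0, P = p$P0, V = p$V0, W = p$W0, Z = p$Z0)
  times <- seq(0, t_end, by = step)
  out <- deSolve::ode(y0, times, deriv, parms = NULL,
                      rtol = 1e-8, atol = 1e-10)
  states <- out[, -1, drop = FALSE]
  if (any(states[, c("X", "V")] <= 0) || any(states[, "S"] < -1e-6))
    stop("model validity error: non-positive biomass/volume or negative substrate")
  rr <- pichia_rates(p, pmax(states[, "S"], 0), states[, "W"])
  F <- vapply(seq_len(nrow(states)), function(i)
    pichia_feed(p, max(states[i, "S"], 0), states[i, "X"], states[i, "V"]), 0)
  traj <- ddehm_traj(times, states,
                     rates = cbind(rS = rr$rS, mu = rr$mu, rP = rr$rP))
  traj$exog <- cbind(F = F, D = F / states[, "V"])
  traj
}

#' Convolution oracle for the Erlang-2 distributed delay
#'
#' Evaluates the delayed substrate signal directly as the convolution
#' `W(t) = int_0^inf S(t - a) a/beta^2 exp(-a/beta) da` with the
#' history clamped to `S(t0)` before `t0` (the tail then has the closed
#' form `S0 (1 + u/beta) exp(-u/beta)`, `u = t - t0`). Serves as the
#' independent check of the linear-chain realisation.
#'
#' @param S_fn function of time returning the substrate signal for
#'   `t >= t0`.
#' @param beta kernel scale.
#' @param t evaluation time.
#' @param t0 history start (signal clamped to `S_fn(t0)` earlier).
#' @return numeric W(t).
#' @export
distributed_delay_oracle <- function(S_fn, beta, t, t0 = 0) {
  u <- t - t0
  if (u <= 0) return(S_fn(t0))
  kern <- function(a) S_fn(t - a) * a / beta^2 * exp(-a / beta)
  # composite Simpson on the finite part (robust for tabulated signals)
  n <- 4000L
  a <- seq(0, u, length.out = n + 1L)
  k <- kern(a)
  wts <- c(1, rep(c(4, 2), length.out = n - 1L), 1)
  finite <- sum(wts * k) * (u / n) / 3
  tail <- S_fn(t0) * (1 + u / beta) * exp(-u / beta)
  finite + tail
}

#' Corrupt a clean trajectory with white noise
#'
#' Adds independent Gaussian noise to every sample. With
#' `relative_sd > 0` the noise standard deviation is proportional to
#' each clean value; with `sigma_abs` it is a fixed absolute value per
#' variable. The injected per-variable standard deviation (root mean
#' square over samples for relative noise) is recorded as the dataset's
#' `sigma`, and the draw is reproducible from `seed`.
#'
#' @param traj a [ddehm_traj()] (clean simulation).
#' @param relative_sd relative noise level (>= 0); 0 returns the clean
#'   values.
#' @param seed integer seed.
#' @param role split role recorded on the run.
#' @param sigma_abs optional named absolute noise SD per variable
#'   (overrides `relative_sd`).
#' @param config generating configuration stored with the run.
#' @return a run (see [ddehm_run()]) with the trajectory's exogenous
#'   record carried over.
#' @export
add_noise <- function(traj, relative_sd = 0.05, seed = 1,
                      role = "train", sigma_abs = NULL, config = NULL) {
  stopifnot(inherits(traj, "ddehm_traj"), relative_sd >= 0)
  clean <- traj$conc
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  eps <- matrix(stats::rnorm(length(clean)), nrow(clean), ncol(clean))
  if (!is.null(sigma_abs)) {
    sd_mat <- matrix(rep(sigma_abs[colnames(clean)], each = nrow(clean)),
                     nrow(clean), ncol(clean))
  } else {
    sd_mat <- relative_sd * abs(clean)
  }
  noisy <- clean + sd_mat * eps
  sigma <- sqrt(colMeans(sd_mat^2))
  sigma[sigma <= 0] <- 1e-12
  names(sigma) <- colnames(clean)
  ddehm_run(traj$time, noisy, sigma = sigma, exog = traj$exog,
            x0 = clean[1, ], role = role, clean = clean, config = config)
}

#' Generate a packaged case study
#'
#' Builds the synthetic train/validation/test datasets for a case
#' study. For `"tfa"`, three clean delayed-induction trajectories with
#' distinct initial concentrations are each corrupted independently so
#' that every split role receives two noisy runs (six noisy datasets
#' from three clean trajectories). For `"pichia"`, four fed-batch runs
#' with varied feed set points and inoculum sizes are generated and
#' split two/one/one. Every run carries its generating configuration;
#' regeneration from the same configuration and master seed is
#' byte-identical.
#'
#' @param case `"tfa"` or `"pichia"`.
#' @param config optional list overriding generator defaults; entries:
#'   `params` (a [tfa_params()] / [pichia_params()]), `t_grid` or
#'   `t_end`/`step`, `relative_sd`, `x0_set` (TF-A initial
#'   concentrations), `role_runs` (TF-A: list mapping role to clean-run
#'   indices).
#' @param master_seed integer master seed; per-run noise seeds are
#'   derived from it through named substreams.
#' @return list with elements `train`, `valid`, `test`
#'   ([ddehm_dataset()]s) and `clean` (list of clean trajectories).
#' @export
make_case_study <- function(case = c("tfa", "pichia"), config = list(),
                            master_seed = 1) {
  case <- match.arg(case)
  if (case == "tfa") make_tfa_study(config, master_seed)
  else make_pichia_study(config, master_seed)
}

make_tfa_study <- function(config, master_seed) {
  params <- config$params
  if (is.null(params)) params <- tfa_params()
  t_grid <- config$t_grid
  if (is.null(t_grid)) t_grid <- seq(0, 1000, by = 10)
  relative_sd <- config$relative_sd
  if (is.null(relative_sd)) relative_sd <- 0.05
  x0_set <- config$x0_set
  if (is.null(x0_set)) x0_set <- params$x0 * c(0.7, 1.0, 1.4)
  role_runs <- config$role_runs
  if (is.null(role_runs))
    role_runs <- list(train = c(1, 2), valid = c(3, 1), test = c(2, 3))
  clean <- lapply(x0_set, function(x0) {
    pp <- params; pp$x0 <- x0
    simulate_tfa(pp, t_grid)
  })
  cfg <- list(case = "tfa", params = unclass(params), t_grid_step = diff(t_grid[1:2]),
              t_end = t_grid[length(t_grid)], relative_sd = relative_sd,
              x0_set = x0_set, master_seed = master_seed)
  out <- list()
  for (role in names(role_runs)) {
    runs <- lapply(seq_along(role_runs[[role]]), function(j) {
      idx <- role_runs[[role]][j]
      sd_seed <- derive_seed(master_seed, paste0("noise_", role), j)
      add_noise(clean[[idx]], relative_sd, seed = sd_seed, role = role,
                config = c(cfg, list(clean_run = idx, noise_seed = sd_seed)))
    })
    out[[role]] <- ddehm_dataset(runs, state_names = "x")
  }
  out$clean <- clean
  out
}

make_pichia_study <- function(config, master_seed) {
  params <- config$params
  if (is.null(params)) params <- pichia_params()
  t_end <- config$t_end; if (is.null(t_end)) t_end <- 100
  step <- config$step; if (is.null(step)) step <- 1
  relative_sd <- config$relative_sd
  if (is.null(relative_sd)) relative_sd <- 0.05
  variations <- config$variations
  if (is.null(variations))
    variations <- list(list(S_set = 1.0, X0 = 2.0, role = "train"),
                       list(S_set = 0.8, X0 = 2.6, role = "train"),
                       list(S_set = 1.2, X0 = 1.6, role = "valid"),
                       list(S_set = 1.0, X0 = 2.2, role = "test"))
  clean <- list(); runs <- list()
  for (j in seq_along(variations)) {
    v <- variations[[j]]
    pp <- params
    for (nm in setdiff(names(v), "role")) pp[[nm]] <- v[[nm]]
    traj <- simulate_pichia(pp, t_end = t_end, step = step)
    clean[[j]] <- traj
    sd_seed <- derive_seed(master_seed, "noise_pichia", j)
    # only X, S, P are "measured"; V, W, Z stay clean (V is a known
    # reactor signal; W, Z are unobservable model internals)
    meas <- ddehm_traj(traj$time, traj$conc[, c("X", "S", "P")])
    meas$exog <- cbind(traj$exog, V = traj$conc[, "V"])
    r <- add_noise(meas, relative_sd, seed = sd_seed, role = v$role,
                   config = list(case = "pichia", variation = v,
                                 master_seed = master_seed,
                                 noise_seed = sd_seed))
    runs[[j]] <- r
  }
  ds <- ddehm_dataset(runs, state_names = c("X", "S", "P"),
                      exog_names = c("F", "D", "V"))
  list(train = dataset_role(ds, "train"),
       valid = dataset_role(ds, "valid"),
       test = dataset_role(ds, "test"),
       clean = clean)
}
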