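# Ready-made hybrid model structures for the two case studies.

#' Hybrid model structures for the delayed TF autoactivation system
#'
#' Builds the hybrid structure used to identify the delayed
#' transcription-factor dynamics from data:
#' \describe{
#' \item{`"1B"`}{no prior knowledge: `dx/dt = rho(X, w)` with the whole
#'   right-hand side nonparametric.}
#' \item{`"1C"`}{prior knowledge of first-order dissociation and basal
#'   synthesis: `dx/dt = rho(X, w) - k_deg x + R_bas` with the network
#'   covering only the delayed synthesis kinetics.}
#' }
#' In both structures the network input vector holds the instantaneous
#' and lagged nuclear concentrations plus a time input that is squashed
#' through the hyperbolic tangent (`g((t - t_ref)/t_scale)`), giving the
#' network a smooth switch feature around the known induction time.
#'
#' @param structure `"1B"` or `"1C"`.
#' @param hidden hidden-layer width.
#' @param lags lag specification for the state: a [lag_spec()], or a
#'   list `list(tau =, n =)` / `list(offsets =)` for the single state
#'   `x`, or a single delay value (shorthand for one lag at that
#'   offset); 0 or NULL gives the no-delay structure.
#' @param k_deg,r_bas parametric degradation and basal-rate constants
#'   of structure 1C (defaults match the generator's rescaled units).
#' @param t_ref,t_scale centre and scale of the time input (min).
#' @param output_scale fixed output scaling of the network.
#' @return a [hybrid_spec()].
#' @export
tfa_spec <- function(structure = c("1C", "1B"), hidden = 5, lags = 120,
                     k_deg = 1, r_bas = 0.4 / 7,
                     t_ref = 200, t_scale = 120, output_scale = 1) {
  structure <- match.arg(structure)
  if (is.null(lags)) lags <- numeric(0)
  if (is.numeric(lags)) lags <- lags[lags > 0]
  state_entry <- if (inherits(lags, "lag_spec")) lags$states$x
  else if (is.numeric(lags)) {
    if (length(lags) == 0) list(tau = 0, n = 0) else list(offsets = lags)
  } else lags
  sp <- lag_spec(states = list(x = state_entry),
                 exog = list(time = list(tau = 0, n = 0)))
  d_in <- lag_input_dim(sp)
  input_tanh <- c(rep(FALSE, d_in - 1L), TRUE)  # time input is squashed
  time_fn <- local({
    t_ref <- t_ref; t_scale <- t_scale
    function(t) (t - t_ref) / t_scale
  })
  if (structure == "1C") {
    hybrid_spec(state_names = "x", K = matrix(1, 1, 1), lags = sp,
                exog = list(time = time_fn),
                dilution = list(type = "constant", value = k_deg),
                feed = list(type = "constant", value = r_bas),
                hidden = hidden, input_tanh = input_tanh,
                output_scale = output_scale)
  } else {
    hybrid_spec(state_names = "x", K = matrix(1, 1, 1), lags = sp,
                exog = list(time = time_fn),
                hidden = hidden, input_tanh = input_tanh,
                output_scale = output_scale)
  }
}

#' Hybrid model structure for the fed-batch Pichia pastoris case
#'
#' Material balances for biomass, methanol and product with the three
#' specific rates (methanol uptake rS, growth mu, product synthesis rP)
#' delivered by the network from the instantaneous and lagged methanol
#' concentration; all rates are multiplied by biomass (`psi = X`), the
#' dilution rate `D = F/V` and the feed term `D SF` come with the
#' dataset as exogenous records:
#' `dX/dt = mu X - D X`, `dS/dt = -rS X - D (S - SF)`,
#' `dP/dt = rP X - D P`.
#'
#' @param hidden hidden-layer width.
#' @param lags lag specification on the methanol concentration: a list
#'   `list(tau =, n =)`, or NULL/0 for instantaneous input only.
#' @param SF feed methanol concentration (g/L), must match the
#'   generating feed.
#' @param output_scale fixed per-output scaling of the network; the
#'   defaults put the three specific rates on comparable footing.
#' @return a [hybrid_spec()].
#' @export
pichia_spec <- function(hidden = 5, lags = list(tau = 2.5, n = 4),
                        SF = 300, output_scale = c(0.1, 0.05, 0.005)) {
  if (is.null(lags) || (is.numeric(lags) && all(lags == 0)))
    lags <- list(tau = 0, n = 0)
  sp <- lag_spec(states = list(S = lags))
  K <- rbind(c(0, 1, 0),    # dX/dt =            mu X
             c(-1, 0, 0),   # dS/dt = -rS X
             c(0, 0, 1))    # dP/dt =                 rP X
  hybrid_spec(state_names = c("X", "S", "P"), K = K, lags = sp,
              psi = list(type = "state", index = 1L),
              dilution = list(type = "data", column = "D"),
              feed = list(type = "dilution_sf", sf = c(0, SF, 0)),
              hidden = hidden, output_scale = output_scale)
}
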