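#' Free energy of unfolding vs denaturant (linear extrapolation model)
#'
#' \eqn{\Delta G(D) = \Delta G_0 - m_{eq} D}. Positive values favour the
#' native state; the midpoint `Cm = dG0/m_eq` is the denaturant
#' concentration at which the free energy crosses zero.
#'
#' @param params A [two_state_chem_params()] object.
#' @param D Denaturant concentration, M (vectorised, nonnegative).
#' @return Free energy of unfolding, kJ/mol.
#' @examples
#' wt <- two_state_chem_params(30.9, 30.9 / 4.07)
#' dg_chem(wt, c(0, 4.07))   # dG0 at water, 0 at the midpoint
#' @export
dg_chem <- function(params, D) {
  stopifnot(inherits(params, "two_state_chem_params"))
  if (any(D < 0)) abort("Denaturant concentrations must be nonnegative.")
  params$dG0 - params$m_eq * D
}

#' Unfolded fraction vs denaturant
#'
#' Two-state Boltzmann population:
#' \eqn{f_U = 1/(1 + \exp(\Delta G(D)/(RT)))}; strictly increasing in D
#' and exactly 0.5 at the midpoint.
#'
#' @inheritParams dg_chem
#' @param T Temperature, K; positive.
#' @return Fraction unfolded in \[0, 1\].
#' @examples
#' wt <- two_state_chem_params(30.9, 30.9 / 4.07)
#' frac_unfolded_chem(wt, D = 4.07, T = 298)  # 0.5
#' @export
frac_unfolded_chem <- function(params, D, T = 298) {
  if (any(T <= 0)) abort("Temperatures must be positive (kelvin).")
  1 / (1 + exp(dg_chem(params, D) / (.R * T)))
}

#' Two-state signal model for a chemical denaturation curve
#'
#' Linear native/unfolded baselines weighted by the two-state
#' populations: \eqn{y(D) = (a_N + b_N D)(1 - f_U) + (a_U + b_U D) f_U}.
#'
#' @inheritParams frac_unfolded_chem
#' @return Signal values (same units as the baseline coefficients).
#' @export
signal_chem <- function(params, D, T = 298) {
  fU <- frac_unfolded_chem(params, D, T)
  b <- params$baselines
  (b[["aN"]] + b[["bN"]] * D) * (1 - fU) + (b[["aU"]] + b[["bU"]] * D) * fU
}

#' Free energy of a thermal two-state step (Gibbs-Helmholtz)
#'
#' \eqn{\Delta G(T) = \Delta H_m (1 - T/T_m) +
#' \Delta C_p [(T - T_m) - T \ln(T/T_m)]}; zero at `Tm` by construction,
#' and with `dCp > 0` the stability curve has a maximum below `Tm`
#' (cold-denaturation curvature).
#'
#' @param step A [thermal_step_params()] object.
#' @param T Temperature, K (vectorised, positive).
#' @return Free energy, kJ/mol.
#' @examples
#' nu <- thermal_step_params(Tm = 337, dHm = 300)
#' dg_thermal(nu, c(327, 337))
#' @export
dg_thermal <- function(step, T) {
  stopifnot(inherits(step, "thermal_step_params"))
  if (any(T <= 0)) abort("Temperatures must be positive (kelvin).")
  step$dHm * (1 - T / step$Tm) +
    step$dCp * ((T - step$Tm) - T * log(T / step$Tm))
}

#' Unfolded fraction vs temperature for a thermal two-state step
#'
#' @inheritParams dg_thermal
#' @return Fraction converted (unfolded) in \[0, 1\].
#' @export
frac_unfolded_thermal <- function(step, T) {
  1 / (1 + exp(dg_thermal(step, T) / (.R * T)))
}

#' Folding/unfolding relaxation rate vs denaturant (chevron)
#'
#' Under the free-energy-slope convention,
#' \eqn{\ln k_f(D) = \ln k_f^0 + m_f D/(RT)} and
#' \eqn{\ln k_u(D) = \ln k_u^0 + m_u D/(RT)}, with the observed
#' relaxation rate \eqn{\lambda(D) = k_f(D) + k_u(D)}. With
#' `mf < 0 < mu` the log rate traces the characteristic V-shaped
#' chevron.
#'
#' @param params A [chevron_params()] object.
#' @param D Denaturant concentration, M (vectorised, nonnegative).
#' @param T Temperature, K.
#' @param convention Kinetic m-value interpretation. Only
#'   `"free-energy-slope"` (slopes of \eqn{RT \ln k} vs D, m in
#'   kJ/(mol M)) is supported.
#' @return Relaxation rate, 1/s.
#' @examples
#' wt <- chevron_params(44, 1.9e-4, -0.78, 0.51)
#' relaxation_rate(wt, D = 0)   # kf0 + ku0
#' @export
relaxation_rate <- function(params, D, T = 298,
                            convention = "free-energy-slope") {
  stopifnot(inherits(params, "chevron_params"))
  if (!identical(convention, "free-energy-slope"))
    abort(sprintf("Unknown kinetic m-value convention: %s", convention))
  if (any(D < 0)) abort("Denaturant concentrations must be nonnegative.")
  if (any(T <= 0)) abort("Temperatures must be positive (kelvin).")
  RT <- .R * T
  exp(log(params$kf0) + params$mf * D / RT) +
    exp(log(params$ku0) + params$mu * D / RT)
}

#' Denaturant concentration at the chevron minimum
#'
#' Closed-form stationary point of \eqn{\lambda(D)}:
#' \eqn{D^* = RT \ln(k_f^0 |m_f| / (k_u^0 m_u)) / (|m_f| + m_u)}.
#' Returns `NA` when either arm is flat.
#'
#' @inheritParams relaxation_rate
#' @return Denaturant concentration, M.
#' @export
chevron_minimum <- function(params, T = 298) {
  stopifnot(inherits(params, "chevron_params"))
  if (params$mf == 0 || params$mu == 0) return(NA_real_)
  RT <- .R * T
  RT * log(params$kf0 * abs(params$mf) / (params$ku0 * params$mu)) /
    (abs(params$mf) + params$mu)
}
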