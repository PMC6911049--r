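#' Two-state chemical-denaturation parameters (linear extrapolation model)
#'
#' Parameter container for the linear extrapolation model (LEM) of chemical
#' denaturation: \eqn{\Delta G(D) = \Delta G_0 - m_{eq} D}. The optical
#' signal model uses linear native and unfolded baselines.
#'
#' @param dG0 Free energy of unfolding in water, kJ/mol.
#' @param m_eq Equilibrium denaturant dependence (m-value), kJ/(mol M);
#'   must be positive.
#' @param baselines Named numeric vector with elements `aN`, `bN`, `aU`,
#'   `bU`: native/unfolded signal intercepts (signal units) and slopes
#'   (signal units per M denaturant).
#' @return An object of class `two_state_chem_params`.
#' @examples
#' wt <- two_state_chem_params(dG0 = 30.9, m_eq = 30.9 / 4.07)
#' wt$Cm   # denaturation midpoint, M
#' @export
two_state_chem_params <- function(dG0, m_eq,
                                  baselines = c(aN = 1, bN = -0.02,
                                                aU = 0.2, bU = 0.01)) {
  stopifnot(is.numeric(dG0), length(dG0) == 1L,
            is.numeric(m_eq), length(m_eq) == 1L)
  if (m_eq <= 0) abort("`m_eq` must be positive.")
  need <- c("aN", "bN", "aU", "bU")
  if (!all(need %in% names(baselines)))
    abort("`baselines` must contain aN, bN, aU, bU.")
  structure(list(dG0 = dG0, m_eq = m_eq, Cm = dG0 / m_eq,
                 baselines = baselines[need]),
            class = "two_state_chem_params")
}

#' Chevron-plot kinetic parameters
#'
#' Folding/unfolding rates in water and their kinetic m-values, under the
#' free-energy-slope convention: \eqn{\ln k(D) = \ln k^0 + m D/(RT)} with
#' m in kJ/(mol M) (negative for folding, positive for unfolding).
#'
#' @param kf0 Folding rate in water, 1/s; positive.
#' @param ku0 Unfolding rate in water, 1/s; positive.
#' @param mf Kinetic m-value of folding, kJ/(mol M); must be <= 0.
#' @param mu Kinetic m-value of unfolding, kJ/(mol M); must be >= 0.
#' @return An object of class `chevron_params`.
#' @examples
#' chevron_params(kf0 = 44, ku0 = 1.9e-4, mf = -0.78, mu = 0.51)
#' @export
chevron_params <- function(kf0, ku0, mf, mu) {
  if (kf0 <= 0 || ku0 <= 0) abort("`kf0` and `ku0` must be positive.")
  if (mf > 0 || mu < 0) abort("Require mf <= 0 <= mu.")
  structure(list(kf0 = kf0, ku0 = ku0, mf = mf, mu = mu),
            class = "chevron_params")
}

#' Thermal two-state step parameters (Gibbs-Helmholtz)
#'
#' One thermally driven conformational step, parameterised by its midpoint
#' temperature, van't Hoff enthalpy at the midpoint and heat-capacity
#' change, so that \eqn{\Delta G(T_m) = 0} exactly.
#'
#' @param Tm Midpoint temperature, K; positive.
#' @param dHm van't Hoff enthalpy at `Tm`, kJ/mol.
#' @param dCp Heat-capacity change, kJ/(mol K). Default 0.
#' @return An object of class `thermal_step_params`.
#' @examples
#' thermal_step_params(Tm = 337, dHm = 300)
#' @export
thermal_step_params <- function(Tm, dHm, dCp = 0) {
  if (Tm <= 0) abort("`Tm` must be positive (kelvin).")
  structure(list(Tm = Tm, dHm = dHm, dCp = dCp),
            class = "thermal_step_params")
}

#' Association / binding step parameters
#'
#' A mass-action association step (n X <-> X_n) or bimolecular binding
#' step, parameterised by its standard free energy and enthalpy at a
#' reference temperature plus a heat-capacity change:
#' \eqn{\Delta H(T) = \Delta H_{ref} + \Delta C_p (T - T_{ref})},
#' \eqn{\Delta S(T) = (\Delta H_{ref} - \Delta G_{ref})/T_{ref} + \Delta C_p \ln(T/T_{ref})},
#' \eqn{\Delta G(T) = \Delta H(T) - T \Delta S(T)}. Equilibrium constants
#' are on the 1 M standard state.
#'
#' @param dG_ref Standard free energy at `T_ref`, kJ/mol (negative for a
#'   favourable step).
#' @param dH_ref Standard enthalpy at `T_ref`, kJ/mol. Default 0.
#' @param dCp Heat-capacity change, kJ/(mol K). Default 0.
#' @param T_ref Reference temperature, K. Default 298.
#' @param n Stoichiometry of the step (number of associating units).
#' @return An object of class `assoc_step_params`.
#' @examples
#' assoc_step_params(dG_ref = -170, n = 6)  # strongly favourable hexamerisation
#' @export
assoc_step_params <- function(dG_ref, dH_ref = 0, dCp = 0, T_ref = 298, n = 1) {
  if (T_ref <= 0) abort("`T_ref` must be positive (kelvin).")
  if (n < 1) abort("`n` must be >= 1.")
  structure(list(dG_ref = dG_ref, dH_ref = dH_ref, dCp = dCp,
                 T_ref = T_ref, n = n),
            class = "assoc_step_params")
}

#' Free energy of an association/binding step at temperature T
#'
#' @param step An [assoc_step_params()] object.
#' @param T Temperature, K (vectorised).
#' @return Free energy, kJ/mol.
#' @export
dg_assoc <- function(step, T) {
  stopifnot(inherits(step, "assoc_step_params"))
  if (any(T <= 0)) abort("Temperatures must be positive (kelvin).")
  dS_ref <- (step$dH_ref - step$dG_ref) / step$T_ref
  dH <- step$dH_ref + step$dCp * (T - step$T_ref)
  dS <- dS_ref + step$dCp * log(T / step$T_ref)
  dH - T * dS
}

#' Five-species linkage-model parameters
#'
#' Thermodynamic parameters of the coupled scheme linking a monomer fold
#' switch to oligomeric assembly. Species: native monomer N, peptide-bound
#' native monomer NP, fold-switched monomer S, unfolded monomer U, hexamer
#' H (six S) and dodecamer H2 (two H). Only the switched conformation
#' assembles; the effector peptide binds only N.
#'
#' Any step may be `NULL`, which disables it (its equilibrium constant is
#' taken as exactly zero and the corresponding species never populates).
#'
#' @param step_NS [thermal_step_params()] for the N <-> S fold switch.
#' @param step_NU [thermal_step_params()] for N <-> U unfolding.
#' @param assoc_H [assoc_step_params()] for 6 S <-> H (stoichiometry 6).
#' @param assoc_H2 [assoc_step_params()] for 2 H <-> H2 (stoichiometry 2).
#' @param bind_P [assoc_step_params()] for N + P <-> NP peptide binding
#'   (stoichiometry interpreted as bimolecular; `n` is ignored).
#' @return An object of class `linkage_params`.
#' @examples
#' lp <- linkage_params(
#'   step_NS  = thermal_step_params(359, 100),
#'   step_NU  = thermal_step_params(337, 300),
#'   assoc_H  = assoc_step_params(-170, n = 6),
#'   assoc_H2 = assoc_step_params(-23, n = 2)
#' )
#' @export
linkage_params <- function(step_NS = NULL, step_NU = NULL,
                           assoc_H = NULL, assoc_H2 = NULL,
                           bind_P = NULL) {
  chk <- function(x, cls, nm) {
    if (!is.null(x) && !inherits(x, cls))
      abort(sprintf("`%s` must be NULL or a %s object.", nm, cls))
  }
  chk(step_NS, "thermal_step_params", "step_NS")
  chk(step_NU, "thermal_step_params", "step_NU")
  chk(assoc_H, "assoc_step_params", "assoc_H")
  chk(assoc_H2, "assoc_step_params", "assoc_H2")
  chk(bind_P, "assoc_step_params", "bind_P")
  if (!is.null(assoc_H) && assoc_H$n != 6)
    abort("`assoc_H` stoichiometry is fixed at 6.")
  if (!is.null(assoc_H2) && assoc_H2$n != 2)
    abort("`assoc_H2` stoichiometry is fixed at 2.")
  structure(list(step_NS = step_NS, step_NU = step_NU,
                 assoc_H = assoc_H, assoc_H2 = assoc_H2, bind_P = bind_P),
            class = "linkage_params")
}

#' Experimental conditions for the linkage model
#'
#' Builds a tibble of conditions; vector arguments are recycled to a
#' common length, so condition grids chain naturally into
#' [solve_species()].
#'
#' @param C_tot Total protein concentration (monomer equivalents), M; > 0.
#' @param T Temperature, K; > 0.
#' @param P_tot Total effector-peptide concentration, M; >= 0. Default 0.
#' @return A tibble with columns `C_tot`, `T`, `P_tot`.
#' @examples
#' conditions(C_tot = 600e-6, T = seq(290, 370, by = 5))
#' @export
conditions <- function(C_tot, T = 298, P_tot = 0) {
  if (any(C_tot <= 0)) abort("`C_tot` must be positive.")
  if (any(T <= 0)) abort("`T` must be positive (kelvin).")
  if (any(P_tot < 0)) abort("`P_tot` must be nonnegative.")
  tibble(C_tot = C_tot, T = T, P_tot = P_tot)
}

# ---- JSON serialisation ----------------------------------------------------

.params_to_list <- function(x) {
  if (is.null(x)) return(NULL)
  out <- unclass(x)
  if (!is.null(out$baselines)) out$baselines <- as.list(out$baselines)
  out$.class <- class(x)[1]
  out
}

.params_from_list <- function(x) {
  if (is.null(x)) return(NULL)
  cls <- x$.class
  x$.class <- NULL
  switch(cls,
    two_state_chem_params = two_state_chem_params(
      x$dG0, x$m_eq, baselines = unlist(x$baselines)),
    chevron_params = chevron_params(x$kf0, x$ku0, x$mf, x$mu),
    thermal_step_params = thermal_step_params(x$Tm, x$dHm, x$dCp),
    assoc_step_params = assoc_step_params(x$dG_ref, x$dH_ref, x$dCp,
                                          x$T_ref, x$n),
    linkage_params = linkage_params(
      step_NS = .params_from_list(x$step_NS),
      step_NU = .params_from_list(x$step_NU),
      assoc_H = .params_from_list(x$assoc_H),
      assoc_H2 = .params_from_list(x$assoc_H2),
      bind_P = .params_from_list(x$bind_P)),
    abort(sprintf("Unknown parameter class in config: %s", cls))
  )
}

#' Write / read model parameters as flat JSON configs
#'
#' All parameter containers in the package round-trip through JSON, so
#' that the exact configuration behind a synthetic dataset or a fit can
#' be stored alongside its results.
#'
#' @param params A parameter object (`two_state_chem_params`,
#'   `chevron_params`, `thermal_step_params`, `assoc_step_params` or
#'   `linkage_params`).
#' @param path File path.
#' @return `write_params()` returns `path` invisibly; `read_params()`
#'   returns the reconstructed parameter object.
#' @export
write_params <- function(params, path) {
  x <- if (inherits(params, "linkage_params")) {
    out <- lapply(unclass(params), .params_to_list)
    out$.class <- "linkage_params"
    out
  } else {
    .params_to_list(params)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(x$.class, "linkage_params")) {
    x$.class <- NULL
    return(linkage_params(
      step_NS = .params_from_list(x$step_NS),
      step_NU = .params_from_list(x$step_NU),
      assoc_H = .params_from_list(x$assoc_H),
      assoc_H2 = .params_from_list(x$assoc_H2),
      bind_P = .params_from_list(x$bind_P)))
  }
  .params_from_list(x)
}

# ---- printed-parameter fixtures -------------------------------------------

#' Built-in parameter fixtures
#'
#' Returns parameter sets shipped with the package. `"ci2_wt"` and
#' `"ci2_eng"` carry the published two-state equilibrium and chevron
#' parameters of wild-type CI2 and its fold-switch-engineered variant
#' (chemical denaturation at 298 K in GdmCl). `"ci2_eng_linkage"` and
#' `"ci2_158_linkage"` are illustrative five-species linkage parameter
#' sets calibrated to reproduce the qualitative behaviour of the
#' engineered variants (concentration-dependent destabilisation, DSC
#' peak splitting, peptide rescue); their step energies are package
#' defaults, not measured values.
#'
#' @param name One of `"ci2_wt"`, `"ci2_eng"`, `"ci2_eng_linkage"`,
#'   `"ci2_158_linkage"`.
#' @return For the two-state fixtures, a list with elements `chem`
#'   ([two_state_chem_params()]) and `chevron` ([chevron_params()]); for
#'   the linkage fixtures, a [linkage_params()] object.
#' @examples
#' wt <- ci2_fixture("ci2_wt")
#' wt$chem$Cm
#' @export
ci2_fixture <- function(name = c("ci2_wt", "ci2_eng",
                                 "ci2_eng_linkage", "ci2_158_linkage")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".json"), package = "allofold",
                      mustWork = TRUE)
  if (grepl("linkage", name)) return(read_params(path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(
    variant = x$variant,
    chem = two_state_chem_params(x$chem$dG0, x$chem$dG0 / x$chem$Cm),
    chevron = chevron_params(x$chevron$kf0, x$chevron$ku0,
                             x$chevron$mf, x$chevron$mu)
  )
}
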