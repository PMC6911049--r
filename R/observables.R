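#' Per-species optical signal basis
#'
#' Signal coefficients used to synthesise melt curves: each species
#' contributes `a + b*T` weighted by its per-monomer fraction. Species
#' sharing a photophysical state may share coefficients. The default is
#' the tryptophan-fluorescence basis in which the native monomer and its
#' peptide-bound form are bright and all other species (switched,
#' unfolded, assembled) are dark — the first transition erases the
#' whole signal.
#'
#' @param intercepts Named numeric vector over species
#'   `N, NP, S, U, H, H2`: signal intercepts (signal units).
#' @param slopes Same shape: temperature slopes (signal units per K).
#' @return An object of class `signal_basis`.
#' @examples
#' signal_basis()  # native-bright fluorescence default
#' @export
signal_basis <- function(
    intercepts = c(N = 1, NP = 1, S = 0, U = 0, H = 0, H2 = 0),
    slopes = c(N = 0, NP = 0, S = 0, U = 0, H = 0, H2 = 0)) {
  sp <- c("N", "NP", "S", "U", "H", "H2")
  if (!all(sp %in% names(intercepts)) || !all(sp %in% names(slopes)))
    abort("`intercepts` and `slopes` must name all of N, NP, S, U, H, H2.")
  structure(list(intercepts = intercepts[sp], slopes = slopes[sp]),
            class = "signal_basis")
}

.basis_signal <- function(state, basis) {
  a <- basis$intercepts; b <- basis$slopes
  T <- state$T
  state$frac_N  * (a[["N"]]  + b[["N"]]  * T) +
  state$frac_NP * (a[["NP"]] + b[["NP"]] * T) +
  state$frac_S  * (a[["S"]]  + b[["S"]]  * T) +
  state$frac_U  * (a[["U"]]  + b[["U"]]  * T) +
  state$frac_H  * (a[["H"]]  + b[["H"]]  * T) +
  state$frac_H2 * (a[["H2"]] + b[["H2"]] * T)
}

#' Thermal melt curve of the linkage model
#'
#' Population-weighted signal
#' \eqn{y(T) = \sum_i f_i(T) (a_i + b_i T)} over the six species. With
#' every species sharing one baseline the curve is that baseline
#' exactly; with assembly disabled and an N/U basis it is the familiar
#' two-state sigmoid.
#'
#' @param params A [linkage_params()] object.
#' @param basis A [signal_basis()].
#' @param C_tot Total protein concentration, M.
#' @param P_tot Total peptide concentration, M.
#' @param T_grid Temperature grid, K.
#' @return A [curve_table()] (kind `"melt"`) with `x = T`.
#' @examples
#' lp <- ci2_fixture("ci2_eng_linkage")
#' melt_curve(lp, signal_basis(), C_tot = 600e-6,
#'            T_grid = seq(280, 370, 1))
#' @export
melt_curve <- function(params, basis = signal_basis(), C_tot, P_tot = 0,
                       T_grid = seq(273, 393, by = 1)) {
  stopifnot(inherits(basis, "signal_basis"))
  st <- solve_species(params, conditions(C_tot = C_tot, T = T_grid,
                                         P_tot = P_tot))
  curve_table(x = T_grid, y = .basis_signal(st, basis), sigma = 0,
              kind = "melt", C_tot = C_tot, T = T_grid, P_tot = P_tot,
              series = format(C_tot, digits = 4))
}

.dH_thermal <- function(step, T) {
  if (is.null(step)) return(rep(0, length(T)))
  step$dHm + step$dCp * (T - step$Tm)
}

.dH_assoc <- function(step, T) {
  if (is.null(step)) return(rep(0, length(T)))
  step$dH_ref + step$dCp * (T - step$T_ref)
}

#' Excess molar enthalpy per mole of monomer
#'
#' Population-weighted enthalpy referenced to the native monomer:
#' \deqn{h(T) = f_S \Delta H_{NS} + f_U \Delta H_{NU}
#'  + f_H [\Delta H_{NS} + \Delta H_H/6]
#'  + f_{H2} [\Delta H_{NS} + \Delta H_H/6 + \Delta H_{H2}/12]
#'  + f_{NP} \Delta H_P}
#' with \eqn{\Delta H_{step}(T) = \Delta H_m + \Delta C_p (T - T_m)}
#' (conformational) or \eqn{\Delta H_{ref} + \Delta C_p (T - T_{ref})}
#' (association/binding). Its temperature derivative is the DSC excess
#' heat capacity.
#'
#' @param params A [linkage_params()] object.
#' @param cond A [conditions()] tibble.
#' @return Excess enthalpy, kJ/mol monomer (one value per condition row).
#' @export
excess_enthalpy <- function(params, cond) {
  st <- solve_species(params, cond)
  T <- cond$T
  dH_NS <- .dH_thermal(params$step_NS, T)
  dH_NU <- .dH_thermal(params$step_NU, T)
  dH_H  <- .dH_assoc(params$assoc_H, T)
  dH_H2 <- .dH_assoc(params$assoc_H2, T)
  dH_P  <- .dH_assoc(params$bind_P, T)
  st$frac_S * dH_NS + st$frac_U * dH_NU +
    st$frac_H  * (dH_NS + dH_H / 6) +
    st$frac_H2 * (dH_NS + dH_H / 6 + dH_H2 / 12) +
    st$frac_NP * dH_P
}

# prominence of interior local maxima (classic topographic definition)
.find_peaks <- function(x, y, min_prominence) {
  n <- length(y)
  if (n < 3L) return(numeric(0))
  is_max <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  keep <- numeric(0)
  for (i in is_max) {
    left <- y[1:i]
    higher_l <- which(left > y[i])
    base_l <- if (length(higher_l)) min(y[max(higher_l):i]) else min(left)
    right <- y[i:n]
    higher_r <- which(right > y[i])
    base_r <- if (length(higher_r)) min(y[i:(i - 1 + min(higher_r))]) else min(right)
    prom <- y[i] - max(base_l, base_r)
    if (prom >= min_prominence) keep <- c(keep, i)
  }
  x[keep]
}

#' DSC thermogram: excess heat capacity with peak extraction
#'
#' Central-difference temperature derivative of [excess_enthalpy()]
#' (step `dT`, default 0.02 K), with peaks detected as interior local
#' maxima whose prominence exceeds `prominence` times the trace
#' maximum. For a pure two-state step with `dCp = 0` the peak sits at
#' `Tm` (within `dT`) with height \eqn{\Delta H_m^2/(4 R T_m^2)}.
#'
#' @inheritParams melt_curve
#' @param dT Differentiation half-step, K (> 0; grid spacing must be at
#'   least `2 * dT`).
#' @param prominence Peak-prominence threshold as a fraction of the
#'   trace maximum. Default 0.01.
#' @return An object of class `dsc_trace`: list with `trace` (tibble of
#'   `T_K`, `Cp_excess_kJ_per_mol_K`), sorted `peaks` (K), and the
#'   conditions.
#' @examples
#' lp <- ci2_fixture("ci2_eng_linkage")
#' dsc_thermogram(lp, C_tot = 600e-6, T_grid = seq(280, 375, 0.25))
#' @export
dsc_thermogram <- function(params, C_tot, P_tot = 0,
                           T_grid = seq(273, 393, by = 0.25),
                           dT = 0.02, prominence = 0.01) {
  if (dT <= 0) abort("`dT` must be positive.")
  sp <- min(diff(T_grid))
  if (sp < 2 * dT) abort("T_grid spacing must be at least 2*dT.")
  h_hi <- excess_enthalpy(params, conditions(C_tot, T_grid + dT, P_tot))
  h_lo <- excess_enthalpy(params, conditions(C_tot, T_grid - dT, P_tot))
  cp <- (h_hi - h_lo) / (2 * dT)
  peaks <- if (max(cp) > 0) {
    sort(.find_peaks(T_grid, cp, prominence * max(cp)))
  } else numeric(0)
  # resolution check: a transition narrower than ~4 grid steps is
  # under-sampled for peak picking
  for (pk in peaks) {
    i <- which.min(abs(T_grid - pk))
    half <- cp[i] / 2
    w <- which(cp > half & abs(T_grid - pk) < 20)
    if (sum(w > i - 2 & w < i + 2) == length(w) && length(w) < 4)
      warn("DSC grid is coarse relative to a transition width; refine T_grid.")
  }
  structure(list(
    trace = tibble(T_K = T_grid, Cp_excess_kJ_per_mol_K = cp),
    peaks = peaks, C_tot = C_tot, P_tot = P_tot, dT = dT,
    prominence = prominence),
    class = "dsc_trace")
}

#' @export
print.dsc_trace <- function(x, ...) {
  cat(sprintf("<dsc_trace: %d points, C_tot = %.3g M, %d peak(s)%s>\n",
              nrow(x$trace), x$C_tot, length(x$peaks),
              if (length(x$peaks))
                paste0(" at ", paste(sprintf("%.1f K", x$peaks),
                                     collapse = ", "))
              else ""))
  invisible(x)
}

#' Plot a DSC trace
#'
#' @param object A `dsc_trace` from [dsc_thermogram()].
#' @param ... Unused.
#' @return A ggplot object with detected peaks marked.
#' @export
autoplot.dsc_trace <- function(object, ...) {
  p <- ggplot2::ggplot(object$trace,
                       ggplot2::aes(x = .data$T_K,
                                    y = .data$Cp_excess_kJ_per_mol_K)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Temperature (K)",
                  y = expression(C[p]^{exc} ~ "(kJ" ~ mol^{-1} ~ K^{-1} * ")")) +
    ggplot2::theme_minimal()
  if (length(object$peaks))
    p <- p + ggplot2::geom_vline(xintercept = object$peaks,
                                 linetype = "dashed", colour = "red3")
  p
}

#' Species distribution (monomer / hexamer / dodecamer)
#'
#' Pools the four monomeric species into a single monomer row M and
#' reports per-monomer fractions and molar masses of M, H and H2 —
#' the quantities resolved by size-exclusion chromatography with
#' light-scattering detection or by sedimentation velocity.
#'
#' @inheritParams excess_enthalpy
#' @param monomer_mass Monomer molar mass, Da (e.g. from
#'   [average_mass()]).
#' @return A tibble with columns `C_tot`, `T`, `P_tot`, `species`
#'   (`"M"`, `"H"`, `"H2"`), `fraction` and `mass_da` (1x, 6x, 12x the
#'   monomer mass).
#' @examples
#' lp <- ci2_fixture("ci2_eng_linkage")
#' species_distribution(lp, conditions(C_tot = 1e-3, T = 308),
#'                      monomer_mass = 7332.5)
#' @export
species_distribution <- function(params, cond, monomer_mass) {
  st <- solve_species(params, cond)
  base <- st[, c("C_tot", "T", "P_tot")]
  bind_rows(
    mutate(base, species = "M", fraction = monomer_fraction(st),
           mass_da = monomer_mass),
    mutate(base, species = "H", fraction = st$frac_H,
           mass_da = oligomer_mass(monomer_mass, 6)),
    mutate(base, species = "H2", fraction = st$frac_H2,
           mass_da = oligomer_mass(monomer_mass, 12))
  ) |>
    arrange(.data$C_tot, .data$T, .data$P_tot)
}

#' Plot species fractions along a condition axis
#'
#' Stacked-area view of the per-monomer fractions of all six species
#' from a `species_state` trajectory (e.g. along a temperature grid).
#'
#' @param object A `species_state` from [solve_species()].
#' @param x Name of the condition column to use as abscissa
#'   (`"T"`, `"C_tot"` or `"P_tot"`). Default `"T"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.species_state <- function(object, x = "T", ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c(x, grep("^frac_", names(object), value = TRUE))],
    cols = tidyr::starts_with("frac_"),
    names_to = "species", values_to = "fraction",
    names_prefix = "frac_")
  long$species <- factor(long$species,
                         levels = c("N", "NP", "S", "U", "H", "H2"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[x]], y = .data$fraction,
                                     fill = .data$species)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = x, y = "monomer fraction") +
    ggplot2::theme_minimal()
}
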