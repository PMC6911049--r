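# Five-species linkage model: N, NP, S, U monomers; hexamer H = 6 S;
# dodecamer H2 = 2 H. Only S assembles; the effector peptide binds only N.
# With x = [N]:
#   [S]  = K_S x                [U]  = K_U x
#   [H]  = K_H (K_S x)^6        [H2] = K_H2 K_H^2 (K_S x)^12
#   [NP] = K_P x P_free,  P_free = P_tot / (1 + K_P x)
# Monomer mass balance total(x) = C_tot is strictly increasing in x, so the
# root is unique and bracketed in (0, C_tot]; it is found by bisection on
# ln x with high-order terms evaluated in log space.

.lnK_step <- function(step, T, thermal = FALSE) {
  if (is.null(step)) return(rep(-Inf, length(T)))
  dG <- if (thermal) dg_thermal(step, T) else dg_assoc(step, T)
  -dG / (.R * T)
}

.lnK_all <- function(params, T) {
  list(
    lnK_S  = .lnK_step(params$step_NS, T, thermal = TRUE),
    lnK_U  = .lnK_step(params$step_NU, T, thermal = TRUE),
    lnK_H  = .lnK_step(params$assoc_H, T),
    lnK_H2 = .lnK_step(params$assoc_H2, T),
    lnK_P  = .lnK_step(params$bind_P, T)
  )
}

#' Equilibrium constants of the five-species scheme at temperature T
#'
#' Each constant is \eqn{K = \exp(-\Delta G(T)/(RT))}, with the
#' conformational steps (N-S, N-U) evaluated through the
#' Gibbs-Helmholtz form and the association/binding steps through their
#' \eqn{\Delta H/\Delta S/\Delta C_p} form, all computed in log space.
#' Disabled (`NULL`) steps give K = 0.
#'
#' @param params A [linkage_params()] object.
#' @param T Temperature, K (vectorised).
#' @return A tibble with columns `T`, `K_S`, `K_U` (dimensionless),
#'   `K_H` (1/M^5), `K_H2` (1/M), `K_P` (1/M) and their logarithms
#'   `lnK_*`.
#' @examples
#' lp <- ci2_fixture("ci2_eng_linkage")
#' equilibrium_constants(lp, T = c(298, 337))
#' @export
equilibrium_constants <- function(params, T) {
  stopifnot(inherits(params, "linkage_params"))
  if (any(T <= 0)) abort("Temperatures must be positive (kelvin).")
  ln <- .lnK_all(params, T)
  tibble(T = T,
         K_S = exp(ln$lnK_S), K_U = exp(ln$lnK_U), K_H = exp(ln$lnK_H),
         K_H2 = exp(ln$lnK_H2), K_P = exp(ln$lnK_P),
         lnK_S = ln$lnK_S, lnK_U = ln$lnK_U, lnK_H = ln$lnK_H,
         lnK_H2 = ln$lnK_H2, lnK_P = ln$lnK_P)
}

# total monomer equivalents at ln x (all arguments vectors of equal length)
.total_monomer <- function(lnx, lnK_S, lnK_U, lnK_H, lnK_H2, lnK_P,
                           P_tot) {
  x <- exp(lnx)
  safe_exp <- function(l) exp(pmin(l, 700))  # overflow -> Inf via 700 cap
  KPx <- safe_exp(lnK_P + lnx)
  mono <- x + safe_exp(lnK_S + lnx) + safe_exp(lnK_U + lnx) +
    KPx * P_tot / (1 + KPx)
  lS6 <- 6 * (lnK_S + lnx)
  mono + 6 * safe_exp(lnK_H + lS6) +
    12 * safe_exp(lnK_H2 + 2 * lnK_H + 2 * lS6)
}

# vectorised bisection for ln [N]; bracket (C_tot*1e-14, C_tot]
.solve_lnx <- function(lnK_S, lnK_U, lnK_H, lnK_H2, lnK_P,
                       C_tot, P_tot, max_iter = 300L, rel_tol = 1e-12) {
  hi <- log(C_tot)
  lo <- hi - log(1e14)
  f_lo <- .total_monomer(lo, lnK_S, lnK_U, lnK_H, lnK_H2, lnK_P, P_tot)
  if (any(f_lo > C_tot))
    abort(paste0("Mass-balance bracket failure: total monomer at the lower ",
                 "bracket already exceeds C_tot (pathological equilibrium ",
                 "constants). Bracket: [C_tot*1e-14, C_tot]."))
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    f_mid <- .total_monomer(mid, lnK_S, lnK_U, lnK_H, lnK_H2, lnK_P, P_tot)
    up <- f_mid <= C_tot
    lo <- ifelse(up, mid, lo)
    hi <- ifelse(up, hi, mid)
    if (max(hi - lo) < rel_tol) break
  }
  (lo + hi) / 2
}

.species_from_lnx <- function(lnx, lnK_S, lnK_U, lnK_H, lnK_H2, lnK_P,
                              C_tot, T, P_tot) {
  x <- exp(lnx)
  conc_S <- exp(lnK_S + lnx)
  conc_U <- exp(lnK_U + lnx)
  conc_H <- exp(lnK_H + 6 * (lnK_S + lnx))
  conc_H2 <- exp(lnK_H2 + 2 * lnK_H + 12 * (lnK_S + lnx))
  KP <- exp(lnK_P)
  conc_P_free <- P_tot / (1 + KP * x)
  conc_NP <- KP * x * conc_P_free
  out <- tibble(
    C_tot = C_tot, T = T, P_tot = P_tot,
    conc_N = x, conc_NP = conc_NP, conc_S = conc_S, conc_U = conc_U,
    conc_H = conc_H, conc_H2 = conc_H2, conc_P_free = conc_P_free,
    frac_N = x / C_tot, frac_NP = conc_NP / C_tot,
    frac_S = conc_S / C_tot, frac_U = conc_U / C_tot,
    frac_H = 6 * conc_H / C_tot, frac_H2 = 12 * conc_H2 / C_tot)
  class(out) <- c("species_state", class(out))
  out
}

#' Solve the five-species equilibrium at given conditions
#'
#' Computes the unique equilibrium composition of the linkage scheme at
#' each condition row by bisection on \eqn{\ln [N]} of the monomer
#' mass-balance equation (strictly increasing, so the root is unique and
#' bracketed in \eqn{(0, C_{tot}]}); high-order assembly terms are
#' evaluated in log space. Peptide mass balance
#' \eqn{[P] + [NP] = P_{tot}} holds by construction.
#'
#' @param params A [linkage_params()] object.
#' @param cond A tibble of conditions as produced by [conditions()]
#'   (columns `C_tot`, `T`, `P_tot`).
#' @param max_iter Bisection iteration cap (default 300).
#' @param rel_tol Relative tolerance on `[N]` (default 1e-12).
#' @return A `species_state` tibble: the condition columns plus molar
#'   concentrations `conc_N`, `conc_NP`, `conc_S`, `conc_U`, `conc_H`,
#'   `conc_H2`, `conc_P_free` and per-monomer fractions `frac_*`
#'   (H counts 6 monomers, H2 counts 12; fractions sum to 1).
#' @examples
#' lp <- ci2_fixture("ci2_eng_linkage")
#' st <- solve_species(lp, conditions(C_tot = 600e-6, T = seq(290, 370, 2)))
#' head(st)
#' @export
solve_species <- function(params, cond, max_iter = 300L, rel_tol = 1e-12) {
  stopifnot(inherits(params, "linkage_params"))
  if (!all(c("C_tot", "T", "P_tot") %in% names(cond)))
    abort("`cond` must have columns C_tot, T, P_tot (see conditions()).")
  ln <- .lnK_all(params, cond$T)
  lnx <- .solve_lnx(ln$lnK_S, ln$lnK_U, ln$lnK_H, ln$lnK_H2, ln$lnK_P,
                    cond$C_tot, cond$P_tot, max_iter, rel_tol)
  .species_from_lnx(lnx, ln$lnK_S, ln$lnK_U, ln$lnK_H, ln$lnK_H2, ln$lnK_P,
                    cond$C_tot, cond$T, cond$P_tot)
}

#' Solve the five-species equilibrium from explicit equilibrium constants
#'
#' Lower-level interface taking the five constants directly (all on the
#' 1 M standard state); useful for analytical checks and for conditions
#' where the constants are known rather than derived from step
#' thermodynamics. Arguments are recycled to a common length.
#'
#' @param K_S,K_U Conformational constants (dimensionless, >= 0).
#' @param K_H Hexamerisation constant, 1/M^5.
#' @param K_H2 Dodecamerisation constant, 1/M.
#' @param K_P Peptide-binding constant, 1/M.
#' @param C_tot,P_tot Total protein / peptide concentrations, M.
#' @param T Temperature metadata, K (not used in the solve).
#' @inheritParams solve_species
#' @return A `species_state` tibble (see [solve_species()]).
#' @examples
#' solve_species_k(K_S = 1, K_U = 0, K_H = 0, K_H2 = 0, K_P = 0,
#'                 C_tot = 1e-4)
#' @export
solve_species_k <- function(K_S, K_U, K_H, K_H2, K_P, C_tot, P_tot = 0,
                            T = 298, max_iter = 300L, rel_tol = 1e-12) {
  n <- max(lengths(list(K_S, K_U, K_H, K_H2, K_P, C_tot, P_tot, T)))
  r <- function(v) rep_len(v, n)
  if (any(c(K_S, K_U, K_H, K_H2, K_P) < 0))
    abort("Equilibrium constants must be nonnegative.")
  if (any(C_tot <= 0)) abort("`C_tot` must be positive.")
  lnx <- .solve_lnx(log(r(K_S)), log(r(K_U)), log(r(K_H)), log(r(K_H2)),
                    log(r(K_P)), r(C_tot), r(P_tot), max_iter, rel_tol)
  .species_from_lnx(lnx, log(r(K_S)), log(r(K_U)), log(r(K_H)),
                    log(r(K_H2)), log(r(K_P)), r(C_tot), r(T), r(P_tot))
}

#' Monomeric fraction of a species state
#'
#' Sum of the per-monomer fractions of the four monomeric species
#' (N, NP, S, U); complements the assembled fraction (H + H2) to 1.
#'
#' @param state A `species_state` tibble from [solve_species()].
#' @return Numeric vector of monomer fractions in \[0, 1\].
#' @export
monomer_fraction <- function(state) {
  stopifnot(inherits(state, "species_state"))
  state$frac_N + state$frac_NP + state$frac_S + state$frac_U
}

#' Assembled fraction of a species state
#'
#' @inheritParams monomer_fraction
#' @return Numeric vector: `frac_H + frac_H2`.
#' @export
assembled_fraction <- function(state) {
  stopifnot(inherits(state, "species_state"))
  state$frac_H + state$frac_H2
}

#' Apparent melting midpoint of the native fold
#'
#' Temperature at which the native-like population
#' (`frac_N + frac_NP`) crosses 0.5, linearly interpolated on the
#' supplied grid. With assembly disabled this reduces to the two-state
#' midpoint of the unfolding step. When the population never crosses
#' 0.5 within the grid there is no transition to report and `NA` is
#' returned (with a warning) rather than a number.
#'
#' @param params A [linkage_params()] object.
#' @param C_tot Total protein concentration, M.
#' @param P_tot Total peptide concentration, M. Default 0.
#' @param T_grid Monotone increasing temperature grid spanning the
#'   transition, K.
#' @return Midpoint temperature (K), or `NA_real_` if no crossing.
#' @examples
#' lp <- ci2_fixture("ci2_eng_linkage")
#' apparent_native_midpoint(lp, C_tot = 600e-6, T_grid = seq(280, 370, 0.5))
#' @export
apparent_native_midpoint <- function(params, C_tot, P_tot = 0,
                                     T_grid = seq(273, 393, by = 0.5)) {
  if (is.unsorted(T_grid, strictly = TRUE))
    abort("`T_grid` must be strictly increasing.")
  st <- solve_species(params, conditions(C_tot = C_tot, T = T_grid,
                                         P_tot = P_tot))
  f <- st$frac_N + st$frac_NP
  s <- f - 0.5
  cross <- which(s[-length(s)] * s[-1] <= 0 & (s[-length(s)] != s[-1]))
  if (length(cross) == 0L) {
    warn("Native population never crosses 0.5 on the grid: no transition.")
    return(NA_real_)
  }
  i <- cross[1]
  T_grid[i] + (0.5 - f[i]) * (T_grid[i + 1] - T_grid[i]) / (f[i + 1] - f[i])
}

#' Peptide rescue curve: monomer fraction vs total peptide
#'
#' Titration of the assembly with the allosteric effector peptide at
#' fixed protein concentration and temperature. Binding of the peptide
#' to the native monomer drains the switched conformation and dissolves
#' the assemblies, so the monomer fraction is monotone nondecreasing in
#' `P_tot` and tends to 1 at saturating peptide.
#'
#' @inheritParams apparent_native_midpoint
#' @param T Temperature, K.
#' @param P_grid Nonnegative, sorted total peptide concentrations, M.
#' @return A [curve_table()] (kind `"titration"`) with `x = P_tot` and
#'   `y` the monomer fraction.
#' @examples
#' lp <- ci2_fixture("ci2_158_linkage")
#' peptide_rescue_curve(lp, C_tot = 80e-6, T = 298,
#'                      P_grid = seq(0, 4e-3, length.out = 9))
#' @export
peptide_rescue_curve <- function(params, C_tot, T = 298,
                                 P_grid = seq(0, 1e-2, length.out = 50)) {
  if (any(P_grid < 0) || is.unsorted(P_grid))
    abort("`P_grid` must be nonnegative and sorted.")
  st <- solve_species(params, conditions(C_tot = C_tot, T = T,
                                         P_tot = P_grid))
  curve_table(x = P_grid, y = monomer_fraction(st), sigma = 0,
              kind = "titration", C_tot = C_tot, T = T, P_tot = P_grid)
}

#' Peptide concentration at half rescue
#'
#' Total peptide concentration at which the monomer fraction crosses
#' halfway between its unrescued value and 1, linearly interpolated.
#'
#' @param curve A titration [curve_table()] from
#'   [peptide_rescue_curve()].
#' @return Peptide concentration (M), or `NA_real_` if the curve never
#'   reaches the halfway point.
#' @export
half_rescue_point <- function(curve) {
  y0 <- curve$y[1]
  target <- (y0 + 1) / 2
  s <- curve$y - target
  cross <- which(s[-length(s)] * s[-1] <= 0 & (s[-length(s)] != s[-1]))
  if (length(cross) == 0L) return(NA_real_)
  i <- cross[1]
  curve$x[i] + (target - curve$y[i]) * (curve$x[i + 1] - curve$x[i]) /
    (curve$y[i + 1] - curve$y[i])
}
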