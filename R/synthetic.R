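# Seeded generators for every dataset shape the fitting layer consumes.
# Noise model: additive homoscedastic Gaussian, parameterised as a
# fraction of the noise-free signal range (or absolute, e.g. for
# log-rates). Each dataset draws from its own pseudorandom stream,
# derived from the master seed by stable hashing of the generator
# configuration so replicate suites never collide.

#' Noise specification for synthetic data
#'
#' @param sd Standard deviation: a fraction of the noise-free signal
#'   range when `relative = TRUE` (default), otherwise in signal units.
#' @param seed Integer master seed; identical seed and configuration
#'   reproduce the dataset bit for bit.
#' @param relative Interpret `sd` as fraction of signal range?
#' @return An object of class `noise_spec`.
#' @examples
#' noise_spec(sd = 0.02, seed = 1)
#' @export
noise_spec <- function(sd = 0.02, seed = 1L, relative = TRUE) {
  if (sd < 0) abort("`sd` must be nonnegative.")
  structure(list(sd = sd, seed = as.integer(seed), relative = relative),
            class = "noise_spec")
}

# stable 31-bit string hash (polynomial rolling hash in double precision)
.hash_string <- function(s) {
  v <- utf8ToInt(s)
  h <- 0
  for (i in seq_along(v)) h <- (h * 31 + v[i]) %% 2147483629
  h
}

.stream_seed <- function(noise, config) {
  (abs(noise$seed) %% 65521 * 32749 + .hash_string(config)) %% 2147483629
}

.sd_abs <- function(noise, y0) {
  if (!noise$relative) return(noise$sd)
  rng <- diff(range(y0))
  if (rng == 0) noise$sd else noise$sd * rng
}

.add_noise <- function(y0, noise, config) {
  sd_abs <- .sd_abs(noise, y0)
  y <- if (noise$sd == 0) y0 else
    withr::with_seed(.stream_seed(noise, config),
                     y0 + rnorm(length(y0), sd = sd_abs))
  list(y = y, sd = sd_abs)
}

#' Generate a synthetic chemical-denaturation curve
#'
#' Two-state baseline-weighted signal from [signal_chem()] plus
#' Gaussian noise.
#'
#' @param params A [two_state_chem_params()] object.
#' @param D_grid Sorted denaturant grid, M; at least 8 points, spanning
#'   the midpoint `Cm` (a warning is issued otherwise).
#' @param T Temperature, K.
#' @param noise A [noise_spec()].
#' @return A [curve_table()] (kind `"chem_denaturation"`) carrying the
#'   generator seed and configuration as attributes.
#' @examples
#' wt <- ci2_fixture("ci2_wt")$chem
#' gen_chem_denaturation(wt, seq(0, 7, length.out = 25),
#'                       noise = noise_spec(0.02, seed = 7))
#' @export
gen_chem_denaturation <- function(params, D_grid = seq(0, 7, length.out = 25),
                                  T = 298, noise = noise_spec()) {
  if (is.unsorted(D_grid) || length(D_grid) < 8L)
    abort("`D_grid` must be sorted with at least 8 points.")
  if (params$Cm < min(D_grid) || params$Cm > max(D_grid))
    warn("`D_grid` does not span the transition midpoint Cm.")
  y0 <- signal_chem(params, D_grid, T)
  cfg <- paste("chem", signif(params$dG0, 10), signif(params$m_eq, 10),
               length(D_grid), signif(range(D_grid), 10), T,
               signif(noise$sd, 10), sep = ",", collapse = ";")
  ns <- .add_noise(y0, noise, cfg)
  curve_table(x = D_grid, y = ns$y, sigma = ns$sd,
              kind = "chem_denaturation", T = T,
              seed = noise$seed, config = cfg)
}

#' Generate a synthetic chevron dataset (log relaxation rates)
#'
#' Relaxation rates from [relaxation_rate()], with Gaussian noise added
#' on the log rate (rates are log-normal in practice); `y` holds
#' \eqn{\ln \lambda}, which is always finite, so the underlying rate is
#' always positive.
#'
#' @param params A [chevron_params()] object.
#' @param D_grid Sorted denaturant grid, M. Default: 20 points from 0 to
#'   1.6 times the chevron minimum, covering both arms.
#' @param T Temperature, K.
#' @param noise A [noise_spec()]; interpreted on the ln-rate scale
#'   (absolute), so `noise_spec(0.01, relative = FALSE)` is 1% noise on
#'   the rate.
#' @return A [curve_table()] (kind `"chevron"`) with `y` = ln(rate/s^-1).
#' @examples
#' wt <- ci2_fixture("ci2_wt")$chevron
#' gen_chevron(wt, noise = noise_spec(0.01, seed = 3, relative = FALSE))
#' @export
gen_chevron <- function(params, D_grid = NULL, T = 298,
                        noise = noise_spec(0.01, relative = FALSE)) {
  if (is.null(D_grid)) {
    Dmin <- chevron_minimum(params, T)
    if (is.na(Dmin)) abort("Cannot derive a default grid for a flat chevron.")
    D_grid <- seq(0, 1.6 * Dmin, length.out = 20)
  }
  if (is.unsorted(D_grid)) abort("`D_grid` must be sorted.")
  y0 <- log(relaxation_rate(params, D_grid, T))
  cfg <- paste("chevron", signif(params$kf0, 10), signif(params$ku0, 10),
               signif(params$mf, 10), signif(params$mu, 10),
               length(D_grid), signif(range(D_grid), 10), T,
               signif(noise$sd, 10), sep = ",", collapse = ";")
  ns <- .add_noise(y0, noise, cfg)
  curve_table(x = D_grid, y = ns$y, sigma = ns$sd, kind = "chevron", T = T,
              seed = noise$seed, config = cfg)
}

#' Generate synthetic thermal melt series
#'
#' One melt series per protein concentration, from [melt_curve()] plus
#' Gaussian noise (shared absolute sd computed from the pooled signal
#' range so series are comparable).
#'
#' @param params A [linkage_params()] object.
#' @param basis A [signal_basis()].
#' @param C_tot Vector of total protein concentrations, M (one series
#'   each).
#' @param T_grid Temperature grid, K.
#' @param P_tot Total peptide concentration, M.
#' @param noise A [noise_spec()].
#' @return A [curve_table()] (kind `"melt"`), `series` labelled by
#'   concentration.
#' @export
gen_thermal_melts <- function(params, basis = signal_basis(),
                              C_tot, T_grid = seq(280, 370, by = 1),
                              P_tot = 0, noise = noise_spec()) {
  curves <- lapply(C_tot, function(cc)
    melt_curve(params, basis, C_tot = cc, P_tot = P_tot, T_grid = T_grid))
  y0_all <- unlist(lapply(curves, function(cv) cv$y))
  cfg <- paste("melts", paste(signif(C_tot, 8), collapse = "/"),
               length(T_grid), signif(range(T_grid), 10),
               signif(P_tot, 8), signif(noise$sd, 10), sep = ",", collapse = ";")
  ns <- .add_noise(y0_all, noise, cfg)
  out <- bind_rows(curves)
  out$y <- ns$y
  out$sigma <- ns$sd
  attr(out, "seed") <- noise$seed
  attr(out, "config") <- cfg
  out
}

#' Generate synthetic DSC series
#'
#' One thermogram per protein concentration from [dsc_thermogram()],
#' with Gaussian noise on the excess heat capacity.
#'
#' @inheritParams gen_thermal_melts
#' @param dT Differentiation half-step for the thermogram, K.
#' @return A [curve_table()] (kind `"dsc"`; `y` in kJ/(mol K)).
#' @export
gen_dsc_series <- function(params, C_tot, T_grid = seq(280, 375, by = 0.25),
                           P_tot = 0, dT = 0.02, noise = noise_spec()) {
  traces <- lapply(C_tot, function(cc)
    dsc_thermogram(params, C_tot = cc, P_tot = P_tot, T_grid = T_grid,
                   dT = dT))
  y0_all <- unlist(lapply(traces, function(tr) tr$trace$Cp_excess_kJ_per_mol_K))
  cfg <- paste("dsc", paste(signif(C_tot, 8), collapse = "/"),
               length(T_grid), signif(range(T_grid), 10),
               signif(noise$sd, 10), sep = ",", collapse = ";")
  ns <- .add_noise(y0_all, noise, cfg)
  out <- bind_rows(lapply(seq_along(C_tot), function(i)
    curve_table(x = T_grid, y = traces[[i]]$trace$Cp_excess_kJ_per_mol_K,
                sigma = 0, kind = "dsc", C_tot = C_tot[i], T = T_grid,
                P_tot = P_tot, series = format(C_tot[i], digits = 4))))
  out$y <- ns$y
  out$sigma <- ns$sd
  attr(out, "seed") <- noise$seed
  attr(out, "config") <- cfg
  out
}

#' Generate a synthetic peptide-titration curve
#'
#' Monomer fraction vs total peptide from [peptide_rescue_curve()] plus
#' Gaussian noise.
#'
#' @inheritParams gen_thermal_melts
#' @param C_tot Total protein concentration, M (scalar).
#' @param T Temperature, K.
#' @param P_grid Sorted nonnegative peptide grid, M.
#' @return A [curve_table()] (kind `"titration"`).
#' @export
gen_peptide_titration <- function(params, C_tot, T = 298,
                                  P_grid = seq(0, 1e-2, length.out = 25),
                                  noise = noise_spec()) {
  cv <- peptide_rescue_curve(params, C_tot, T, P_grid)
  cfg <- paste("titration", signif(C_tot, 8), T, length(P_grid),
               signif(range(P_grid), 10), signif(noise$sd, 10), sep = ",", collapse = ";")
  ns <- .add_noise(cv$y, noise, cfg)
  cv$y <- ns$y
  cv$sigma <- ns$sd
  attr(cv, "seed") <- noise$seed
  attr(cv, "config") <- cfg
  cv
}

#' Generate a synthetic initial-velocity curve
#'
#' Michaelis-Menten velocities (with competitive inhibition folded into
#' the apparent Km) plus Gaussian noise.
#'
#' @param Vmax Maximal velocity.
#' @param Km True Michaelis constant, M.
#' @param I Inhibitor concentration, M (0 for the uninhibited assay).
#' @param Ki Inhibitor dissociation constant, M (ignored when `I = 0`).
#' @param S_grid Substrate grid, M; default 10 log-spaced points over
#'   10-1000 uM, the span of the reference chromogenic assay.
#' @param noise A [noise_spec()].
#' @return A [curve_table()] (kind `"velocity"`).
#' @export
gen_velocity_curves <- function(Vmax, Km, I = 0, Ki = 1,
                                S_grid = exp(seq(log(1e-5), log(1e-3),
                                                 length.out = 10)),
                                noise = noise_spec()) {
  Km_app <- if (I > 0) km_apparent(Km, I, Ki) else Km
  y0 <- initial_velocity(Vmax, Km_app, S_grid)
  cfg <- paste("velocity", signif(Vmax, 10), signif(Km_app, 10),
               length(S_grid), signif(range(S_grid), 10),
               signif(noise$sd, 10), sep = ",", collapse = ";")
  ns <- .add_noise(y0, noise, cfg)
  curve_table(x = S_grid, y = ns$y, sigma = ns$sd, kind = "velocity",
              seed = noise$seed, config = cfg)
}
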