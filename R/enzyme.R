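# Competitive-inhibition Michaelis-Menten analysis: classical (non
# tight-binding) treatment. Note the reference assay (53 nM enzyme,
# 200 nM inhibitor) sits near the tight-binding regime where the free
# inhibitor concentration is appreciably depleted; the classical
# expressions below are used regardless, as is conventional for
# apparent-Km reporting, and this validity caveat is documented.

#' Apparent Michaelis constant under competitive inhibition
#'
#' \eqn{K_m^{app} = K_m (1 + I/K_i)}; equals `Km` when `I = 0`.
#'
#' @param Km True Michaelis constant, M (> 0).
#' @param I Inhibitor concentration, M (>= 0).
#' @param Ki Inhibitor dissociation constant, M (> 0).
#' @return Apparent Michaelis constant, M.
#' @examples
#' km_apparent(Km = 40e-6, I = 200e-9, Ki = 50e-9)  # 200e-6
#' @export
km_apparent <- function(Km, I, Ki) {
  if (any(Km <= 0)) abort("`Km` must be positive.")
  if (any(I < 0)) abort("`I` must be nonnegative.")
  if (any(Ki <= 0)) abort("`Ki` must be positive.")
  Km * (1 + I / Ki)
}

#' Michaelis-Menten initial velocity
#'
#' \eqn{V_0 = V_{max} S / (K_m^{app} + S)}: hyperbolic in substrate,
#' half-maximal at `S = Km_app`.
#'
#' @param Vmax Maximal velocity (signal/s or M/s; > 0).
#' @param Km_app Apparent Michaelis constant, M (> 0).
#' @param S Substrate concentration, M (>= 0, vectorised).
#' @return Initial velocity, same units as `Vmax`.
#' @examples
#' initial_velocity(Vmax = 1, Km_app = 100e-6, S = 100e-6)  # Vmax/2
#' @export
initial_velocity <- function(Vmax, Km_app, S) {
  if (any(S < 0)) abort("`S` must be nonnegative.")
  Vmax * S / (Km_app + S)
}

#' Fit a Michaelis-Menten velocity curve
#'
#' Nonlinear least squares of \eqn{V_0 = V_{max} S/(K_m^{app} + S)} to
#' an initial-velocity dataset; recovers the generating parameters
#' exactly on noise-free data.
#'
#' @param curve A [curve_table()] (kind `"velocity"`) or any data frame
#'   with columns `x` (substrate, M) and `y` (initial velocity); at
#'   least 4 distinct substrate concentrations are required.
#' @return A `fold_fit` with estimates `Vmax` and `Km_app`.
#' @examples
#' s <- c(10, 30, 100, 300, 1000) * 1e-6
#' fit_mm(curve_table(s, initial_velocity(2, 1e-4, s), kind = "velocity"))
#' @export
fit_mm <- function(curve) {
  S <- curve$x; V <- curve$y
  if (length(unique(S)) < 4L)
    abort("At least 4 distinct substrate concentrations are required.")
  start <- list(Vmax = max(V) * 1.2, Km_app = S[which.min(abs(V - max(V) / 2))])
  fit <- minpack.lm::nlsLM(
    y ~ Vmax * x / (Km_app + x),
    data = data.frame(x = S, y = V), start = start,
    lower = c(Vmax = 0, Km_app = 0),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  .fold_fit_from_nls(fit, model = "michaelis_menten", data = curve)
}

#' Inhibitor dissociation constant from apparent-Km shift
#'
#' Rearrangement of the competitive-inhibition relation:
#' \eqn{K_i = I/(K_m^{app}/K_m - 1)}. When `Km_app <= Km` there is no
#' measurable inhibition and `NA` is returned with a warning.
#'
#' @param Km True Michaelis constant, M.
#' @param Km_app Apparent Michaelis constant in the presence of
#'   inhibitor, M.
#' @param I Inhibitor concentration, M (> 0).
#' @return Inhibitor dissociation constant, M, or `NA_real_` if no
#'   inhibition is detectable.
#' @examples
#' infer_ki(Km = 40e-6, Km_app = 200e-6, I = 200e-9)  # 50e-9
#' @export
infer_ki <- function(Km, Km_app, I) {
  if (any(I <= 0)) abort("`I` must be positive.")
  if (any(Km <= 0)) abort("`Km` must be positive.")
  out <- I / (Km_app / Km - 1)
  no_inhib <- Km_app <= Km
  if (any(no_inhib)) {
    warn("Km_app <= Km: no inhibition detectable; Ki undefined (NA).")
    out[no_inhib] <- NA_real_
  }
  out
}
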