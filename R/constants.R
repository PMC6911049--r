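#' Physical constants
#'
#' Single package-wide definition of the molar gas constant, in the unit
#' system used throughout: energies in kJ/mol, temperatures in kelvin,
#' concentrations in mol/L.
#'
#' @format A named list with one element:
#' \describe{
#'   \item{R}{Molar gas constant, 8.314462618e-3 kJ/(mol K).}
#' }
#' @examples
#' fold_constants$R * 298  # thermal energy RT at 298 K, kJ/mol
#' @export
fold_constants <- list(R = 8.314462618e-3)

# internal shorthand
.R <- fold_constants$R
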