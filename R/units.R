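## Internal unit system: mmHg - mL - s.  CGS only inside field-metric kernels.

#' Unit conversion constants
#'
#' The package works in mmHg, mL and seconds; wall-shear and energy kernels
#' convert to CGS.  `MMHG_TO_DYN_CM2` is the pressure conversion
#' (1 mmHg = 1333.22 dyn/cm2), `KPA_TO_MMHG` converts elastic moduli
#' (1 kPa = 7.50062 mmHg) and `WOOD_TO_MMHG_S_ML` converts Wood units
#' (mmHg.min/L) to mmHg.s/mL.
#'
#' @name unit-constants
#' @keywords internal
NULL

MMHG_TO_DYN_CM2 <- 1333.22
KPA_TO_MMHG <- 7.50062
WOOD_TO_MMHG_S_ML <- 60 / 1000

#' Blood fluid constants
#'
#' Default Newtonian blood properties used throughout: density
#' 1.06 g/cm3 and dynamic viscosity 0.04 poise (dyn.s/cm2).
#'
#' @param density Blood density, g/cm3.
#' @param viscosity Dynamic viscosity, poise.
#' @return An object of class `fluid_constants`.
#' @examples
#' fluid_constants()
#' @export
fluid_constants <- function(density = 1.06, viscosity = 0.04) {
  stopifnot(density > 0, viscosity > 0)
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_constants")
}
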