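## Reduced-order conduit segment: stenosis pressure loss, Laplace-law
## compliance, and wall-modulus tuning against fractional area change.

#' Construct a reduced-order graft segment model
#'
#' Combines a conduit geometry with wall properties and the empirical
#' pressure-loss coefficients.  The loss element is a two-term law
#' (viscous throat term plus a sudden-expansion term, see
#' [stenosis_pressure_loss()]); the default viscous coefficient `kv = 128/pi`
#' makes the no-stenosis limit equal the Poiseuille closed form, and the
#' default turbulent coefficient `kt = 1.52` is the classical empirical
#' expansion value for constricted tubes.
#'
#' @param geometry A [graft_geometry()].
#' @param elastic_modulus Wall elastic modulus, kPa.
#' @param wall_thickness Wall thickness, mm.
#' @param kv Viscous loss coefficient (dimensionless; 128/pi recovers
#'   Poiseuille in the unstenosed limit).
#' @param kt Expansion loss coefficient (dimensionless).
#' @return Object of class `graft_segment`, with derived `compliance`
#'   (mL/mmHg; 0 when the geometry is rigid).
#' @export
graft_segment <- function(geometry, elastic_modulus = 13,
                          wall_thickness = 1.5, kv = 128 / pi, kt = 1.52) {
  stopifnot(inherits(geometry, "graft_geometry"), elastic_modulus > 0,
            wall_thickness > 0, kv > 0, kt >= 0)
  m <- structure(list(geometry = geometry, elastic_modulus = elastic_modulus,
                      wall_thickness = wall_thickness, kv = kv, kt = kt),
                 class = "graft_segment")
  m$compliance <- graft_compliance(m)
  m
}

#' Laplace-law volume compliance of the graft
#'
#' Thin-wall linear-elastic tube compliance `C = 3 pi r^3 L / (2 E h)`,
#' converted to mL/mmHg; zero for a rigid wall.
#'
#' @param model A [graft_segment()].
#' @return Compliance, mL/mmHg.
#' @export
graft_compliance <- function(model) {
  stopifnot(inherits(model, "graft_segment"))
  g <- model$geometry
  if (isTRUE(g$rigid_wall)) return(0)
  r <- g$nominal_diameter / 2 / 10          # cm
  L <- g$graft_length / 10                  # cm
  h <- model$wall_thickness / 10            # cm
  E_dyn <- model$elastic_modulus * 1e4      # kPa -> dyn/cm2
  C_cgs <- 3 * pi * r^3 * L / (2 * E_dyn * h)  # mL per dyn/cm2
  C_cgs * MMHG_TO_DYN_CM2                   # mL/mmHg
}

#' Empirical stenosis pressure loss
#'
#' Two-term loss law replacing a full 3D computation of flow through the
#' constricted conduit:
#' \deqn{\Delta P = K_v \mu L_s / D_s^4 \, Q
#'   + (128/\pi)\, \mu (L - L_s)/D_0^4 \, Q
#'   + K_t \frac{\rho}{2}\left(\frac{A_0}{A_s} - 1\right)^2
#'     \frac{Q}{A_s}\left|\frac{Q}{A_s}\right|}
#' (CGS internally, returned in mmHg).  The second term is the Poiseuille
#' loss of the unconstricted remainder of the conduit; with the default
#' `kv = 128/pi` and no constriction the total reduces exactly to the
#' Poiseuille loss of the full length.  The expansion term vanishes when
#' the throat equals the reference lumen, is odd in `Q`, and grows with
#' both flow magnitude and severity.
#'
#' @param model A [graft_segment()].
#' @param Q Flow rate, mL/s (signed).
#' @param fluid [fluid_constants()].
#' @return Pressure loss, mmHg (same sign as `Q`).
#' @examples
#' g <- graft_geometry(16, 9.6)
#' stenosis_pressure_loss(graft_segment(g), Q = 20)
#' @export
stenosis_pressure_loss <- function(model, Q, fluid = fluid_constants()) {
  co <- graft_loss_coefficients(model, fluid)
  co$R * Q + co$K * Q * abs(Q)
}

#' Linear and quadratic loss coefficients of the graft element
#'
#' Decomposes the loss law of [stenosis_pressure_loss()] into
#' `dP = R*Q + K*Q*|Q|` for use inside the circulation network.
#'
#' @inheritParams stenosis_pressure_loss
#' @return List with `R` (mmHg.s/mL) and `K` (mmHg.s2/mL2).
#' @export
graft_loss_coefficients <- function(model, fluid = fluid_constants()) {
  stopifnot(inherits(model, "graft_segment"))
  g <- model$geometry
  D0 <- g$nominal_diameter / 10                  # cm
  Ds <- g$min_diameter / 10
  if (Ds <= 0) stop("zero stenotic area")
  L <- g$graft_length / 10
  Ls <- min(g$stenosis_length / 10, L)
  A0 <- pi * D0^2 / 4
  As <- pi * Ds^2 / 4
  mu <- fluid$viscosity
  rho <- fluid$density
  R_dyn <- model$kv * mu * Ls / Ds^4 + (128 / pi) * mu * (L - Ls) / D0^4
  K_dyn <- model$kt * (rho / 2) * (A0 / As - 1)^2 / As^2
  list(R = R_dyn / MMHG_TO_DYN_CM2, K = K_dyn / MMHG_TO_DYN_CM2)
}

#' Fractional area change of a thin-wall conduit under a pressure waveform
#'
#' Linear-elastic Laplace response: circumferential strain
#' `dP * r / (E * h)` relative to the diastolic (minimum-pressure) state,
#' giving `FAC = (A_max - A_min)/A_min = (1 + strain)^2 - 1`.
#'
#' @param elastic_modulus Wall modulus, kPa.
#' @param pressure_waveform Numeric vector of luminal pressures over a
#'   cardiac cycle, mmHg.
#' @param geometry A [graft_geometry()]; the mid-conduit (minimum) lumen is
#'   used, matching where area deformation is measured.
#' @param wall_thickness Wall thickness, mm.
#' @return Fractional area change (dimensionless).
#' @export
fractional_area_change <- function(elastic_modulus, pressure_waveform,
                                   geometry, wall_thickness = 1.5) {
  stopifnot(elastic_modulus > 0, length(pressure_waveform) >= 2)
  pp <- max(pressure_waveform) - min(pressure_waveform)
  if (pp <= 0) stop("pressure waveform must have positive pulse pressure")
  r0 <- geometry$min_diameter / 2 / 10   # cm, diastolic radius
  h <- wall_thickness / 10
  strain <- pp * MMHG_TO_DYN_CM2 * r0 / (elastic_modulus * 1e4 * h)
  (1 + strain)^2 - 1
}

#' Tune the wall modulus to a target fractional area change
#'
#' Finds the elastic modulus whose thin-wall area response to the given
#' pressure waveform reproduces the observed fractional area change, by
#' bracketed root finding.  The response is strictly decreasing in the
#' modulus, so the root is unique when attainable.
#'
#' @param target_fac Target fractional area change, in (0, 1).
#' @param pressure_waveform Luminal pressure waveform, mmHg.
#' @param geometry A [graft_geometry()].
#' @param wall_thickness Wall thickness, mm.
#' @param bounds Modulus search bracket, kPa.
#' @param tol Relative tolerance on the achieved FAC.
#' @return List with `modulus` (kPa), `achieved_fac`, `converged` (logical),
#'   and `iterations`.
#' @examples
#' g <- graft_geometry(16, 8)
#' wave <- 13 + 2 * sin(seq(0, 2 * pi, length.out = 50))
#' fac <- fractional_area_change(13.14, wave, g)
#' tune_wall_modulus(fac, wave, g)$modulus
#' @export
tune_wall_modulus <- function(target_fac, pressure_waveform, geometry,
                              wall_thickness = 1.5, bounds = c(0.5, 500),
                              tol = 5e-3) {
  if (target_fac <= 0 || target_fac >= 1)
    stop("target_fac must lie in (0, 1)")
  f <- function(E) fractional_area_change(E, pressure_waveform, geometry,
                                          wall_thickness) - target_fac
  f_lo <- f(bounds[1]); f_hi <- f(bounds[2])
  if (f_lo < 0 || f_hi > 0)
    stop(sprintf(
      "target FAC %.3g unattainable within modulus bounds [%g, %g] kPa",
      target_fac, bounds[1], bounds[2]))
  root <- uniroot(f, bounds, tol = 1e-10)
  achieved <- fractional_area_change(root$root, pressure_waveform, geometry,
                                     wall_thickness)
  list(modulus = root$root, achieved_fac = achieved,
       converged = abs(achieved - target_fac) <= tol * target_fac,
       iterations = root$iter)
}
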