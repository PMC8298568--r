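## Ring-test scaffold mechanics (hanging-weight compliance testing).

#' Construct a ring-test sample
#'
#' A scaffold ring mounted on a rod with a hanging weight.  The hanging
#' length `L` maps to an equivalent internal radius `r = L/pi`, and wall
#' thickness follows from incompressibility of the original sample volume,
#' `h = V0/(2*pi*r*w)`.
#'
#' @param mass Hanging mass, g.
#' @param width Sample width along the axial direction, cm.
#' @param length Hanging length L, cm.
#' @param length0 Original (unloaded) length L0, cm.
#' @param volume0 Original sample volume V0, cm3.
#' @param gravity Gravitational acceleration, cm/s2.
#' @return Object of class `ring_sample` with derived fields `radius` and
#'   `thickness`.
#' @export
ring_sample <- function(mass, width, length, length0 = length, volume0,
                        gravity = 981) {
  stopifnot(mass >= 0, width > 0, length > 0, length0 > 0, volume0 > 0,
            gravity > 0)
  r <- length / pi
  h <- volume0 / (2 * pi * r * width)
  structure(list(mass = mass, width = width, length = length,
                 length0 = length0, volume0 = volume0, gravity = gravity,
                 radius = r, thickness = h),
            class = "ring_sample")
}

#' Equivalent luminal pressure of a hanging-weight ring test
#'
#' P = m g / (2 w r), converted from dyn/cm2 to mmHg.
#'
#' @param sample A [ring_sample()].
#' @return Pressure, mmHg.
#' @examples
#' s <- ring_sample(mass = 50, width = 0.5, length = 0.8 * pi, volume0 = 0.5)
#' ring_pressure(s)
#' @export
ring_pressure <- function(sample) {
  stopifnot(inherits(sample, "ring_sample"))
  if (sample$width <= 0 || sample$radius <= 0) stop("degenerate ring geometry")
  p_dyn <- sample$mass * sample$gravity / (2 * sample$width * sample$radius)
  p_dyn / MMHG_TO_DYN_CM2
}

#' Stress and stretch of a ring sample
#'
#' Circumferential Cauchy stress mg/(2wh) (dyn/cm2), with thickness from
#' incompressibility, against stretch L/L0.
#'
#' @param sample A [ring_sample()].
#' @return Named numeric vector `c(stress = , stretch = )`.
#' @export
ring_stress_stretch <- function(sample) {
  stopifnot(inherits(sample, "ring_sample"))
  if (sample$thickness <= 0 || sample$length0 <= 0)
    stop("degenerate ring geometry")
  stress <- sample$mass * sample$gravity / (2 * sample$width * sample$thickness)
  c(stress = stress, stretch = sample$length / sample$length0)
}

#' Secant stiffness of a pressure-diameter curve
#'
#' Slope of the equivalent pressure-diameter response between the diameters
#' interpolated at physiologic pressures of 5 and 50 mmHg.
#'
#' @param curve data.frame with columns `pressure` (mmHg) and `diameter`.
#' @param p_lo,p_hi Evaluation pressures, mmHg.
#' @return Secant slope, mmHg per diameter unit.
#' @export
stiffness_from_curve <- function(curve, p_lo = 5, p_hi = 50) {
  stopifnot(is.data.frame(curve), all(c("pressure", "diameter") %in% names(curve)))
  if (min(curve$pressure) > p_lo || max(curve$pressure) < p_hi)
    stop(sprintf("curve must span [%g, %g] mmHg", p_lo, p_hi))
  d_lo <- approx(curve$pressure, curve$diameter, xout = p_lo)$y
  d_hi <- approx(curve$pressure, curve$diameter, xout = p_hi)$y
  if (abs(d_hi - d_lo) < .Machine$double.eps * 100)
    stop("flat pressure-diameter curve between evaluation pressures")
  (p_hi - p_lo) / (d_hi - d_lo)
}

#' Burst pressure of a loading series
#'
#' The equivalent pressure at the weight that caused sample failure.
#'
#' @param load_series data.frame with columns `mass` (g), `length` (cm) and
#'   logical `failed`; rows in loading order, ending in a failure event.
#' @param width,volume0,length0,gravity Ring sample geometry shared across
#'   the series (see [ring_sample()]).
#' @return Burst pressure, mmHg (pressure at the failure weight).
#' @export
burst_pressure <- function(load_series, width, volume0,
                           length0 = load_series$length[1], gravity = 981) {
  stopifnot(is.data.frame(load_series),
            all(c("mass", "length", "failed") %in% names(load_series)))
  if (!any(load_series$failed)) stop("no failure event recorded in series")
  i <- which(load_series$failed)[1]
  s <- ring_sample(mass = load_series$mass[i], width = width,
                   length = load_series$length[i], length0 = length0,
                   volume0 = volume0, gravity = gravity)
  ring_pressure(s)
}
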