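## Conduit geometry and analytic flow-field fixtures.

#' Construct a graft geometry
#'
#' Describes one conduit configuration: the local reference (nominal) lumen,
#' the minimum (throat) diameter, and the position and length of the
#' constriction.  Virtual stenoses are applied relative to this geometry
#' (the measured lumen), not to the nominal diameter at implant.  The
#' constriction is modelled as an axisymmetric smooth (cosine) narrowing of
#' the stated length centred at `stenosis_position`.
#'
#' @param nominal_diameter Reference lumen diameter, mm.
#' @param min_diameter Throat diameter, mm (<= nominal).
#' @param graft_length Conduit length, mm.
#' @param stenosis_length Axial extent of the constriction, mm.
#' @param stenosis_position Fraction of length from the inferior
#'   anastomosis; defaults to 0.5 (mid-conduit).
#' @param rigid_wall Logical; `TRUE` models a non-compliant wall (ePTFE or
#'   the rigid comparison arm).
#' @return Object of class `graft_geometry`.
#' @export
graft_geometry <- function(nominal_diameter, min_diameter = nominal_diameter,
                           graft_length = 50, stenosis_length = 20,
                           stenosis_position = 0.5, rigid_wall = FALSE) {
  stopifnot(nominal_diameter > 0, min_diameter > 0, graft_length > 0,
            stenosis_length >= 0)
  if (min_diameter > nominal_diameter + 1e-9)
    stop("min_diameter must not exceed nominal_diameter")
  if (stenosis_position < 0 || stenosis_position > 1)
    stop("stenosis_position must lie in [0, 1]")
  if (stenosis_length > graft_length)
    stop("stenosis_length must not exceed graft_length")
  structure(list(nominal_diameter = nominal_diameter,
                 min_diameter = min_diameter, graft_length = graft_length,
                 stenosis_length = stenosis_length,
                 stenosis_position = stenosis_position,
                 rigid_wall = rigid_wall),
            class = "graft_geometry")
}

#' @export
print.graft_geometry <- function(x, ...) {
  cat(sprintf("<graft_geometry> nominal %g mm, min %g mm, length %g mm%s\n",
              x$nominal_diameter, x$min_diameter, x$graft_length,
              if (x$rigid_wall) " (rigid)" else ""))
  invisible(x)
}

#' Lumen diameter profile along the conduit
#'
#' Axisymmetric cosine constriction from the nominal lumen down to the
#' throat diameter over `stenosis_length`, centred at `stenosis_position`.
#'
#' @param geometry A [graft_geometry()].
#' @param x Axial positions, mm from the inferior anastomosis.
#' @return Diameters, mm.
#' @export
lumen_profile <- function(geometry, x) {
  g <- geometry
  d <- rep(g$nominal_diameter, length(x))
  if (g$stenosis_length > 0 && g$min_diameter < g$nominal_diameter) {
    x0 <- g$stenosis_position * g$graft_length
    s <- abs(x - x0) / (g$stenosis_length / 2)
    inside <- s < 1
    depth <- (g$nominal_diameter - g$min_diameter) / 2
    d[inside] <- g$nominal_diameter -
      depth * (1 + cos(pi * s[inside]))
  }
  d
}

#' Virtual stenosis series
#'
#' Applies degrees of stenosis to a base geometry: each level reduces the
#' base minimum diameter by the stated fraction
#' (`min = base_min * (1 - level)`), with the constriction placed
#' mid-conduit by default.
#'
#' @param base A [graft_geometry()].
#' @param levels Fractional diameter reductions, each strictly in (0, 1).
#' @return List of `graft_geometry` objects, one per level.
#' @examples
#' g <- graft_geometry(12)
#' stenosis_series(g, c(0.1, 0.5, 0.9))
#' @export
stenosis_series <- function(base, levels) {
  stopifnot(inherits(base, "graft_geometry"))
  if (any(levels <= 0) || any(levels >= 1))
    stop("stenosis levels must lie strictly in (0, 1)")
  lapply(levels, function(lv) {
    graft_geometry(nominal_diameter = base$min_diameter,
                   min_diameter = base$min_diameter * (1 - lv),
                   graft_length = base$graft_length,
                   stenosis_length = base$stenosis_length,
                   stenosis_position = 0.5,
                   rigid_wall = base$rigid_wall)
  })
}

#' Analytic flow-field fixtures
#'
#' Emits space-time sampled velocity and wall-shear tables with closed-form
#' metric values, for testing the local hemodynamic metrics.  Supported
#' kinds:
#' \describe{
#'   \item{`plug`}{Uniform axial velocity `u` (cm/s); zero wall shear
#'     gradient information is not needed, WSS set to the plug value
#'     `4*mu*Q/(pi*r^3)` with `Q = u*pi*r^2` for convenience.}
#'   \item{`poiseuille`}{Steady Poiseuille flow of flow rate `Q` (mL/s) in a
#'     tube of radius `r` (cm); wall shear magnitude `4*mu*Q/(pi*r^3)` at
#'     all times.}
#'   \item{`oscillatory`}{Zero-mean sinusoidal WSS of amplitude `amp`
#'     (dyn/cm2) and period `period`; its oscillatory shear index is exactly
#'     0.5 and its time-averaged magnitude is `2*amp/pi`.}
#' }
#'
#' @param kind One of `"plug"`, `"poiseuille"`, `"oscillatory"`.
#' @param Q Flow rate, mL/s (poiseuille).
#' @param r Tube radius, cm.
#' @param u Plug velocity, cm/s.
#' @param amp WSS amplitude, dyn/cm2 (oscillatory).
#' @param period Period, s.
#' @param n_time,n_loc Number of time and surface samples.
#' @param fluid [fluid_constants()].
#' @return A list with elements `table` (long data.frame with columns
#'   `location`, `time`, `wss`, `velocity`) and `field` (a [wss_field()]).
#' @export
analytic_flow_fixture <- function(kind = c("plug", "poiseuille", "oscillatory"),
                                  Q = 20, r = 0.8, u = 10, amp = 1,
                                  period = 1, n_time = 200, n_loc = 8,
                                  fluid = fluid_constants()) {
  kind <- match.arg(kind)
  stopifnot(r > 0, period > 0, n_time > 1, n_loc >= 1)
  tt <- seq(0, period, length.out = n_time + 1)[-(n_time + 1)]
  wss_row <- switch(kind,
    plug = {
      Qp <- u * pi * r^2
      rep(4 * fluid$viscosity * Qp / (pi * r^3), length(tt))
    },
    poiseuille = rep(4 * fluid$viscosity * Q / (pi * r^3), length(tt)),
    oscillatory = amp * sin(2 * pi * tt / period))
  vel_row <- switch(kind,
    plug = rep(u, length(tt)),
    poiseuille = rep(2 * Q / (pi * r^2), length(tt)),  # centreline
    oscillatory = rep(0, length(tt)))
  wss <- matrix(rep(wss_row, each = n_loc), nrow = n_loc)
  tab <- data.frame(
    location = rep(seq_len(n_loc), times = length(tt)),
    time = rep(tt, each = n_loc),
    wss = as.vector(wss),
    velocity = rep(vel_row, each = n_loc))
  list(table = tab, field = wss_field(tt, wss, period = period))
}
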