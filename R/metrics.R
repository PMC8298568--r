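## Oxygenation, systemic/venous and local hemodynamic metrics.

#' Oxygenation constants
#'
#' Constants of the Fick-principle oxygenation estimates: hemoglobin
#' 13.26 g/dL, oxygen-carrying capacity 1.34 mL O2/g, arterial saturation
#' 0.94, arterial/venous oxygen partial pressures 90/40 mmHg, basal VO2
#' 6.5 mL/kg/min in children, and the dL-to-L factor 10.  The dissolved-
#' oxygen coefficient is 0.003 in the extraction-ratio formula and 0.03 in
#' the venous-saturation formula; both printed values are preserved as-is
#' (they differ by the dL/L convention), with `harmonize_dissolved` available
#' to force a common value.
#'
#' @param hb Hemoglobin, g/dL.
#' @param o2_capacity mL O2 per g hemoglobin.
#' @param sa_o2 Arterial oxygen saturation, fraction.
#' @param po2_arterial,po2_venous Oxygen partial pressures, mmHg.
#' @param basal_vo2 Basal oxygen consumption, mL/kg/min.
#' @param dissolved_oer Dissolved-O2 coefficient in the OER denominator.
#' @param dissolved_svo2 Dissolved-O2 coefficient in the sVO2 numerator.
#' @param harmonize_dissolved Optional single value overriding both.
#' @return Object of class `oxygen_constants`.
#' @export
oxygen_constants <- function(hb = 13.26, o2_capacity = 1.34, sa_o2 = 0.94,
                             po2_arterial = 90, po2_venous = 40,
                             basal_vo2 = 6.5, dissolved_oer = 0.003,
                             dissolved_svo2 = 0.03,
                             harmonize_dissolved = NULL) {
  if (!is.null(harmonize_dissolved))
    dissolved_oer <- dissolved_svo2 <- harmonize_dissolved
  structure(list(hb = hb, o2_capacity = o2_capacity, sa_o2 = sa_o2,
                 po2_arterial = po2_arterial, po2_venous = po2_venous,
                 basal_vo2 = basal_vo2, dissolved_oer = dissolved_oer,
                 dissolved_svo2 = dissolved_svo2, dl_to_l = 10),
            class = "oxygen_constants")
}

#' Oxygen extraction ratio
#'
#' Fick-principle estimate of the fraction of delivered oxygen consumed:
#' \deqn{OER = \frac{MET \times 6.5 \times weight}
#'   {((13.26 \times 1.34 \times 0.94) + 0.003 \, PO_{2,arterial})
#'     \times 10 \times CO}}
#' Values above 1 are non-physiologic (oxygen demand exceeding delivery)
#' and are flagged via the `"nonphysiologic"` attribute.
#'
#' @param met Metabolic equivalent.
#' @param weight Body mass, kg.
#' @param co Cardiac output, L/min.
#' @param constants [oxygen_constants()].
#' @return OER (dimensionless), attribute `nonphysiologic` TRUE when > 1.
#' @examples
#' oer(met = 1, weight = 12, co = 1.79)
#' @export
oer <- function(met, weight, co, constants = oxygen_constants()) {
  if (any(co <= 0)) stop("cardiac output must be positive")
  if (any(weight <= 0)) stop("weight must be positive")
  if (any(met < 0)) stop("met must be non-negative")
  k <- constants
  denom <- ((k$hb * k$o2_capacity * k$sa_o2) +
              k$dissolved_oer * k$po2_arterial) * k$dl_to_l * co
  out <- met * k$basal_vo2 * weight / denom
  attr(out, "nonphysiologic") <- out > 1
  out
}

#' Mixed venous oxygen saturation
#'
#' Fick-principle estimate of the saturation of blood returning to the
#' heart:
#' \deqn{sVO_2 = 0.94 - \frac{MET \times 6.5 \times weight / CO
#'   + 0.03 (PO_{2,arterial} - PO_{2,venous})}{13.26 \times 1.34 \times 10}}
#' Negative values are non-physiologic (the exercise state cannot be
#' supplied by the available output) and are flagged.
#'
#' @inheritParams oer
#' @return sVO2 as a fraction, attribute `nonphysiologic` TRUE when < 0.
#' @export
svo2 <- function(met, weight, co, constants = oxygen_constants()) {
  if (any(co <= 0)) stop("cardiac output must be positive")
  k <- constants
  out <- k$sa_o2 -
    (met * k$basal_vo2 * weight / co +
       k$dissolved_svo2 * (k$po2_arterial - k$po2_venous)) /
    (k$hb * k$o2_capacity * k$dl_to_l)
  attr(out, "nonphysiologic") <- out < 0
  out
}

#' Cardiac index from a converged trace
#'
#' `CI = SV x HR / BSA` averaged across the respiratory cycle, with stroke
#' volume taken per cardiac cycle from the ventricular volume series.
#'
#' @param trace An `lpn_trace` covering one respiratory cycle.
#' @param bsa Body surface area, m2.
#' @return Cardiac index, L/min/m2.
#' @export
cardiac_index <- function(trace, bsa) {
  stopifnot(inherits(trace, "lpn_trace"), bsa > 0)
  k <- attr(trace, "cardiac_cycles")
  if (is.null(k) || k < 1) stop("trace does not cover a full respiratory cycle")
  t_card <- attr(trace, "t_resp") / k
  idx <- findInterval(trace$time, seq(0, attr(trace, "t_resp"), by = t_card),
                      rightmost.closed = TRUE)
  sv <- tapply(trace$v_v, idx, function(v) max(v) - min(v))
  mean(sv * attr(trace, "hr")) / 1000 / bsa
}

#' Energy efficiency across a set of inlet and outlet surfaces
#'
#' Percentage of total (static plus dynamic) pressure energy retained
#' between the inlets and outlets of a control volume over one respiratory
#' cycle:
#' \deqn{E = \frac{\sum_{out} \int (p + \tfrac12 \rho u^2)\, Q \; dt}
#'   {\sum_{in} \int (p + \tfrac12 \rho u^2)\, Q \; dt} \times 100}
#'
#' @param inlets,outlets Lists of data.frames, each with columns `time`
#'   (s, shared grid), `p` (mmHg), `q` (mL/s) and `area` (cm2).
#' @param fluid [fluid_constants()].
#' @return Efficiency, percent.
#' @export
energy_efficiency <- function(inlets, outlets, fluid = fluid_constants()) {
  flux <- function(surf) {
    stopifnot(all(c("time", "p", "q", "area") %in% names(surf)))
    u <- surf$q / surf$area
    e <- (surf$p * MMHG_TO_DYN_CM2 + 0.5 * fluid$density * u^2) * surf$q
    cycle_mean(surf$time, e)
  }
  ein <- sum(vapply(inlets, flux, numeric(1)))
  eout <- sum(vapply(outlets, flux, numeric(1)))
  if (ein <= 0) stop("zero or negative inlet energy flux")
  100 * eout / ein
}

#' TCPC energy efficiency of a converged trace
#'
#' Applies [energy_efficiency()] to the total cavopulmonary connection:
#' inlets are the SVC node and the Fontan-conduit inlet (IVC node), outlets
#' the left and right pulmonary branches at the PA node.
#'
#' @param trace An `lpn_trace`.
#' @param graft_area Conduit inlet cross-section, cm2.
#' @param a_svc,a_lpa,a_rpa Vessel cross-sections, cm2 (pediatric defaults).
#' @param fluid [fluid_constants()].
#' @return Efficiency, percent.
#' @export
tcpc_energy_efficiency <- function(trace, graft_area, a_svc = 0.9,
                                   a_lpa = 0.64, a_rpa = 0.64,
                                   fluid = fluid_constants()) {
  stopifnot(inherits(trace, "lpn_trace"), graft_area > 0)
  mk <- function(p, q, a) data.frame(time = trace$time, p = p, q = q, area = a)
  energy_efficiency(
    inlets = list(mk(trace$p_svc, trace$q_svc, a_svc),
                  mk(trace$p_ivc, trace$q_gr, graft_area)),
    outlets = list(mk(trace$p_pa, trace$q_lpa, a_lpa),
                   mk(trace$p_pa, trace$q_rpa, a_rpa)),
    fluid = fluid)
}

#' Construct a wall-shear field
#'
#' Wall-shear samples over surface locations and one period: a matrix of the
#' signed primary-direction wall shear stress (dyn/cm2), locations in rows,
#' times in columns, on a uniform time grid spanning the period.
#'
#' @param times Sample times, s (uniform grid; the endpoint `period` may be
#'   included or excluded).
#' @param wss Numeric matrix, locations x times.
#' @param period Period T, s.
#' @return Object of class `wss_field`.
#' @export
wss_field <- function(times, wss, period = max(times)) {
  wss <- rbind(wss)
  stopifnot(length(times) == ncol(wss), period > 0)
  if (length(times) < 2) stop("need at least two time samples")
  structure(list(times = times, wss = wss, period = period),
            class = "wss_field")
}

#' Read a wall-shear field from a long-format table
#'
#' Accepts the delimited layout emitted by field samplers and by
#' [analytic_flow_fixture()]: one row per (location, time) with columns
#' `location` (id), `time` (s) and either a signed scalar `wss` (primary
#' flow direction, dyn/cm2) or vector components `wss_x`, `wss_y`, `wss_z`
#' whose signed magnitude (projected on the first component's sign) is
#' used.
#'
#' @param x A data.frame in the layout above, or a path to a delimited
#'   file readable by [read.csv()].
#' @param period Period T, s; defaults to the time span implied by the
#'   grid.
#' @return A [wss_field()].
#' @export
wss_field_from_table <- function(x, period = NULL) {
  if (is.character(x)) x <- read.csv(x)
  stopifnot(all(c("location", "time") %in% names(x)))
  if (!"wss" %in% names(x)) {
    comp <- c("wss_x", "wss_y", "wss_z")
    if (!all(comp %in% names(x)))
      stop("table needs a 'wss' column or 'wss_x'/'wss_y'/'wss_z' components")
    mag <- sqrt(x$wss_x^2 + x$wss_y^2 + x$wss_z^2)
    x$wss <- mag * ifelse(x$wss_x < 0, -1, 1)
  }
  times <- sort(unique(x$time))
  locs <- unique(x$location)
  m <- matrix(NA_real_, length(locs), length(times),
              dimnames = list(locs, NULL))
  m[cbind(match(x$location, locs), match(x$time, times))] <- x$wss
  if (anyNA(m)) stop("table does not cover the full location x time grid")
  if (is.null(period)) {
    dt <- mean(diff(times))
    period <- max(times) - min(times) + dt
  }
  wss_field(times, m, period = period)
}

# Integrate a sampled periodic signal over its period.  Uses the trapezoid
# rule when the grid includes the period endpoint, and a plain (circular)
# mean times T otherwise.
.period_integral <- function(times, x, period) {
  span <- max(times) - min(times)
  dt_grid <- mean(diff(times))
  if (span >= period - 0.5 * dt_grid && span <= period + 1e-9) {
    n <- length(times)
    sum(diff(times) * (x[-1] + x[-n]) / 2) * period / span
  } else {
    mean(x) * period
  }
}

#' Time-averaged wall shear stress
#'
#' Time average of the wall-shear magnitude at each location over one
#' period, then spatial average over the region of interest.
#'
#' @param field A [wss_field()].
#' @return TAWSS, dyn/cm2.
#' @export
tawss <- function(field) {
  stopifnot(inherits(field, "wss_field"))
  if (nrow(field$wss) == 0) stop("empty wall-shear field")
  per_loc <- apply(field$wss, 1, function(w)
    .period_integral(field$times, abs(w), field$period) / field$period)
  mean(per_loc)
}

#' Oscillatory shear index
#'
#' `OSI = (1 - |int WSS dt| / int |WSS| dt) / 2` at each location, averaged
#' over the region; 0 for unidirectional shear, 0.5 for fully oscillatory
#' zero-mean shear.  Locations with identically-zero shear contribute 0
#' (no oscillation).
#'
#' @param field A [wss_field()].
#' @return OSI in [0, 0.5].
#' @export
osi <- function(field) {
  stopifnot(inherits(field, "wss_field"))
  per_loc <- apply(field$wss, 1, function(w) {
    num <- abs(.period_integral(field$times, w, field$period))
    den <- .period_integral(field$times, abs(w), field$period)
    if (den <= 0) return(0)
    0.5 * (1 - num / den)
  })
  min(0.5, max(0, mean(pmin(0.5, pmax(0, per_loc)))))
}

#' First invariant of the Green strain
#'
#' `I_E = tr((F'F - I)/2)` for a time series of deformation gradient
#' tensors, time-averaged for magnitude and then averaged across locations.
#'
#' @param samples Either a 3 x 3 x n_time array (one location) or a list of
#'   such arrays (one per location).
#' @return Averaged strain invariant (dimensionless).
#' @examples
#' F <- array(diag(c(1.1, 1, 1)), c(3, 3, 1))
#' green_strain_invariant(F)  # 0.105
#' @export
green_strain_invariant <- function(samples) {
  if (!is.list(samples)) samples <- list(samples)
  per_loc <- vapply(samples, function(Fs) {
    stopifnot(length(dim(Fs)) == 3, dim(Fs)[1] == 3, dim(Fs)[2] == 3)
    ie <- apply(Fs, 3, function(F) {
      if (det(F) <= 0) stop("deformation gradient must have positive determinant")
      sum(diag(0.5 * (t(F) %*% F - diag(3))))
    })
    mean(abs(ie))
  }, numeric(1))
  mean(per_loc)
}

#' Maximum residence time in the conduit
#'
#' Solves the residence-time transport equation
#' `dtau/dt + u dtau/dx = 1` (tau = 0 at the inflow) on a one-dimensional
#' axisymmetric discretization of the conduit with first-order upwinding,
#' integrating repeated cycles until the cycle-averaged field is damped,
#' and returns the maximum over the region of the cycle-averaged residence
#' time, in units of cardiac cycles.
#'
#' @param u Axial velocity, cm/s: a constant, or a function `u(x, t)` of
#'   position (cm) and time (s).
#' @param length Conduit length, cm.
#' @param period Averaging period T, s (one respiratory cycle).
#' @param cardiac_period Cardiac period used to express the result in
#'   cycles; defaults to `period`.
#' @param n_cycles Maximum number of periods to integrate.
#' @param nx Number of grid cells.
#' @param damp_tol Relative change of the cycle-averaged maximum below which
#'   the transient is considered damped.
#' @return List with `rt_cycles` (max cycle-averaged residence time, cardiac
#'   cycles), `rt_profile` (cycle-averaged tau per cell, s), `damped`
#'   (logical), `stagnant` (TRUE when residence time grows without bound,
#'   i.e. the cap `n_cycles * period` was reached in a stagnant sub-region).
#' @examples
#' max_residence_time(u = 10, length = 5, period = 1)$rt_cycles  # 0.5
#' @export
max_residence_time <- function(u, length, period, cardiac_period = period,
                               n_cycles = 10, nx = 200, damp_tol = 0.02) {
  stopifnot(length > 0, period > 0, cardiac_period > 0, nx >= 4)
  ufun <- if (is.function(u)) u else function(x, t) rep_len(u, base::length(x))
  dx <- length / nx
  xc <- (seq_len(nx) - 0.5) * dx
  # CFL-limited step that divides the period exactly
  umax <- max(abs(ufun(xc, 0)), abs(ufun(xc, period / 3)),
              abs(ufun(xc, 2 * period / 3)), 1e-6)
  nt <- max(50L, ceiling(period / (0.4 * dx / umax)))
  dt <- period / nt
  tau <- numeric(nx)
  cap <- n_cycles * period
  prev_max <- NA_real_
  damped <- FALSE
  stagnant <- FALSE
  avg <- numeric(nx)
  for (cyc in seq_len(n_cycles)) {
    avg[] <- 0
    t <- (cyc - 1) * period
    for (s in seq_len(nt)) {
      uu <- ufun(xc, t)
      adv <- numeric(nx)
      # first-order upwind; tau = 0 at whichever end is the inflow
      up_l <- c(0, tau[-nx])      # neighbour on the left
      up_r <- c(tau[-1], 0)       # neighbour on the right
      pos <- uu >= 0
      adv[pos] <- uu[pos] * (tau[pos] - up_l[pos]) / dx
      adv[!pos] <- uu[!pos] * (up_r[!pos] - tau[!pos]) / dx
      tau <- tau + dt * (1 - adv)
      tau[tau < 0] <- 0
      tau[tau > cap] <- cap
      avg <- avg + tau * dt
      t <- t + dt
    }
    avg <- avg / period
    cur_max <- max(avg)
    if (!is.na(prev_max)) {
      if (abs(cur_max - prev_max) <= damp_tol * max(prev_max, 1e-9)) {
        damped <- TRUE
        break
      }
    }
    prev_max <- cur_max
  }
  if (max(tau) >= cap - 1e-9) stagnant <- TRUE
  if (!damped && !stagnant)
    warning("residence-time transient not damped within n_cycles")
  list(rt_cycles = max(avg) / cardiac_period, rt_profile = avg,
       damped = damped, stagnant = stagnant)
}

#' Pressure gradient across the conduit
#'
#' Difference of respiratory-cycle-mean pressures between two named trace
#' nodes (defaults: IVC node upstream, pulmonary-artery node downstream).
#'
#' @param trace An `lpn_trace`.
#' @param upstream,downstream Trace pressure column names.
#' @return Gradient, mmHg.
#' @export
pressure_gradient <- function(trace, upstream = "p_ivc", downstream = "p_pa") {
  stopifnot(inherits(trace, "lpn_trace"))
  if (!upstream %in% names(trace)) stop("upstream node not in trace: ", upstream)
  if (!downstream %in% names(trace)) stop("downstream node not in trace: ", downstream)
  cycle_mean(trace$time, trace[[upstream]]) -
    cycle_mean(trace$time, trace[[downstream]])
}
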