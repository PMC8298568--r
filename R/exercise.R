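## MET-dependent exercise scaling and blood-volume compensation.

#' Total vascular resistance at a metabolic equivalent
#'
#' Exercise relation for total vascular resistance:
#' `TVR_MET = -6.25 * ln(MET) / BSA + TVR_MET1`, with TVR in Wood units
#' (mmHg.min/L) and BSA in m2.  For small patients at high MET the closed
#' form can cross zero; results at or below `floor_frac * tvr_met1` are
#' floored there and flagged.
#'
#' @param tvr_met1 Resting total vascular resistance, Wood units.
#' @param met Metabolic equivalent (>= 1).
#' @param bsa Body surface area, m2.
#' @param floor_frac Physical floor as a fraction of the resting value.
#' @return TVR at the requested MET, Wood units, with attribute `floored`
#'   (logical) set when the floor was applied.
#' @examples
#' tvr_at_met(20, met = 3, bsa = 0.67)  # 9.75
#' @export
tvr_at_met <- function(tvr_met1, met, bsa, floor_frac = 0.1) {
  if (any(met < 1)) stop("met must be >= 1")
  if (any(bsa <= 0)) stop("bsa must be positive")
  stopifnot(tvr_met1 > 0)
  tvr <- -6.25 * log(met) / bsa + tvr_met1
  floor_val <- floor_frac * tvr_met1
  floored <- tvr <= floor_val
  tvr[floored] <- floor_val
  attr(tvr, "floored") <- floored
  tvr
}

#' Split a total resistance into parallel upper/lower branches
#'
#' Returns branch resistances whose parallel combination equals `tvr` and
#' whose flow split (at equal downstream pressures) equals `split_fraction`
#' through the lower-body branch.
#'
#' @param tvr Total resistance (any consistent unit).
#' @param split_fraction Fraction of flow through the lower body, in (0, 1).
#' @return Named vector `c(upper = , lower = )` in the units of `tvr`.
#' @examples
#' distribute_tvr(1.5, 0.55)
#' @export
distribute_tvr <- function(tvr, split_fraction) {
  stopifnot(tvr > 0)
  if (split_fraction <= 0 || split_fraction >= 1)
    stop("split_fraction must lie strictly in (0, 1)")
  c(upper = tvr / (1 - split_fraction), lower = tvr / split_fraction)
}

#' Heart rate at a metabolic equivalent
#'
#' Linear chronotropic law: the rate rises from the resting value at MET 1
#' to `hr_max` at MET 5 (a typical pediatric maximum).  Heart rate is a
#' function of MET only and is never altered by stenosis level.
#'
#' @param hr_rest Resting heart rate, beats/min.
#' @param met Metabolic equivalent (>= 1).
#' @param hr_max Heart rate at MET 5, beats/min.
#' @return Heart rate, beats/min.
#' @export
scale_heart_rate <- function(hr_rest, met, hr_max = 190) {
  if (any(met < 1)) stop("met must be >= 1")
  stopifnot(hr_rest > 0, hr_max >= hr_rest)
  hr_rest + (hr_max - hr_rest) * (met - 1) / 4
}

#' Apply an exercise (MET) state to an LPN parameter set
#'
#' Scales the circulation for exercise: systemic resistances follow the
#' total-vascular-resistance relation [tvr_at_met()], the heart rate follows
#' [scale_heart_rate()] (then re-snapped to an integer number of beats per
#' respiratory cycle), pulmonary resistances fall linearly with MET
#' (recruitment/distension), and ventricular contractility rises linearly
#' with MET.  Stressed blood volume is untouched; stenosis compensation is
#' handled separately by [compensate_blood_volume()].
#'
#' @param params [lpn_parameters()] describing the resting (MET 1) state.
#' @param met Metabolic equivalent (1 = rest; the study protocol uses
#'   1, 3, 5).
#' @param hr_max Heart rate at MET 5, beats/min.
#' @param pvr_slope Fractional pulmonary-resistance reduction per MET above
#'   rest (default 0.05: 0.9x at MET 3, 0.8x at MET 5).
#' @param contractility_slope Fractional E_max increase per MET above rest.
#' @param venoconstriction_slope Fractional reduction of systemic venous
#'   capacitances per MET above rest (sympathetic venoconstriction and the
#'   muscle pump shift blood centrally during exercise, sustaining preload
#'   and raising caval pressures).
#' @param t_resp Respiratory period during exercise, s (breathing speeds up
#'   with exercise).
#' @return A new `lpn_params` object for the exercise state, with attribute
#'   `tvr_floored` when the TVR floor engaged.
#' @export
apply_met <- function(params, met, hr_max = 190, pvr_slope = 0.05,
                      contractility_slope = 0.25,
                      venoconstriction_slope = 0.07, t_resp = NULL) {
  stopifnot(inherits(params, "lpn_params"))
  if (met < 1) stop("met must be >= 1")
  p <- unclass(params)
  tvr1_wood <- lpn_systemic_tvr(params) / WOOD_TO_MMHG_S_ML
  tvr_wood <- tvr_at_met(tvr1_wood, met, p$bsa)
  f_sys <- as.numeric(tvr_wood) / tvr1_wood
  p$r_ub_a <- p$r_ub_a * f_sys
  p$r_ub_v <- p$r_ub_v * f_sys
  p$r_lb_a <- p$r_lb_a * f_sys
  p$r_lb_v <- p$r_lb_v * f_sys
  f_pvr <- max(0.3, 1 - pvr_slope * (met - 1))
  p$r_lpa <- p$r_lpa * f_pvr
  p$r_rpa <- p$r_rpa * f_pvr
  p$r_pv <- p$r_pv * f_pvr
  f_ven <- max(0.4, 1 - venoconstriction_slope * (met - 1))
  p$c_ub <- p$c_ub * f_ven
  p$c_lb <- p$c_lb * f_ven
  p$c_svc <- p$c_svc * f_ven
  p$c_ivc <- p$c_ivc * f_ven
  p$e_max <- p$e_max * (1 + contractility_slope * (met - 1))
  p$hr <- scale_heart_rate(p$hr_nominal, met, hr_max = hr_max)
  if (!is.null(t_resp)) p$t_resp <- t_resp
  p$met <- met
  p <- .adjust_heart_period(p)
  out <- structure(p, class = "lpn_params")
  attr(out, "tvr_floored") <- any(attr(tvr_wood, "floored"))
  out
}

#' Total systemic resistance of a parameter set
#'
#' Parallel combination of the upper- and lower-body pathways (arterial plus
#' venous limbs), in mmHg.s/mL.
#'
#' @param params [lpn_parameters()].
#' @return Resistance, mmHg.s/mL.
#' @export
lpn_systemic_tvr <- function(params) {
  r_up <- params$r_ub_a + params$r_ub_v
  r_low <- params$r_lb_a + params$r_lb_v
  1 / (1 / r_up + 1 / r_low)
}

#' Compensate stenosis by scaling stressed blood volume
#'
#' Matches the maximum aortic pressure of a (typically stenosed)
#' configuration to a reference value by scaling the total stressed (excess)
#' blood volume only — the model's surrogate for the long-term
#' volume-retention response to venous constriction.  All other parameters
#' are left bit-identical.  Solved by bracketed scalar root finding on the
#' volume scale factor; each evaluation is a full [run_to_periodic()].
#'
#' @param params [lpn_parameters()] of the configuration to compensate.
#' @param reference Either an `lpn_trace` of the reference geometry or a
#'   numeric reference maximum aortic pressure, mmHg.
#' @param tol Pressure-matching tolerance, mmHg.
#' @param bracket Search bracket for the volume scale factor.
#' @param ... Passed to [run_to_periodic()].
#' @return The compensated `lpn_params`, with attribute `compensation`: a
#'   list with `scale`, `residual` (mmHg), `iterations`, `flagged` (TRUE if
#'   the target was unattainable within the bracket and the volume sits at
#'   a bound).
#' @export
compensate_blood_volume <- function(params, reference, tol = 0.5,
                                    bracket = c(0.5, 3), ...) {
  stopifnot(inherits(params, "lpn_params"))
  ref_max <- if (inherits(reference, "lpn_trace"))
    unname(trace_summary(reference)["max_pao"])
  else as.numeric(reference)
  stopifnot(is.finite(ref_max), ref_max > 0)

  n_eval <- 0L
  v0 <- params$stressed_volume
  f <- function(s) {
    n_eval <<- n_eval + 1L
    p <- params
    p$stressed_volume <- v0 * s
    unname(trace_summary(run_to_periodic(p, ...))["max_pao"]) - ref_max
  }
  r1 <- f(1)
  if (abs(r1) <= tol) {
    attr(params, "compensation") <- list(scale = 1, residual = r1,
                                         iterations = n_eval, flagged = FALSE)
    return(params)
  }
  lo <- f(bracket[1]); hi <- f(bracket[2])
  flagged <- FALSE
  if (lo > 0 || hi < 0) {
    # target unattainable: pin the volume at the nearer bound
    s_star <- if (abs(lo) < abs(hi)) bracket[1] else bracket[2]
    resid <- if (s_star == bracket[1]) lo else hi
    flagged <- TRUE
  } else {
    root <- uniroot(f, bracket, f.lower = lo, f.upper = hi, tol = 2e-3,
                    maxiter = 30)
    s_star <- root$root
    resid <- root$f.root
    if (abs(resid) > tol) {
      resid <- f(s_star)  # re-evaluate at the returned root
      if (abs(resid) > tol) flagged <- TRUE
    }
  }
  out <- params
  out$stressed_volume <- v0 * s_star
  attr(out, "compensation") <- list(scale = s_star, residual = resid,
                                    iterations = n_eval, flagged = flagged)
  out
}
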