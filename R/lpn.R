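## Closed-loop lumped-parameter network (LPN) of Fontan circulation.

# Parameter names in the order expected by the compiled core.
.lpn_par_names <- c(
  "hr", "t_resp", "resp_amp", "e_max", "e_min", "t1_frac", "t2_frac",
  "r_av", "r_vao", "e_at", "c_ao", "r_ub_a", "c_ub", "r_ub_v", "c_svc",
  "r_svc", "r_lb_a", "c_lb", "r_lb_v", "c_ivc", "r_gr", "k_gr", "r_lpa",
  "r_rpa", "c_pa", "r_pv", "c_pul", "valve_eps", "linear_valves")

.lpn_state_names <- c("v_v", "v_at", "v_ao", "v_ub", "v_svc", "v_lb",
                      "v_ivc", "v_pa", "v_pul")
.lpn_pressure_names <- c("p_v", "p_at", "p_ao", "p_ub", "p_svc", "p_lb",
                         "p_ivc", "p_pa", "p_pul")
.lpn_flow_names <- c("q_av", "q_vao", "q_ua", "q_uv", "q_svc", "q_la",
                     "q_lv", "q_gr", "q_lpa", "q_rpa", "q_pv")

# Baseline pediatric Fontan parameter set at the reference body size
# (BSA 0.67 m2).  Tuned once so that resting (MET 1) outputs sit at a
# mid-normal Fontan operating point: cardiac index ~3.4 L/min/m2, mean
# aortic pressure ~70 mmHg, caval pressures ~13.5-14 mmHg, mixed venous
# saturation ~68%.  Resistances mmHg.s/mL, capacitances mL/mmHg,
# elastances mmHg/mL, stressed volume mL.
.lpn_baseline <- list(
  bsa_ref = 0.67,
  hr = 80, t_resp = 3, resp_amp = 2,
  e_max = 5.75, e_min = 0.18, t1_frac = 0.30, t2_frac = 0.45,
  r_av = 0.015, r_vao = 0.025, e_at = 0.35,
  c_ao = 0.8,
  r_ub_a = 3.00, c_ub = 3.0, r_ub_v = 0.49, c_svc = 1.2, r_svc = 0.03,
  r_lb_a = 2.45, c_lb = 6.0, r_lb_v = 0.40, c_ivc = 2.5,
  r_gr = 0.01, k_gr = 0,
  r_lpa = 0.30, r_rpa = 0.30, c_pa = 0.8, r_pv = 0.012, c_pul = 4.0,
  valve_eps = 1e-3, linear_valves = 0,
  stressed_volume = 395)

#' Closed-loop LPN parameter set
#'
#' Builds the full parameter set of the closed-loop Fontan circulation:
#' a single time-varying-elastance ventricle, a passive atrium,
#' atrioventricular and aortic smoothed-diode valves, upper- and lower-body
#' systemic blocks, the total cavopulmonary connection (SVC pathway plus the
#' Fontan conduit), left/right pulmonary branches, and a zero-mean
#' sinusoidal respiratory pressure applied to thoracic compartments.
#'
#' The shipped baseline is a pediatric parameter set at reference body
#' surface area 0.67 m2, scaled allometrically: resistances and elastances
#' by `bsa_ref/bsa`, capacitances and volumes by `bsa/bsa_ref`.  The heart
#' period is adjusted to the nearest integer divisor of the respiratory
#' period so that averaging windows contain whole cardiac cycles.
#'
#' @param bsa Body surface area, m2.
#' @param graft Optional [graft_segment()]: its loss coefficients become the
#'   Fontan-conduit element and its Laplace compliance is added to the
#'   IVC-node capacitance.
#' @param fluid [fluid_constants()] used for the graft loss element.
#' @param ... Named overrides of any baseline field (post-scaling), e.g.
#'   `hr = 90`, `resp_amp = 0`, `stressed_volume = 420`.
#' @return Object of class `lpn_params`.
#' @examples
#' p <- lpn_parameters(bsa = 0.64)
#' @export
lpn_parameters <- function(bsa = 0.67, graft = NULL,
                           fluid = fluid_constants(), ...) {
  stopifnot(bsa > 0)
  b <- .lpn_baseline
  sc_r <- b$bsa_ref / bsa   # resistances, elastances
  sc_c <- bsa / b$bsa_ref   # capacitances, volumes
  p <- list(
    bsa = bsa, hr = b$hr, t_resp = b$t_resp, resp_amp = b$resp_amp,
    e_max = b$e_max * sc_r, e_min = b$e_min * sc_r,
    t1_frac = b$t1_frac, t2_frac = b$t2_frac,
    r_av = b$r_av * sc_r, r_vao = b$r_vao * sc_r, e_at = b$e_at * sc_r,
    c_ao = b$c_ao * sc_c,
    r_ub_a = b$r_ub_a * sc_r, c_ub = b$c_ub * sc_c,
    r_ub_v = b$r_ub_v * sc_r, c_svc = b$c_svc * sc_c, r_svc = b$r_svc * sc_r,
    r_lb_a = b$r_lb_a * sc_r, c_lb = b$c_lb * sc_c,
    r_lb_v = b$r_lb_v * sc_r, c_ivc = b$c_ivc * sc_c,
    r_gr = b$r_gr, k_gr = b$k_gr,
    r_lpa = b$r_lpa * sc_r, r_rpa = b$r_rpa * sc_r, c_pa = b$c_pa * sc_c,
    r_pv = b$r_pv * sc_r, c_pul = b$c_pul * sc_c,
    valve_eps = b$valve_eps, linear_valves = b$linear_valves,
    stressed_volume = b$stressed_volume * sc_c,
    met = 1)
  if (!is.null(graft)) {
    stopifnot(inherits(graft, "graft_segment"))
    co <- graft_loss_coefficients(graft, fluid)
    p$r_gr <- co$R
    p$k_gr <- co$K
    p$c_ivc <- p$c_ivc + graft$compliance
    p$graft <- graft
  }
  dots <- list(...)
  bad <- setdiff(names(dots), c(.lpn_par_names, "stressed_volume", "met"))
  if (length(bad)) stop("unknown LPN parameter(s): ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  .validate_lpn(p)
  p <- .adjust_heart_period(p)
  structure(p, class = "lpn_params")
}

.validate_lpn <- function(p) {
  rs <- unlist(p[grep("^r_", names(p))])
  cs <- unlist(p[grep("^c_", names(p))])
  if (any(rs < 0) || any(cs < 0)) stop("resistances and capacitances must be >= 0")
  if (!(p$e_max > p$e_min && p$e_min > 0)) stop("need e_max > e_min > 0")
  if (p$hr <= 0) stop("heart_rate must be positive")
  if (!(p$t1_frac > 0 && p$t1_frac < p$t2_frac && p$t2_frac < 1))
    stop("activation fractions must satisfy 0 < t1 < t2 < 1")
  invisible(p)
}

# Adjust the cardiac period to the nearest divisor of the respiratory
# period; records the nominal rate in hr_nominal.
.adjust_heart_period <- function(p) {
  p$hr_nominal <- p$hr
  k <- max(1, round(p$t_resp / (60 / p$hr)))
  p$hr <- 60 * k / p$t_resp
  p$cardiac_cycles_per_resp <- k
  p
}

#' @export
print.lpn_params <- function(x, ...) {
  cat(sprintf(
    "<lpn_params> BSA %.2f m2, HR %.1f bpm (%d beats/resp cycle of %.2g s), MET %g\n",
    x$bsa, x$hr, x$cardiac_cycles_per_resp, x$t_resp, x$met))
  cat(sprintf("  E_max %.2f, E_min %.3f mmHg/mL; stressed volume %.0f mL\n",
              x$e_max, x$e_min, x$stressed_volume))
  cat(sprintf("  graft element: R %.4f mmHg.s/mL, K %.5f mmHg.s2/mL2\n",
              x$r_gr, x$k_gr))
  invisible(x)
}

# Pack parameters into the numeric vector the compiled core expects.
lpn_par_vector <- function(params) {
  stopifnot(inherits(params, "lpn_params"))
  vapply(.lpn_par_names, function(nm) as.numeric(params[[nm]]), numeric(1))
}

#' Ventricular elastance waveform
#'
#' Time-varying elastance of the single ventricle: a C1 double-cosine
#' activation rising from `e_min` to `e_max` over the first `t1_frac` of the
#' cardiac period and relaxing back by `t2_frac`.
#'
#' @param t Time, s (vectorized).
#' @param params [lpn_parameters()].
#' @return Elastance, mmHg/mL.
#' @export
elastance <- function(t, params) {
  pv <- lpn_par_vector(params)
  vapply(t, function(ti) elastance_cpp(ti, pv), numeric(1))
}

#' Respiratory pressure waveform
#'
#' Zero-mean sinusoidal intrathoracic pressure offset applied to the
#' thoracic compartments (heart, pulmonary arteries and veins), with the
#' configured amplitude and respiratory period.
#'
#' @inheritParams elastance
#' @return Pressure offset, mmHg.
#' @export
respiratory_pressure <- function(t, params) {
  -params$resp_amp * sin(2 * pi * t / params$t_resp)
}

#' Right-hand side of the circulation ODE
#'
#' Derivatives of the nine stressed compartment volumes at state `state`
#' and time `t`.  The same compiled kernel drives [run_to_periodic()], so
#' this function exposes the identical physics for external integrators and
#' conservation checks.
#'
#' @param state Named or unnamed numeric vector of 9 stressed volumes (mL),
#'   in the order ventricle, atrium, aorta, upper body, SVC, lower body,
#'   IVC, pulmonary arteries, pulmonary veins.
#' @param t Time, s.
#' @param params [lpn_parameters()].
#' @return List with `derivs` (mL/s), `pressures` (mmHg), `flows` (mL/s)
#'   and `pth` (respiratory offset, mmHg).
#' @export
lpn_rhs <- function(state, t, params) {
  if (any(!is.finite(state))) stop("integration failure: non-finite state")
  e <- lpn_eval_cpp(t, as.numeric(state), lpn_par_vector(params))
  list(derivs = setNames(e$derivs, .lpn_state_names),
       pressures = setNames(e$pressures, .lpn_pressure_names),
       flows = setNames(e$flows, .lpn_flow_names),
       pth = e$pth)
}

#' Initial state for a given stressed blood volume
#'
#' Distributes the total stressed volume across compartments in proportion
#' to their effective capacitances (diastolic compliance for the heart
#' chambers), a neutral starting point from which the limit cycle is
#' reached.
#'
#' @param params [lpn_parameters()].
#' @return Named numeric vector of 9 stressed volumes, mL.
#' @export
lpn_initial_state <- function(params) {
  w <- c(1 / params$e_min, 1 / params$e_at, params$c_ao, params$c_ub,
         params$c_svc, params$c_lb, params$c_ivc, params$c_pa, params$c_pul)
  setNames(params$stressed_volume * w / sum(w), .lpn_state_names)
}

#' Run the circulation to periodic steady state
#'
#' Integrates the closed-loop network (fixed-step 4th-order Runge-Kutta in
#' compiled code) respiratory cycle by respiratory cycle until the cycle
#' means of all node pressures change by less than `tol` (relative) between
#' successive cycles, then records one full respiratory cycle as the trace.
#'
#' @param params [lpn_parameters()].
#' @param tol Relative convergence tolerance on cycle-mean node pressures.
#' @param dt Integration step, s.
#' @param out_dt Trace output step, s.
#' @param max_cycles Maximum respiratory cycles before declaring failure.
#' @param min_cycles Minimum respiratory cycles to integrate.
#' @return Object of class `lpn_trace`: a data.frame with time, stressed
#'   volumes, node pressures, branch flows and the respiratory offset over
#'   one converged respiratory cycle; attributes carry the parameters,
#'   convergence diagnostics and cycle markers.
#' @export
run_to_periodic <- function(params, tol = 1e-3, dt = 2e-4, out_dt = 2e-3,
                            max_cycles = 80, min_cycles = 4) {
  stopifnot(inherits(params, "lpn_params"))
  res <- lpn_integrate_cpp(lpn_par_vector(params), lpn_initial_state(params),
                           dt = dt, out_dt = out_dt, max_cycles = max_cycles,
                           tol = tol, min_cycles = min_cycles)
  if (!res$converged)
    stop(sprintf(
      "LPN failed to reach a periodic state in %d respiratory cycles (last residual %.3g > tol %.3g)",
      res$n_cycles, res$residual, tol))
  tr <- as.data.frame(res$trace)
  names(tr) <- c("time", .lpn_state_names, .lpn_pressure_names,
                 .lpn_flow_names, "pth")
  structure(tr, class = c("lpn_trace", "data.frame"),
            params = params, converged = res$converged,
            n_cycles = res$n_cycles, residual = res$residual,
            final_state = res$final_state,
            hr = params$hr, t_resp = params$t_resp,
            cardiac_cycles = params$cardiac_cycles_per_resp)
}

#' @export
print.lpn_trace <- function(x, ...) {
  cat(sprintf(
    "<lpn_trace> one respiratory cycle (%.2g s, %d cardiac cycles), converged after %d cycles (residual %.2g)\n",
    attr(x, "t_resp"), attr(x, "cardiac_cycles"), attr(x, "n_cycles"),
    attr(x, "residual")))
  s <- trace_summary(x)
  cat(sprintf("  MAP %.1f, IVC %.1f, SVC %.1f, PA %.1f mmHg; CO %.2f L/min; SV %.1f mL\n",
              s["map"], s["ivc_pressure"], s["svc_pressure"], s["pa_pressure"],
              s["co"], s["sv"]))
  invisible(x)
}

# Trapezoidal mean of a periodic series sampled on [0, T].
cycle_mean <- function(time, x) {
  n <- length(time)
  sum(diff(time) * (x[-1] + x[-n]) / 2) / (time[n] - time[1])
}

#' Respiratory-cycle summary of a converged trace
#'
#' Cycle-mean pressures, cardiac output (mean aortic-valve flow), stroke
#' volume (mean over the cardiac cycles of max minus min ventricular
#' volume), and maximum aortic pressure.
#'
#' @param trace An `lpn_trace`.
#' @return Named numeric vector (`map`, `ivc_pressure`, `svc_pressure`,
#'   `pa_pressure`, `atrial_pressure`, `co` L/min, `sv` mL, `hr` bpm,
#'   `max_pao` mmHg, `graft_gradient` mmHg).
#' @export
trace_summary <- function(trace) {
  stopifnot(inherits(trace, "lpn_trace"))
  tm <- trace$time
  k <- attr(trace, "cardiac_cycles")
  t_card <- attr(trace, "t_resp") / k
  idx <- findInterval(tm, seq(0, attr(trace, "t_resp"), by = t_card),
                      rightmost.closed = TRUE)
  sv <- mean(tapply(trace$v_v, idx, function(v) max(v) - min(v)))
  c(map = cycle_mean(tm, trace$p_ao),
    ivc_pressure = cycle_mean(tm, trace$p_ivc),
    svc_pressure = cycle_mean(tm, trace$p_svc),
    pa_pressure = cycle_mean(tm, trace$p_pa),
    atrial_pressure = cycle_mean(tm, trace$p_at),
    co = cycle_mean(tm, trace$q_vao) * 60 / 1000,
    sv = sv,
    hr = attr(trace, "hr"),
    max_pao = max(trace$p_ao),
    graft_gradient = cycle_mean(tm, trace$p_ivc) - cycle_mean(tm, trace$p_pa))
}
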