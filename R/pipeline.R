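## Study orchestration: cohort -> LPN -> compensation -> metrics.

#' Build the graft model for a comparison arm
#'
#' Maps a patient record and comparison arm to a [graft_segment()]:
#' \describe{
#'   \item{`mri`}{The measured conduit: a uniform lumen at the measured
#'     minimum diameter with the patient's tuned wall modulus.}
#'   \item{`rigid`}{Same geometry with a rigid wall.}
#'   \item{`eptfe16`}{A rigid 16-mm conduit (standard-of-care comparison).}
#' }
#' A virtual stenosis level, when given, constricts the measured lumen by
#' that diameter fraction mid-conduit (relative to the measured geometry,
#' not the nominal implant size).
#'
#' @param patient A [patient_record()].
#' @param arm `"mri"`, `"rigid"` or `"eptfe16"`.
#' @param stenosis_level Fractional diameter reduction in [0, 1), 0 = none.
#' @param graft_length,stenosis_length Conduit dimensions, mm.
#' @param kv,kt Loss coefficients, see [graft_segment()].
#' @return A [graft_segment()].
#' @export
build_graft <- function(patient, arm = c("mri", "rigid", "eptfe16"),
                        stenosis_level = 0, graft_length = 50,
                        stenosis_length = 20, kv = 128 / pi, kt = 1.52) {
  arm <- match.arg(arm)
  stopifnot(inherits(patient, "patient_record"),
            stenosis_level >= 0, stenosis_level < 1)
  base_d <- if (arm == "eptfe16") 16 else patient$min_diameter
  rigid <- arm %in% c("rigid", "eptfe16")
  geom <- if (stenosis_level > 0)
    graft_geometry(nominal_diameter = base_d,
                   min_diameter = base_d * (1 - stenosis_level),
                   graft_length = graft_length,
                   stenosis_length = stenosis_length,
                   stenosis_position = 0.5, rigid_wall = rigid)
  else
    graft_geometry(nominal_diameter = base_d, min_diameter = base_d,
                   graft_length = graft_length,
                   stenosis_length = stenosis_length, rigid_wall = rigid)
  graft_segment(geom, elastic_modulus = patient$elastic_modulus,
                wall_thickness = patient$wall_thickness, kv = kv, kt = kt)
}

#' Simulate one (patient, arm, stenosis, MET) condition
#'
#' Builds the graft model and LPN parameters, applies the exercise state,
#' optionally compensates stressed blood volume against a reference trace
#' (the un-stenosed geometry at the same MET), and runs to periodic steady
#' state.
#'
#' @param patient A [patient_record()].
#' @param arm Comparison arm, see [build_graft()].
#' @param met Metabolic equivalent.
#' @param stenosis_level Fractional diameter reduction in [0, 1).
#' @param reference Optional reference `lpn_trace` (or maximum aortic
#'   pressure, mmHg) for blood-volume compensation; compensation is applied
#'   only when a reference is given.
#' @param fluid [fluid_constants()].
#' @param tol Convergence tolerance passed to [run_to_periodic()].
#' @param ... Further arguments to [build_graft()].
#' @return List with `trace`, `params`, `graft`, `patient`, `met`,
#'   `stenosis_level`, `arm`.
#' @export
simulate_patient <- function(patient, arm = "mri", met = 1,
                             stenosis_level = 0, reference = NULL,
                             fluid = fluid_constants(), tol = 1e-3, ...) {
  graft <- build_graft(patient, arm = arm, stenosis_level = stenosis_level, ...)
  params <- lpn_parameters(bsa = patient$bsa, graft = graft, fluid = fluid)
  if (met > 1) params <- apply_met(params, met)
  if (!is.null(reference))
    params <- compensate_blood_volume(params, reference, tol = 0.5)
  trace <- run_to_periodic(params, tol = tol)
  list(trace = trace, params = params, graft = graft, patient = patient,
       met = met, stenosis_level = stenosis_level, arm = arm)
}

#' Full metric panel for one simulated condition
#'
#' Derives the complete report for one condition: oxygenation (OER, sVO2),
#' systemic/venous (CI, IVC/SVC pressures, MAP), and local hemodynamics
#' (conduit pressure gradient, TCPC energy efficiency, TAWSS, OSI, Green
#' strain invariant, maximum residence time).  Non-physiologic oxygenation
#' states (OER > 1, sVO2 < 0) set flag columns.
#'
#' @param sim Result of [simulate_patient()].
#' @param constants [oxygen_constants()].
#' @param fluid [fluid_constants()].
#' @param rt_r_frac Radial station (fraction of the radius) of the
#'   near-wall streamline used for the residence-time surrogate.
#' @return One-row data.frame (the metrics report).
#' @export
compute_metrics <- function(sim, constants = oxygen_constants(),
                            fluid = fluid_constants(), rt_r_frac = 0.9) {
  trace <- sim$trace
  patient <- sim$patient
  g <- sim$graft$geometry
  s <- trace_summary(trace)
  co <- unname(s["co"])
  oer_v <- oer(sim$met, patient$weight, co, constants)
  svo2_v <- svo2(sim$met, patient$weight, co, constants)
  a_throat <- pi * (g$min_diameter / 10)^2 / 4
  a_nom <- pi * (g$nominal_diameter / 10)^2 / 4

  # Quasi-steady wall-shear surrogate along the lumen profile
  L <- g$graft_length / 10
  x <- seq(0.02, 0.98, length.out = 25) * L
  r <- lumen_profile(g, x * 10) / 2 / 10
  wssm <- outer(1 / r^3, 4 * fluid$viscosity * trace$q_gr / pi)
  fld <- wss_field(trace$time, wssm, period = attr(trace, "t_resp"))

  # Green strain of the compliant wall from the luminal pressure waveform
  ie <- if (isTRUE(g$rigid_wall)) 0 else {
    pw <- trace$p_ivc
    r0 <- g$min_diameter / 2 / 10
    h <- sim$graft$wall_thickness / 10
    lam <- 1 + (pw - min(pw)) * MMHG_TO_DYN_CM2 * r0 /
      (sim$graft$elastic_modulus * 1e4 * h)
    keep <- seq(1, length(lam), by = 4)
    Fs <- array(0, c(3, 3, length(keep)))
    for (i in seq_along(keep)) Fs[, , i] <- diag(c(lam[keep[i]], 1, 1 / lam[keep[i]]))
    green_strain_invariant(Fs)
  }

  # Residence time on a near-wall streamline of the parabolic profile
  t_resp <- attr(trace, "t_resp")
  t_card <- t_resp / attr(trace, "cardiac_cycles")
  qf <- approxfun(trace$time, trace$q_gr, rule = 2)
  prof <- 2 * (1 - rt_r_frac^2)  # parabolic profile factor at the station
  ufun <- function(xx, tt) {
    q <- qf(tt %% t_resp)
    a <- pi * (lumen_profile(g, xx * 10) / 2 / 10)^2
    prof * q / a
  }
  rt <- max_residence_time(ufun, length = L, period = t_resp,
                           cardiac_period = t_card, n_cycles = 8, nx = 120)

  eff <- tcpc_energy_efficiency(trace, graft_area = a_nom, fluid = fluid)

  data.frame(
    patient_id = patient$patient_id, arm = sim$arm, met = sim$met,
    stenosis_level = sim$stenosis_level,
    min_diameter = g$min_diameter,
    oer = as.numeric(oer_v), svo2_pct = 100 * as.numeric(svo2_v),
    ci = cardiac_index(trace, patient$bsa),
    co = co,
    ivc_pressure = unname(s["ivc_pressure"]),
    svc_pressure = unname(s["svc_pressure"]),
    map = unname(s["map"]),
    pressure_gradient = pressure_gradient(trace),
    energy_efficiency = eff,
    tawss = tawss(fld), osi = osi(fld),
    green_strain = ie,
    max_rt_cycles = rt$rt_cycles,
    rt_stagnant = rt$stagnant,
    oer_gt_1 = isTRUE(attr(oer_v, "nonphysiologic")),
    svo2_lt_0 = isTRUE(attr(svo2_v, "nonphysiologic")),
    converged = attr(trace, "converged"),
    n_cycles = attr(trace, "n_cycles"),
    stringsAsFactors = FALSE)
}

#' Study configuration
#'
#' Describes one reproducible study: cohort source, stenosis and MET sweeps,
#' comparison arm, solver settings.  Round-trips losslessly through YAML
#' via [write_study_config()] / [read_study_config()].
#'
#' @param cohort `"fixture"` (the four trial patients at 6 months) or
#'   `"synthetic"`.
#' @param n Cohort size when synthetic.
#' @param seed RNG seed.
#' @param arm One of `"mri"`, `"rigid"`, `"eptfe16"`.
#' @param met_levels MET levels to simulate (study protocol: 1, 3, 5).
#' @param stenosis_levels Additional virtual stenosis levels in (0, 1);
#'   empty for the measured geometries only.
#' @param tol Periodicity tolerance of the solver.
#' @param out_dir Optional output directory for CSV summaries.
#' @return Object of class `study_config`.
#' @export
study_config <- function(cohort = c("fixture", "synthetic"), n = 4, seed = 1,
                         arm = c("mri", "rigid", "eptfe16"),
                         met_levels = c(1, 3, 5),
                         stenosis_levels = numeric(0), tol = 1e-3,
                         out_dir = NULL) {
  cohort <- match.arg(cohort)
  arm <- match.arg(arm)
  if (length(met_levels) < 1) stop("met_levels must be non-empty")
  if (any(met_levels < 1)) stop("met levels must be >= 1")
  if (length(stenosis_levels) &&
      (any(stenosis_levels <= 0) || any(stenosis_levels >= 1)))
    stop("stenosis levels must lie strictly in (0, 1)")
  structure(list(cohort = cohort, n = n, seed = seed, arm = arm,
                 met_levels = met_levels, stenosis_levels = stenosis_levels,
                 tol = tol, out_dir = out_dir),
            class = "study_config")
}

#' @rdname study_config
#' @param config A `study_config`.
#' @param path File path for the YAML serialization.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname study_config
#' @export
read_study_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(study_config, c(
    x[c("cohort", "n", "seed", "arm", "tol")],
    list(met_levels = as.numeric(unlist(x$met_levels)),
         stenosis_levels = as.numeric(unlist(x$stenosis_levels)),
         out_dir = x$out_dir)))
}

#' Run a full study
#'
#' Orchestrates cohort generation, per-condition simulation (with
#' blood-volume compensation of virtual stenoses against the same patient's
#' un-stenosed geometry at the same MET) and the metric panel, for every
#' (patient, stenosis, MET) cell of the configured sweep.  Non-converged
#' cells are recorded and the study continues.
#'
#' @param config A [study_config()].
#' @param quiet Suppress progress messages.
#' @return List of class `study_report` with `results` (one metrics row per
#'   cell), `summary` (cohort mean and SD per arm/MET/stenosis cell),
#'   `failures` (data.frame of failed cells), `config` and `cohort`.  When
#'   `config$out_dir` is set, `results.csv`, `summary.csv` and a JSON
#'   manifest are written there.
#' @export
run_study <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "study_config"))
  cohort <- if (config$cohort == "fixture")
    generate_cohort(4, trial_fixture = TRUE)
  else generate_cohort(config$n, seed = config$seed)
  rows <- list()
  failures <- list()
  for (p in cohort) {
    ref_traces <- list()
    for (met in config$met_levels) {
      cells <- c(0, config$stenosis_levels)
      for (lv in cells) {
        tag <- sprintf("%s/%s/met%g/sten%g", p$patient_id, config$arm, met, lv)
        res <- tryCatch({
          ref <- if (lv > 0) ref_traces[[as.character(met)]] else NULL
          sim <- simulate_patient(p, arm = config$arm, met = met,
                                  stenosis_level = lv, reference = ref,
                                  tol = config$tol)
          if (lv == 0) ref_traces[[as.character(met)]] <- sim$trace
          compute_metrics(sim)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          failures[[length(failures) + 1L]] <-
            data.frame(cell = tag, error = conditionMessage(res),
                       stringsAsFactors = FALSE)
          if (!quiet) message("FAILED ", tag, ": ", conditionMessage(res))
        } else {
          rows[[length(rows) + 1L]] <- res
          if (!quiet) message("done ", tag)
        }
      }
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else NULL
  summary <- if (!is.null(results)) summarize_study(results) else NULL
  out <- structure(list(results = results, summary = summary,
                        failures = if (length(failures))
                          do.call(rbind, failures) else NULL,
                        config = config, cohort = cohort),
                   class = "study_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(results, file.path(config$out_dir, "results.csv"),
              row.names = FALSE)
    write.csv(summary, file.path(config$out_dir, "summary.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(config = unclass(config),
           n_cells = if (is.null(results)) 0L else nrow(results),
           n_failures = if (is.null(out$failures)) 0L else nrow(out$failures),
           package_version = as.character(utils::packageVersion("fontanlpn"))),
      file.path(config$out_dir, "manifest.json"), auto_unbox = TRUE)
  }
  out
}

#' Cohort mean and SD per study cell
#'
#' @param results The per-condition results of [run_study()].
#' @return data.frame with mean and SD of every numeric metric per
#'   (arm, met, stenosis) cell.
#' @export
summarize_study <- function(results) {
  metric_cols <- c("min_diameter", "oer", "svo2_pct", "ci", "ivc_pressure",
                   "svc_pressure", "map", "pressure_gradient",
                   "energy_efficiency", "tawss", "osi", "green_strain",
                   "max_rt_cycles")
  key <- interaction(results$arm, results$met, results$stenosis_level,
                     drop = TRUE)
  do.call(rbind, lapply(split(results, key), function(d) {
    row <- data.frame(arm = d$arm[1], met = d$met[1],
                      stenosis_level = d$stenosis_level[1], n = nrow(d))
    for (m in metric_cols) {
      row[[paste0(m, "_mean")]] <- mean(d[[m]])
      row[[paste0(m, "_sd")]] <- stats::sd(d[[m]])
    }
    row
  }))
}

#' @export
print.study_report <- function(x, ...) {
  nr <- if (is.null(x$results)) 0L else nrow(x$results)
  nf <- if (is.null(x$failures)) 0L else nrow(x$failures)
  cat(sprintf("<study_report> arm %s: %d cells computed, %d failed\n",
              x$config$arm, nr, nf))
  invisible(x)
}

#' Two-term exponential trend fit
#'
#' Least-squares fit of `a*exp(b*x) + c*exp(d*x)` to a set of points, as
#' used to draw trend curves over sweep results.  Intended for
#' visualization only, never as a source of reported values.
#'
#' @param points data.frame with columns `x` and `y` (>= 5 points).
#' @return List with `coefficients` (a, b, c, d), `fitted`, `residuals`,
#'   `degenerate` (TRUE when the data do not constrain two exponential
#'   terms, e.g. constant data), and `predict(x)`.
#' @export
fit_trend <- function(points) {
  stopifnot(is.data.frame(points), all(c("x", "y") %in% names(points)))
  if (nrow(points) < 5) stop("need at least 5 points for a two-term fit")
  x <- points$x; y <- points$y
  if (stats::sd(y) < 1e-12 * max(1, abs(mean(y)))) {
    co <- c(a = mean(y), b = 0, c = 0, d = 0)
    pred <- function(xx) rep(mean(y), length(xx))
    return(list(coefficients = co, fitted = pred(x),
                residuals = y - pred(x), degenerate = TRUE, predict = pred))
  }
  obj <- function(th) {
    yhat <- th[1] * exp(th[2] * x) + th[3] * exp(th[4] * x)
    if (any(!is.finite(yhat))) return(1e30)
    sum((y - yhat)^2)
  }
  sx <- max(abs(x))
  starts <- list(c(mean(y), 0.5 / sx, -0.1 * mean(y), -2 / sx),
                 c(0.5 * y[1], 1 / sx, 0.5 * y[1], -1 / sx),
                 c(y[1], 0.1 / sx, 0, 0))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(optim(st, obj, method = "BFGS",
                          control = list(maxit = 2000, reltol = 1e-14)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("two-term exponential fit failed")
  th <- best$par
  pred <- function(xx) th[1] * exp(th[2] * xx) + th[3] * exp(th[4] * xx)
  list(coefficients = c(a = th[1], b = th[2], c = th[3], d = th[4]),
       fitted = pred(x), residuals = y - pred(x),
       degenerate = best$value > sum((y - mean(y))^2),
       predict = pred)
}

#' Export the velocity waveform at the stenosis throat
#'
#' Cross-section mean and peak axial velocity at the conduit throat per
#' time step, for comparison with external velocity measurements.
#'
#' @param trace An `lpn_trace`.
#' @param geometry A [graft_geometry()].
#' @param profile_factor Peak-to-mean velocity ratio (2 for a parabolic
#'   profile).
#' @return data.frame with `time` (s), `mean_velocity` and `peak_velocity`
#'   (cm/s).
#' @export
export_velocity_waveform <- function(trace, geometry, profile_factor = 2) {
  stopifnot(inherits(trace, "lpn_trace"), inherits(geometry, "graft_geometry"),
            profile_factor >= 1)
  a_s <- pi * (geometry$min_diameter / 10 / 2)^2
  vmean <- trace$q_gr / a_s
  data.frame(time = trace$time, mean_velocity = vmean,
             peak_velocity = profile_factor * vmean)
}
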