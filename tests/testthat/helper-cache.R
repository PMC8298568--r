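# Shared, lazily computed simulation fixtures.  Heavy runs (the trial-cohort
# panel, reference traces) are computed once per test session and reused
# across test files.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) assign(key, expr, envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# Metric rows for the four trial patients (measured geometry arm) at one MET.
fixture_panel <- function(met, arm = "mri") {
  cached(sprintf("panel_%s_met%g", arm, met), {
    do.call(rbind, lapply(trial_cohort("MRI I"), function(p)
      compute_metrics(simulate_patient(p, arm = arm, met = met))))
  })
}

# One converged resting trace for a mid-size trial patient.
fixture_rest_sim <- function() {
  cached("rest_sim", {
    p <- trial_cohort("MRI I")[[1]]
    simulate_patient(p, arm = "mri", met = 1)
  })
}

# The independent closed-form oxygenation relation used as an oracle:
# written out from the printed formulas, separately from the implementation.
oracle_oer <- function(met, weight, co)
  (met * 6.5 * weight) / (((13.26 * 1.34 * 0.94) + 0.003 * 90) * 10 * co)

oracle_svo2 <- function(met, weight, co)
  0.94 - ((met * 6.5 * weight / co) + 0.03 * (90 - 40)) / (13.26 * 1.34 * 10)
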