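test_that("oxygen extraction ratio matches its printed closed form", {
  expect_equal(as.numeric(oer(0, 12, 1.79)), 0)
  # met 1, 12 kg, CO 1.79 L/min: 78 / 303.8 = 0.257
  expect_equal(as.numeric(oer(1, 12, 1.79)), 78 / 303.80409, tolerance = 1e-6)
  expect_equal(as.numeric(oer(1, 12, 1.79)), 0.257, tolerance = 1e-3)
  expect_false(attr(oer(1, 12, 1.79), "nonphysiologic"))
  # met 5, 12 kg, CO 2.0: 1.149, beyond full extraction
  o <- oer(5, 12, 2.0)
  expect_equal(as.numeric(o), 1.149, tolerance = 1e-3)
  expect_true(attr(o, "nonphysiologic"))
  expect_error(oer(1, 12, 0), "positive")
})

test_that("venous saturation matches its printed closed form and flags", {
  # zero-extraction limit with equal partial pressures
  k <- oxygen_constants(po2_venous = 90)
  expect_equal(as.numeric(svo2(0, 12, 2, k)), 0.94)
  # met*6.5*weight/co = 45: 0.94 - 46.5/177.684 = 0.678
  expect_equal(as.numeric(svo2(1, 45, 6.5)), 0.94 - 46.5 / 177.684,
               tolerance = 1e-9)
  expect_equal(as.numeric(svo2(1, 45, 6.5)), 0.678, tolerance = 1e-3)
  s <- svo2(5, 12, 1)
  expect_true(as.numeric(s) < 0)
  expect_true(attr(s, "nonphysiologic"))
  expect_error(svo2(1, 12, -1), "positive")
})

test_that("the two Fick estimates satisfy their exact algebraic relation", {
  # sVO2 = saO2 - (OER*D1 + 0.03*(PO2a - PO2v)) / (hb*1.34*10), with
  # D1 the OER denominator per unit CO.  Checked over random inputs and
  # against independent closed-form oracles.
  set.seed(7)
  for (i in 1:200) {
    met <- runif(1, 0, 6); w <- runif(1, 8, 30); co <- runif(1, 0.5, 8)
    o <- as.numeric(oer(met, w, co))
    s <- as.numeric(svo2(met, w, co))
    D1 <- ((13.26 * 1.34 * 0.94) + 0.003 * 90) * 10
    expect_equal(s, 0.94 - (o * D1 + 0.03 * 50) / (13.26 * 1.34 * 10),
                 tolerance = 1e-12)
    expect_equal(o, oracle_oer(met, w, co), tolerance = 1e-12)
    expect_equal(s, oracle_svo2(met, w, co), tolerance = 1e-12)
  }
})

test_that("both printed dissolved-oxygen coefficients are preserved", {
  k <- oxygen_constants()
  expect_identical(k$dissolved_oer, 0.003)
  expect_identical(k$dissolved_svo2, 0.03)
  h <- oxygen_constants(harmonize_dissolved = 0.003)
  expect_identical(h$dissolved_svo2, 0.003)
})

test_that("cardiac index agrees with mean aortic flow on a converged run", {
  # flow-volume consistency: without respiratory modulation the per-cycle
  # volume swing must equal the integrated aortic flow
  tr0 <- cached("rest_noresp", run_to_periodic(lpn_parameters(resp_amp = 0)))
  ci0 <- cardiac_index(tr0, 0.67)
  expect_equal(ci0, unname(trace_summary(tr0)["co"]) / 0.67,
               tolerance = 0.01)
  # with breathing the respiratory-averaged definition stays within a few
  # percent of the mean-flow estimate
  sim <- fixture_rest_sim()
  ci <- cardiac_index(sim$trace, sim$patient$bsa)
  expect_equal(ci, unname(trace_summary(sim$trace)["co"]) / sim$patient$bsa,
               tolerance = 0.05)
  # SV = 25 mL, HR = 90, BSA = 0.67 arithmetic check of the formula itself
  expect_equal(25 * 90 / 0.67 / 1000, 3.358, tolerance = 1e-3)
})

test_that("energy efficiency is 100% for identical surfaces and follows the
          worked steady case", {
  tm <- seq(0, 1, by = 0.01)
  surf <- function(p, q, a) data.frame(time = tm, p = p, q = q, area = a)
  expect_equal(energy_efficiency(list(surf(13, 20, 2)),
                                 list(surf(13, 20, 2))), 100)
  # steady Q = 20 mL/s, 13.7 -> 13.0 mmHg, equal (large) areas: 94.89%
  eff <- energy_efficiency(list(surf(13.7, 20, 1e6)),
                           list(surf(13.0, 20, 1e6)))
  expect_equal(eff, 100 * 13.0 / 13.7, tolerance = 1e-6)
  expect_equal(eff, 94.9, tolerance = 1e-3)
  # a pure added pressure drop lowers efficiency monotonically
  effs <- vapply(c(0, 0.3, 0.8, 2), function(dp)
    energy_efficiency(list(surf(13.7, 20, 2)), list(surf(13.7 - dp, 20, 2))),
    numeric(1))
  expect_true(all(diff(effs) < 0))
  expect_error(energy_efficiency(list(surf(0, 0, 2)), list(surf(0, 0, 2))),
               "inlet energy")
})

test_that("TAWSS matches closed forms on analytic fields", {
  tm <- seq(0, 1, length.out = 201)[-201]
  const <- wss_field(tm, matrix(7.3, 3, 200), period = 1)
  expect_equal(tawss(const), 7.3)
  pois <- analytic_flow_fixture("poiseuille", Q = 20, r = 0.8)
  expect_equal(tawss(pois$field), 1.99, tolerance = 2e-3)
  sine <- wss_field(tm, matrix(sin(2 * pi * tm), 1, byrow = TRUE), period = 1)
  expect_equal(tawss(sine), 2 / pi, tolerance = 5e-3)
})

test_that("OSI spans its closed-form landmarks and stays within [0, 0.5]", {
  tm <- seq(0, 1, length.out = 401)[-401]
  uni <- wss_field(tm, matrix(2 + sin(2 * pi * tm), 1, byrow = TRUE))
  expect_equal(osi(uni), 0, tolerance = 1e-9)
  square <- wss_field(tm, matrix(ifelse(tm < 0.5, 1, -1), 1, byrow = TRUE),
                      period = 1)
  expect_equal(osi(square), 0.5, tolerance = 1e-6)
  # +1 for 3T/4, -1 for T/4: 0.5*(1 - 0.5/1) = 0.25
  skew <- wss_field(tm, matrix(ifelse(tm < 0.75, 1, -1), 1, byrow = TRUE),
                    period = 1)
  expect_equal(osi(skew), 0.25, tolerance = 1e-6)
  # identically-zero shear is defined as no oscillation
  expect_equal(osi(wss_field(tm, matrix(0, 2, 400))), 0)
  set.seed(11)
  for (i in 1:50) {
    f <- wss_field(tm, matrix(rnorm(3 * 400), 3, 400), period = 1)
    v <- osi(f)
    expect_gte(v, 0); expect_lte(v, 0.5)
  }
})

test_that("long-format shear tables round-trip into fields", {
  fx <- analytic_flow_fixture("poiseuille", Q = 20, r = 0.8)
  fld <- wss_field_from_table(fx$table, period = fx$field$period)
  expect_equal(tawss(fld), tawss(fx$field))
  expect_equal(osi(fld), osi(fx$field))
  # vector components: magnitude with the sign of the primary direction
  tab <- fx$table
  tab$wss_x <- tab$wss; tab$wss_y <- 0; tab$wss_z <- 0; tab$wss <- NULL
  fld2 <- wss_field_from_table(tab, period = fx$field$period)
  expect_equal(tawss(fld2), tawss(fld))
  expect_error(wss_field_from_table(data.frame(location = 1, time = 0)),
               "wss")
})

test_that("Green strain invariant reproduces hand-computed tensors", {
  I3 <- array(diag(3), c(3, 3, 1))
  expect_equal(green_strain_invariant(I3), 0)
  F1 <- array(diag(c(1.1, 1, 1)), c(3, 3, 1))
  expect_equal(green_strain_invariant(F1), 0.105, tolerance = 1e-9)
  F2 <- array(diag(c(1.1, 0.9, 1)), c(3, 3, 1))
  expect_equal(green_strain_invariant(F2), 0.01, tolerance = 1e-9)
  bad <- array(diag(c(-1, 1, 1)), c(3, 3, 1))
  expect_error(green_strain_invariant(bad), "determinant")
  # several locations average; time series average magnitude
  two_t <- array(c(diag(3), diag(c(1.1, 1, 1))), c(3, 3, 2))
  expect_equal(green_strain_invariant(two_t), 0.105 / 2)
})

test_that("plug-flow residence time equals the transit time", {
  rt <- max_residence_time(u = 10, length = 5, period = 1)
  expect_true(rt$damped)
  expect_false(rt$stagnant)
  expect_equal(rt$rt_cycles, 0.5, tolerance = 0.02)
})

test_that("a near-wall parabolic streamline matches its analytic transit", {
  # u(0.9R) = 2*(1 - 0.81)*u_mean = 0.38*u_mean
  u_mean <- 20
  u_wall <- 2 * (1 - 0.9^2) * u_mean
  rt <- max_residence_time(u = u_wall, length = 5, period = 1)
  expect_equal(rt$rt_cycles, 5 / (0.38 * u_mean), tolerance = 0.05)
})

test_that("a stagnant region is capped and flagged", {
  expect_warning(rt <- max_residence_time(u = 0, length = 5, period = 1,
                                          n_cycles = 4),
                 NA)  # capping marks stagnation without warning noise
  expect_true(rt$stagnant)
})

test_that("pressure gradients read respiratory-cycle-mean differences", {
  sim <- fixture_rest_sim()
  expect_equal(pressure_gradient(sim$trace, "p_ivc", "p_ivc"), 0)
  expect_error(pressure_gradient(sim$trace, "p_xyz"), "not in trace")
  # synthetic trace with an imposed 0.7 mmHg offset
  tm <- seq(0, 3, by = 0.01)
  fake <- structure(
    data.frame(time = tm, p_ivc = 13.7 + sin(tm), p_pa = 13.0 + sin(tm)),
    class = c("lpn_trace", "data.frame"))
  expect_equal(pressure_gradient(fake), 0.7, tolerance = 1e-9)
})

test_that("trace gradients agree with the quasi-steady loss law", {
  p <- trial_cohort("MRI I")[[2]]
  sim <- cached("p2_sten03", simulate_patient(p, met = 1, stenosis_level = 0.3))
  q_mean <- fontanlpn:::cycle_mean(sim$trace$time, sim$trace$q_gr)
  dp_quasi <- stenosis_pressure_loss(sim$graft, q_mean)
  dp_trace <- pressure_gradient(sim$trace)
  expect_equal(dp_trace, dp_quasi, tolerance = 0.1)
})
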