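test_that("ring-test pressure follows P = mg/(2wr) with unit conversion", {
  s0 <- ring_sample(mass = 0, width = 0.5, length = 0.8 * pi, volume0 = 0.4)
  expect_equal(ring_pressure(s0), 0)
  # m = 50 g, g = 981, w = 0.5 cm, r = 0.8 cm: 61312.5 dyn/cm2 = 45.99 mmHg
  s <- ring_sample(mass = 50, width = 0.5, length = 0.8 * pi, volume0 = 0.4)
  expect_equal(s$radius, 0.8)
  expect_equal(ring_pressure(s), 50 * 981 / (2 * 0.5 * 0.8) / 1333.22)
  expect_equal(ring_pressure(s), 45.99, tolerance = 1e-4)
  s2 <- ring_sample(mass = 50, width = 1.0, length = 0.8 * pi, volume0 = 0.4)
  expect_equal(ring_pressure(s2), ring_pressure(s) / 2)
})

test_that("ring stress-stretch uses incompressibility for thickness", {
  s <- ring_sample(mass = 0, width = 0.5, length = 1.2, length0 = 1.2,
                   volume0 = 0.3)
  expect_equal(unname(ring_stress_stretch(s)), c(0, 1))
  expect_equal(s$thickness, 0.3 / (2 * pi * (1.2 / pi) * 0.5))
  # doubling r at fixed w and V0 halves h, doubling the stress
  a <- ring_sample(mass = 20, width = 0.5, length = 1.0, length0 = 1.0,
                   volume0 = 0.3)
  b <- ring_sample(mass = 20, width = 0.5, length = 2.0, length0 = 1.0,
                   volume0 = 0.3)
  expect_equal(b$thickness, a$thickness / 2)
  expect_equal(ring_stress_stretch(b)[["stress"]],
               2 * ring_stress_stretch(a)[["stress"]])
  expect_equal(ring_stress_stretch(b)[["stretch"]], 2)
  # independent hand computation: stress = mg/(2wh)
  expect_equal(ring_stress_stretch(a)[["stress"]],
               20 * 981 / (2 * 0.5 * a$thickness))
})

test_that("secant stiffness between 5 and 50 mmHg recovers known slopes", {
  d <- seq(0.05, 3, length.out = 100)
  expect_equal(stiffness_from_curve(data.frame(pressure = 30 * d, diameter = d)),
               30)
  expect_error(stiffness_from_curve(data.frame(pressure = c(10, 40),
                                               diameter = c(1, 2))),
               "span")
  # nonlinear (stiffening) curve vs a secant oracle computed by hand
  p <- seq(0, 80, length.out = 400)
  dd <- 1 + 0.02 * p + 0.0005 * p^2
  curve <- data.frame(pressure = p, diameter = dd)
  d5 <- 1 + 0.02 * 5 + 0.0005 * 25
  d50 <- 1 + 0.02 * 50 + 0.0005 * 2500
  expect_equal(stiffness_from_curve(curve), 45 / (d50 - d5), tolerance = 1e-2)
  # stiffness ratio (percent difference) is a plain ratio of slopes
  d6 <- seq(0.05, 6, length.out = 100)
  soft <- data.frame(pressure = 10 * d6, diameter = d6)
  stiff <- data.frame(pressure = 53.3 * d6, diameter = d6)
  expect_equal(100 * (stiffness_from_curve(stiff) / stiffness_from_curve(soft) - 1),
               433, tolerance = 1e-6)
})

test_that("burst pressure is the pressure at the failure weight", {
  series <- data.frame(mass = c(10, 20, 40), length = c(1, 1.1, 1.3),
                       failed = c(FALSE, FALSE, TRUE))
  bp <- burst_pressure(series, width = 0.5, volume0 = 0.3)
  hand <- 40 * 981 / (2 * 0.5 * (1.3 / pi)) / 1333.22
  expect_equal(bp, hand)
  first <- data.frame(mass = 5, length = 0.9, failed = TRUE)
  expect_equal(burst_pressure(first, width = 0.5, volume0 = 0.3),
               5 * 981 / (2 * 0.5 * (0.9 / pi)) / 1333.22)
  expect_error(burst_pressure(data.frame(mass = 1, length = 1, failed = FALSE),
                              width = 0.5, volume0 = 0.3), "failure")
  # monotone loading: burst equals the maximum achieved pressure
  ps <- vapply(seq_len(nrow(series)), function(i)
    ring_pressure(ring_sample(series$mass[i], 0.5, series$length[i],
                              length0 = 1, volume0 = 0.3)), numeric(1))
  expect_equal(bp, max(ps))
})

test_that("wall-modulus tuning round-trips the four trial moduli within 1%", {
  geom <- graft_geometry(16, 9)
  wave <- 13.5 + 2 * sin(seq(0, 2 * pi, length.out = 80))
  for (E in c(8.00, 13.14, 16.00, 14.72)) {
    fac <- fractional_area_change(E, wave, geom)
    fit <- tune_wall_modulus(fac, wave, geom)
    expect_true(fit$converged)
    expect_equal(fit$modulus, E, tolerance = 0.01)
  }
})

test_that("area response is monotone in modulus and bounded targets error", {
  geom <- graft_geometry(16, 9)
  wave <- c(12, 16)
  E <- seq(2, 100, length.out = 40)
  fac <- vapply(E, fractional_area_change, numeric(1),
                pressure_waveform = wave, geometry = geom)
  expect_true(all(diff(fac) < 0))   # stiffer wall deforms less
  # a vanishing target drives the root to the stiff limit and out of bounds
  expect_error(tune_wall_modulus(1e-6, wave, geom, bounds = c(0.5, 500)),
               "unattainable")
  expect_error(tune_wall_modulus(0, wave, geom))
})

test_that("stenosis loss reduces to Poiseuille with no constriction", {
  g <- graft_geometry(16, 16, graft_length = 50)
  m <- graft_segment(g)
  mu <- 0.04
  for (Q in c(5, 20, 60)) {
    hand <- 8 * mu * 5 * Q / (pi * 0.8^4) / 1333.22
    expect_equal(stenosis_pressure_loss(m, Q), hand, tolerance = 1e-3)
  }
  expect_equal(stenosis_pressure_loss(m, 0), 0)
  co <- graft_loss_coefficients(m)
  expect_equal(co$K, 0)
})

test_that("stenosis loss is odd in flow and monotone in severity and flow", {
  g <- graft_geometry(16, 9.6, graft_length = 50, stenosis_length = 20)
  m <- graft_segment(g)
  for (Q in c(1, 10, 35))
    expect_equal(stenosis_pressure_loss(m, -Q), -stenosis_pressure_loss(m, Q))
  Qs <- seq(1, 60, by = 1)
  dp <- vapply(Qs, function(q) stenosis_pressure_loss(m, q), numeric(1))
  expect_true(all(diff(dp) > 0))
  lv <- seq(0.1, 0.8, by = 0.1)
  dp_lv <- vapply(stenosis_series(graft_geometry(16, 16), lv), function(gg)
    stenosis_pressure_loss(graft_segment(gg), 20), numeric(1))
  expect_true(all(diff(dp_lv) > 0))
  expect_error(graft_geometry(16, 0))  # a closed lumen is rejected outright
})

test_that("the worked two-term loss value matches an independent evaluation", {
  # min 9.6 mm, nominal 16 mm, Q = 20 mL/s, defaults kv = 128/pi, kt = 1.52
  m <- graft_segment(graft_geometry(16, 9.6, graft_length = 50,
                                    stenosis_length = 20))
  # independent spreadsheet-style evaluation, CGS step by step:
  # viscous: (128/pi)*0.04*2.0/0.96^4 * Q + (128/pi)*0.04*3.0/1.6^4 * Q
  # expansion: 1.52*(1.06/2)*(A0/As-1)^2 * (Q/As)^2 with
  #   A0 = pi*0.8^2, As = pi*0.48^2
  visc <- (128 / pi) * 0.04 * (2.0 / 0.96^4 + 3.0 / 1.6^4) * 20
  A0 <- pi * 0.8^2; As <- pi * 0.48^2
  expn <- 1.52 * (1.06 / 2) * (A0 / As - 1)^2 * (20 / As)^2
  expect_equal(stenosis_pressure_loss(m, 20), (visc + expn) / 1333.22,
               tolerance = 1e-10)
})

test_that("Laplace compliance scales as 3*pi*r^3*L/(2Eh) and is 0 when rigid", {
  rigid <- graft_segment(graft_geometry(16, 16, rigid_wall = TRUE))
  expect_equal(graft_compliance(rigid), 0)
  m1 <- graft_segment(graft_geometry(16, 16), elastic_modulus = 10)
  m2 <- graft_segment(graft_geometry(16, 16), elastic_modulus = 20)
  expect_equal(graft_compliance(m1), 2 * graft_compliance(m2))
  # hand evaluation: r = 0.8 cm, L = 5 cm, h = 0.15 cm, E = 1e5 dyn/cm2
  hand <- 3 * pi * 0.8^3 * 5 / (2 * 1e5 * 0.15) * 1333.22
  expect_equal(graft_compliance(m1), hand)
})
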