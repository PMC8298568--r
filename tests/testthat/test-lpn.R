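test_that("elastance spans [E_min, E_max] smoothly with the cardiac period", {
  p <- lpn_parameters()
  T_card <- 60 / p$hr
  expect_equal(elastance(p$t1_frac * T_card, p), p$e_max)
  expect_equal(elastance(0.9 * T_card, p), p$e_min)   # diastole
  expect_equal(elastance(0, p), p$e_min)
  expect_equal(elastance(0.2, p), elastance(0.2 + 3 * T_card, p))
  # mean over one period equals the quadrature of the activation shape
  act <- function(s) {
    t1 <- p$t1_frac; t2 <- p$t2_frac
    ifelse(s < t1, 0.5 * (1 - cos(pi * s / t1)),
           ifelse(s < t2, 0.5 * (1 + cos(pi * (s - t1) / (t2 - t1))), 0))
  }
  mean_oracle <- p$e_min + (p$e_max - p$e_min) *
    stats::integrate(act, 0, 1, subdivisions = 2000)$value
  tt <- seq(0, T_card, length.out = 20001)[-20001]
  expect_equal(mean(elastance(tt, p)), mean_oracle, tolerance = 1e-4)
})

test_that("respiratory pressure is zero-mean and modulates caval flow", {
  p <- lpn_parameters()
  tt <- seq(0, p$t_resp, length.out = 1201)[-1201]
  expect_equal(mean(respiratory_pressure(tt, p)), 0, tolerance = 1e-12)
  p0 <- lpn_parameters(resp_amp = 0)
  expect_true(all(respiratory_pressure(tt, p0) == 0))

  tr <- run_to_periodic(p)
  tr0 <- run_to_periodic(p0)
  # spectral line at the respiratory frequency appears only with breathing
  power_at_resp <- function(tr) {
    q <- tr$q_gr[-nrow(tr)]
    Mod(fft(q - mean(q)))[2]  # first harmonic of the record = 1/T_resp
  }
  expect_gt(power_at_resp(tr), 50 * max(1e-12, power_at_resp(tr0)))
  # amplitude 0 reproduces the no-respiration trace
  tr0b <- run_to_periodic(p0)
  expect_identical(tr0$p_ao, tr0b$p_ao)
})

test_that("the network conserves volume exactly and at every instant", {
  p <- lpn_parameters()
  st <- lpn_initial_state(p)
  expect_equal(sum(st), p$stressed_volume)
  # flow conservation: derivatives sum to zero at arbitrary states/times
  set.seed(3)
  for (i in 1:20) {
    s <- runif(9, 1, 80)
    d <- lpn_rhs(s, runif(1, 0, 3), p)
    expect_lt(abs(sum(d$derivs)), 1e-10)
  }
  tr <- run_to_periodic(p)
  vol <- rowSums(tr[, c("v_v", "v_at", "v_ao", "v_ub", "v_svc", "v_lb",
                        "v_ivc", "v_pa", "v_pul")])
  drift <- (max(vol) - min(vol)) / p$stressed_volume
  expect_lt(drift, 1e-3)  # < 0.1% over the cycle
})

test_that("valve branches never carry meaningfully negative flow", {
  tr <- run_to_periodic(lpn_parameters())
  eps <- 1e-2  # mL/s, the smoothed-diode leak scale
  expect_gt(min(tr$q_av), -eps)
  expect_gt(min(tr$q_vao), -eps)
})

test_that("symmetric pulmonary branches split flow equally", {
  p <- lpn_parameters()
  expect_equal(p$r_lpa, p$r_rpa)
  tr <- run_to_periodic(p)
  expect_equal(tr$q_lpa, tr$q_rpa, tolerance = 1e-12)
})

test_that("an isolated RC discharge follows the analytic exponential", {
  skip_if_not_installed("deSolve")
  # cut every path except pulmonary veins -> atrium; constant elastance,
  # linear valves, no respiration: a pure two-capacitor RC discharge
  p <- lpn_parameters(resp_amp = 0, linear_valves = 1,
                      e_max = 0.35 + 1e-9, e_min = 0.35)
  big <- 1e9
  for (nm in c("r_av", "r_vao", "r_ub_a", "r_ub_v", "r_svc", "r_lb_a",
               "r_lb_v", "r_gr", "r_lpa", "r_rpa")) p[[nm]] <- big
  c_pul <- p$c_pul; c_at <- 1 / p$e_at
  tau <- p$r_pv * (c_pul * c_at) / (c_pul + c_at)
  y0 <- setNames(c(10, 10, 10, 10, 10, 10, 10, 10, 40), names(lpn_initial_state(p)))
  sol <- deSolve::lsoda(
    y = y0, times = seq(0, 3 * tau, length.out = 31),
    func = function(t, y, parms) list(lpn_rhs(y, t, p)$derivs),
    rtol = 1e-10, atol = 1e-10)
  dp0 <- 40 / c_pul - 10 * p$e_at
  dp <- sol[, "v_pul"] / c_pul - sol[, "v_at"] * p$e_at
  expect_equal(dp, dp0 * exp(-sol[, "time"] / tau), tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("the DC limit relaxes to the uniform-pressure linear solution", {
  # constant elastance, linear valves, no respiration: a source-free linear
  # RC network whose steady state has equal node pressures and zero flows
  p <- lpn_parameters(resp_amp = 0, linear_valves = 1,
                      e_max = 0.35 + 1e-9, e_min = 0.35)
  tr <- run_to_periodic(p, max_cycles = 300)
  caps <- c(1 / 0.35, 1 / p$e_at, p$c_ao, p$c_ub, p$c_svc, p$c_lb, p$c_ivc,
            p$c_pa, p$c_pul)
  p_eq <- p$stressed_volume / sum(caps)   # linear-algebra steady state
  pr <- unlist(tr[nrow(tr), c("p_v", "p_at", "p_ao", "p_ub", "p_svc",
                              "p_lb", "p_ivc", "p_pa", "p_pul")])
  expect_equal(unname(pr), rep(p_eq, 9), tolerance = 1e-3)
  flows <- unlist(tr[nrow(tr), c("q_ua", "q_uv", "q_svc", "q_la", "q_lv",
                                 "q_gr", "q_lpa", "q_rpa", "q_pv")])
  expect_true(all(abs(flows) < 1e-2))
})

test_that("near-zero elastance amplitude produces no stroke volume", {
  p <- lpn_parameters(e_max = 0.35 + 1e-9, e_min = 0.35, resp_amp = 0)
  tr <- run_to_periodic(p, max_cycles = 300)
  s <- trace_summary(tr)
  expect_lt(s[["sv"]], 0.1)
  expect_lt(abs(s[["co"]]), 0.05)
})

test_that("identical inputs give identical traces; tolerances agree", {
  p <- lpn_parameters(bsa = 0.6)
  a <- run_to_periodic(p)
  b <- run_to_periodic(p)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # refinement: tol 1e-3 vs 1e-4 changes cycle-mean pressures < 0.5%
  s3 <- trace_summary(run_to_periodic(p, tol = 1e-3))
  s4 <- trace_summary(run_to_periodic(p, tol = 1e-4, max_cycles = 200))
  for (nm in c("map", "ivc_pressure", "svc_pressure", "pa_pressure"))
    expect_equal(s3[[nm]], s4[[nm]], tolerance = 5e-3)
})

test_that("heart period snaps to a divisor of the respiratory period", {
  p <- lpn_parameters(hr = 90, t_resp = 3)
  expect_equal((p$t_resp / (60 / p$hr)) %% 1, 0, tolerance = 1e-12)
  expect_equal(p$hr_nominal, 90)
  p2 <- apply_met(lpn_parameters(), 5)
  expect_equal((p2$t_resp / (60 / p2$hr)) %% 1, 0, tolerance = 1e-12)
})

test_that("non-finite states are reported as integration failures", {
  p <- lpn_parameters()
  expect_error(lpn_rhs(c(NaN, rep(10, 8)), 0, p), "non-finite")
})

test_that("an unconvergeable configuration fails with diagnostics", {
  p <- lpn_parameters()
  expect_error(run_to_periodic(p, tol = 1e-12, max_cycles = 5),
               "periodic state")
})
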