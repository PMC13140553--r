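# curve families for pairing fixtures: tents peaked at t = 10
tent <- function(t0, r0, rpk, r1, t1) {
  force(t0); force(t1)
  function(t) ifelse(t <= 10, r0 + (rpk - r0) * (t - t0) / (10 - t0),
                     rpk - (rpk - r1) * (t - 10) / (t1 - 10))
}

test_that("each pairing criterion is individually necessary", {
  ctrl <- make_sr(tent(1, 8, 14, 6, 19), 1, 19)
  test_ok <- make_sr(tent(4, 9, 13, 8, 16), 4, 16)

  base <- pair_units(list(c = ctrl, t = test_ok))
  expect_equal(nrow(base), 1L)
  expect_equal(base$control_id, "c")
  expect_equal(unname(attr(base, "rejections")), rep(0L, 4))

  # (i) uncorrelated test curve -> rejected on r_rate only
  wig <- make_sr(function(t) 10 + sin(5 * t), 4, 16)
  p1 <- pair_units(list(c = ctrl, t = wig))
  expect_equal(nrow(p1), 0L)
  expect_equal(attr(p1, "rejections")[["r_rate"]], 1L)
  expect_equal(sum(attr(p1, "rejections")), 1L)

  # (ii) recruitment gap 0.8 s -> rejected on recruit_gap only
  close_t <- make_sr(tent(1.8, 9, 13, 8, 16), 1.8, 16)
  p2 <- pair_units(list(c = ctrl, t = close_t))
  expect_equal(nrow(p2), 0L)
  expect_equal(attr(p2, "rejections")[["recruit_gap"]], 1L)
  expect_equal(sum(attr(p2, "rejections")), 1L)

  # (iii) control with < 0.5 pps modulation after test recruitment
  flat_c <- make_sr(function(t) 10 + 0.02 * (t - 1), 1, 19)
  rising_t <- make_sr(function(t) 9 + (t - 4) / 3, 4, 16)
  p3 <- pair_units(list(c = flat_c, t = rising_t))
  expect_equal(nrow(p3), 0L)
  expect_equal(attr(p3, "rejections")[["control_mod"]], 1L)
  expect_equal(sum(attr(p3, "rejections")), 1L)

  # (iv) test unit outlasting the control
  late_t <- make_sr(tent(4, 9, 13, 8, 19.5), 4, 19.5)
  p4 <- pair_units(list(c = ctrl, t = late_t))
  expect_equal(nrow(p4), 0L)
  expect_equal(attr(p4, "rejections")[["derec_order"]], 1L)
  expect_equal(sum(attr(p4, "rejections")), 1L)
})

test_that("threshold sweeps around each criterion flip acceptance", {
  ctrl <- make_sr(tent(1, 8, 14, 6, 19), 1, 19)
  test_ok <- make_sr(tent(4, 9, 13, 8, 16), 4, 16)
  base <- pair_units(list(c = ctrl, t = test_ok))
  # tightening any single criterion beyond the pair's measured value removes it
  expect_equal(nrow(pair_units(list(c = ctrl, t = test_ok),
    pairing_criteria(r_min = base$r_rate + 0.01))), 0L)
  expect_equal(nrow(pair_units(list(c = ctrl, t = test_ok),
    pairing_criteria(gap_min = base$recruit_gap + 0.1))), 0L)
  expect_equal(nrow(pair_units(list(c = ctrl, t = test_ok),
    pairing_criteria(mod_min = base$control_mod + 0.1))), 0L)
})

test_that("delta F reads the control curve at the test unit's landmarks", {
  ctrl <- make_sr(function(t) 10 - 2.5 * (t - 4) / 12, 1, 19)
  tst <- make_sr(function(t) 11 + 0 * t, 4, 16)
  expect_equal(delta_f(ctrl, tst), 2.5, tolerance = 1e-9)

  flat <- make_sr(function(t) 9 + 0 * t, 1, 19)
  expect_equal(delta_f(flat, tst), 0)

  outlast <- make_sr(function(t) 11 + 0 * t, 4, 19.5)
  expect_error(delta_f(ctrl, outlast), "criterion")
})

test_that("per-test-unit delta F is the unweighted pairwise mean", {
  expect_equal(delta_f_per_test_unit(c(2, 3)), 2.5)
  expect_equal(delta_f_per_test_unit(4.2), 4.2)
  expect_equal(delta_f_per_test_unit(c(1, 2, 6)), 3)  # no outlier trimming
  expect_true(is.na(delta_f_per_test_unit(numeric(0))))
  set.seed(1)
  v <- rnorm(7)
  expect_equal(delta_f_per_test_unit(v), delta_f_per_test_unit(sample(v)))
})

test_that("brace height matches the analytic unit-square geometry", {
  x <- seq(0, 1, by = 1e-4)
  # chord-linear curve scores zero
  expect_equal(brace_height(make_asc(x, 8 + 6 * x))$brace_height, 0,
               tolerance = 1e-9)
  # instant rise to plateau passes through the right-angle vertex: 100
  expect_equal(brace_height(make_asc(x, c(0, rep(1, length(x) - 1))))$brace_height,
               100, tolerance = 0.1)
  # y = sqrt(x): analytic maximum of (sqrt(x) - x)/sqrt(2) at x = 1/4
  g <- brace_height(make_asc(x, sqrt(x)))
  expect_equal(g$brace_height, 25.0, tolerance = 0.1)
  expect_equal(g$insertion_time, 0.25, tolerance = 1e-3)
  # brute-force oracle: direct point-to-line distance maximisation
  d_bf <- max((sqrt(x) - x) / sqrt(2))
  expect_equal(g$brace_height, 100 * sqrt(2) * d_bf, tolerance = 1e-6)
  # convex curve never rises above the chord: zero, not negative
  expect_equal(brace_height(make_asc(x, x^2))$brace_height, 0, tolerance = 1e-6)
})

test_that("brace height is invariant to separate affine rescaling of each axis", {
  x <- seq(0, 1, by = 1e-3)
  shapes <- list(sqrt, function(u) u^0.3, function(u) sin(pi * u / 2))
  set.seed(42)
  for (f in shapes) {
    ref <- brace_height(make_asc(x, f(x)))$brace_height
    for (k in 1:5) {
      a <- runif(1, 0.1, 50); b <- runif(1, -20, 20)
      cc <- runif(1, 0.1, 50); d <- runif(1, -20, 20)
      got <- brace_height(make_asc(a * x + b, cc * f(x) + d))$brace_height
      expect_equal(got, ref, tolerance = 1e-9)
    }
    expect_gte(ref, 0); expect_lte(ref, 100)
  }
})

test_that("degenerate ascending segments yield no geometry", {
  g <- brace_height(structure(list(time = 1, rate = 5, degenerate = TRUE),
                              class = "ascending_phase"))
  expect_true(is.na(g$brace_height))
  # zero rate range
  x <- seq(0, 1, by = 0.01)
  expect_true(is.na(brace_height(make_asc(x, rep(3, length(x))))$brace_height))
})

test_that("attenuation slope is the OLS rate-vs-torque slope over the window", {
  tq <- structure(list(time = seq(0, 4, by = 0.01),
                       torque_pct = 10 + 2 * seq(0, 4, by = 0.01), fs = 100),
                  class = "filtered_torque")
  asc <- make_asc(seq(0, 4, by = 0.01), 12 + seq(0, 4, by = 0.01))
  expect_equal(attenuation_slope(asc, 0, tq), 0.5, tolerance = 1e-9)

  flat <- make_asc(seq(0, 4, by = 0.01), rep(15, 401))
  expect_equal(attenuation_slope(flat, 0, tq), 0, tolerance = 1e-9)

  # saturating rate over the same torque window attenuates the slope
  satur <- make_asc(seq(0, 4, by = 0.01), 12 + 4 * (1 - exp(-seq(0, 4, by = 0.01))))
  expect_lt(attenuation_slope(satur, 0, tq), attenuation_slope(asc, 0, tq))

  expect_true(is.na(attenuation_slope(asc, 3.99, tq)))  # < 3 samples
})

test_that("thresholds read the filtered torque at the firing landmarks", {
  tr <- ideal_trial(peak = 10)  # triangle to 20% of 10 N·m
  ft <- filter_torque(tr)
  # unit recruited when torque = 2.0 N·m (= 20% of peak) i.e. at t = 10
  sr <- make_sr(function(t) 10 + 0 * t, 10, 15)
  th <- unit_thresholds(sr, ft)
  expect_equal(th$recruitment_threshold, 20, tolerance = 0.1)
  expect_equal(th$derecruitment_threshold, 10, tolerance = 0.1)
  expect_equal(th$peak_discharge_rate, 10)

  # recruited at ramp onset: threshold ~ 0
  sr0 <- make_sr(function(t) 8 + 0 * t, 0, 5)
  expect_lt(unit_thresholds(sr0, ft)$recruitment_threshold, 0.5)

  sr_out <- make_sr(function(t) 8 + 0 * t, 10, 25)
  expect_error(unit_thresholds(sr_out, ft), "outside")
})

test_that("simulated units recover their drive thresholds at zero noise", {
  cfg <- pool_config(n_participants = 1, units_per_trial = 2,
                     threshold_range = c(8, 8), isi_cv = 0,
                     hysteresis_mean = 2, hysteresis_sd = 0,
                     hysteresis_range = c(2, 2), pic_amplitude = 0,
                     tracking_noise_sd = 0, torque_noise_sd = 0,
                     participant_rmin_sd = 0, participant_delta_sd = 0,
                     gain_cv = 0, seed = 2)
  st <- simulate_study(cfg, conditions = "Control")
  out <- analyze_study(st)
  expect_true(all(abs(out$recruitment_threshold - 8) < 0.5))
})

test_that("pipeline delta F matches the g*delta oracle on near-noiseless pairs", {
  cfg <- pool_config(n_participants = 1, units_per_trial = 8, isi_cv = 0.01,
                     gain = 1, gain_cv = 0, hysteresis_mean = 3,
                     hysteresis_sd = 0, hysteresis_range = c(3, 3),
                     pic_amplitude = 0, tracking_noise_sd = 0,
                     torque_noise_sd = 0, participant_rmin_sd = 0,
                     participant_delta_sd = 0, seed = 4)
  st <- simulate_study(cfg, conditions = "Control")
  out <- analyze_study(st)
  df <- out$delta_f[!is.na(out$delta_f)]
  expect_gt(length(df), 5)
  expect_true(all(abs(df - 3) < 0.2))
})

test_that("delta F rows appear only for units with at least one control", {
  cfg <- pool_config(n_participants = 1, units_per_trial = 6, seed = 9)
  out <- analyze_study(simulate_study(cfg, conditions = "Control"))
  expect_true(all(is.na(out$delta_f[out$n_control_units == 0])))
  expect_true(all(!is.na(out$delta_f[out$n_control_units > 0])))
})
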