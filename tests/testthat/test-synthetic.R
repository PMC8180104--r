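presets <- c("sham", "sham_wk1", "snl_wk1", "snl_wk4")

test_that("noiseless fluctuation equals the amplitude parameter for every joint and preset", {
  for (nm in presets) {
    tr <- preset_trial(nm)
    cyc <- segment_cycles(tr$truth$events, 10)
    for (j in c("iliac", "hip", "knee", "ankle", "mtp5")) for (s in c("left", "right")) {
      f <- fluctuation_height(tr$series, cyc, j, s)
      expect_equal(f$mean, tr$truth$shape$amplitude[[j]][[s]],
                   tolerance = 1e-6,
                   label = sprintf("%s %s/%s fluctuation", nm, j, s))
      expect_lt(f$sd, 1e-9)
    }
  }
})

test_that("ground-truth timing identities hold: swing, stride, step split, bfc", {
  for (nm in presets) {
    tr <- preset_trial(nm)
    tm <- tr$truth$timing
    ev <- tr$truth$events
    ct <- circular_times(ev, 10)
    expect_equal(ct[["left"]],  (1 - tm$duty_left) * tm$cycle_period,
                 tolerance = 1e-9)
    expect_equal(ct[["right"]], (1 - tm$duty_right) * tm$cycle_period,
                 tolerance = 1e-9)
    belt <- to_belt_frame(tr$series)
    stride <- stride_length(belt, ev, "left")
    expect_equal(stride, 20 * tm$cycle_period, tolerance = 1e-6)
    expect_equal(stride_length(belt, ev, "right"), stride, tolerance = 1e-6)
    sl <- step_length(belt, ev, "left"); sr <- step_length(belt, ev, "right")
    expect_equal(sl + sr, stride, tolerance = 1e-6)
    expect_equal(sl, tm$phase_offset * stride, tolerance = 1e-6)
    expect_equal(both_foot_contact_time(ev, 10),
                 tr$truth$metrics$both_foot_contact_window10, tolerance = 1e-9)
  }
})

test_that("fixed seed gives bitwise-identical trials", {
  p <- gait_preset("snl_wk1")
  a <- simulate_trial(p$timing, p$shape, noise_sd = 0.05, seed = 99)
  b <- simulate_trial(p$timing, p$shape, noise_sd = 0.05, seed = 99)
  expect_identical(a$series$z, b$series$z)
  expect_identical(a$series$x, b$series$x)
})

test_that("preset shape invariants: dip and ankle slopes separate SNL from sham", {
  sham <- gait_preset("sham"); snl <- gait_preset("snl_wk1")
  expect_equal(sham$shape$dip[["left"]], 0)
  expect_gt(snl$shape$dip[["left"]], 0)
  expect_gte(sham$shape$ankle_s1[["left"]], sham$shape$ankle_s2[["left"]] / 2)
  expect_gt(snl$shape$ankle_s2[["left"]], 2 * snl$shape$ankle_s1[["left"]])
  # SNL left hip actually dips below its stance baseline in swing
  tr <- preset_trial("snl_wk1")
  cyc <- segment_cycles(tr$truth$events, 10)
  z <- marker_track(tr$series, "hip", "left")$z
  t <- marker_track(tr$series, "hip", "left")$t
  st <- cyc$left[1, ]
  stance <- z[t >= st$touchdown & t < st$lift_off]
  swing  <- z[t >= st$lift_off & t < st$next_touchdown]
  expect_lt(min(swing), min(stance) - 0.1)
})

test_that("duty-factor calibration matches the brute-force overlap oracle", {
  cases <- list(c(1.03, 1.0, 0.5), c(2.0, 0.66, 8.1 / 12.8),
                c(1.9, 0.62, 8.2 / 12.8), c(1.5, 0.8, 0.55))
  for (cs in cases) {
    d <- calibrate_duty_factors(cs[1], cs[2], cs[3])
    expect_true(all(d > 0.5 & d < 0.9))
    ev <- periodic_events(T = 0.64, duty_left = d[["duty_left"]],
                          duty_right = d[["duty_right"]],
                          phase_offset = cs[3], n = 12)
    span <- c(0.64, 0.64 + 10 * 0.64)
    expect_equal(brute_force_overlap(ev, span), cs[1], tolerance = 2e-3)
    # swing-ratio constraint honored
    expect_equal((1 - d[["duty_right"]]) / (1 - d[["duty_left"]]), cs[2],
                 tolerance = 1e-9)
  }
  expect_error(calibrate_duty_factors(6, 1, 0.5), class = "rg_parameter_error")
})

test_that("cohort generator: sigma = 0 duplicates the mean animal; guards fire", {
  spec <- gait_preset("sham", n_animals = 3, noise_sd = 0, seed = 1)
  spec$sd <- lapply(spec$sd, function(x) x * 0)
  co <- simulate_cohort(spec)
  expect_equal(co[[1]]$params$cycle_period, co[[2]]$params$cycle_period)
  expect_equal(co[[1]]$params$duty_left, co[[3]]$params$duty_left)
  expect_equal(co[[1]]$params$amplitude$hip, co[[2]]$params$amplitude$hip)
  spec1 <- gait_preset("sham", n_animals = 1)
  expect_error(simulate_cohort(spec1), class = "rg_parameter_error")
  expect_error(gait_timing_params(cycle_period = 0.64, duty_left = 0.95),
               class = "rg_parameter_error")
})

test_that("von Frey generator: deterministic arithmetic cases", {
  # sigma 0, trial noise 0: every left trial is right * (1 - 0.47)
  rec <- simulate_vonfrey_cohort(n_animals = 2, weeks = 1:2, delta_mean = 0.47,
                                 delta_sd = 0, right_sd = 0, trial_sd = 0,
                                 right_mean = 10, seed = 1)
  expect_true(all(rec$threshold_time_s[rec$side == "right"] == 10))
  expect_true(all(abs(rec$threshold_time_s[rec$side == "left"] - 5.3) < 1e-12))
  # null effect recovers ~0
  rec0 <- simulate_vonfrey_cohort(n_animals = 6, weeks = 1:4,
                                  delta_mean = 1e-6, delta_sd = 0, seed = 2)
  s <- threshold_summary(rec0)
  expect_lt(abs(s$overall$mean), 5)
  expect_error(simulate_vonfrey_cohort(delta_mean = 1.2),
               class = "rg_parameter_error")
})
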