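# One hand-built cycle: z samples [2.0, 2.5, 3.0, 2.2] -> height 1.0 cm.
test_that("fluctuation height is max minus min within the cycle", {
  t <- seq(0, 0.07, by = 0.01)
  z <- c(2.0, 2.5, 3.0, 2.2, 2.0, 2.0, 2.0, 2.0)
  s <- toy_series(t, overrides = list("hip.left" = list(z = z)))
  ev <- gait_events(c(0, 0.04), 0.03, c(0.02, 0.06), 0.05)
  cyc <- segment_cycles(ev, NULL)
  f <- fluctuation_height(s, cyc, "hip", "left")
  expect_equal(f$per_cycle, 1.0)
  expect_equal(f$mean, 1.0)
})

test_that("published amplitudes are reproduced exactly on noiseless presets", {
  sham <- preset_trial("sham"); snl1 <- preset_trial("snl_wk1")
  cyc_sham <- segment_cycles(sham$truth$events, 10)
  cyc_snl <- segment_cycles(snl1$truth$events, 10)
  expect_equal(fluctuation_height(sham$series, cyc_sham, "hip", "left")$mean, 1.0,
               tolerance = 1e-9)
  expect_equal(fluctuation_height(snl1$series, cyc_snl, "hip", "left")$mean, 1.47,
               tolerance = 1e-9)
  expect_equal(fluctuation_height(snl1$series, cyc_snl, "knee", "left")$mean, 1.80,
               tolerance = 1e-9)
})

test_that("fluctuation is shift/translation invariant and scales linearly", {
  tr <- preset_trial("sham", noise_sd = 0.05, seed = 17)
  cyc <- segment_cycles(tr$truth$events, 10)
  base <- fluctuation_height(tr$series, cyc, "knee", "left")$mean
  df <- as.data.frame(tr$series)
  df$z <- df$z + 7.5
  up <- marker_series(df, sample_rate = 100, belt_speed = 20)
  expect_equal(fluctuation_height(up, cyc, "knee", "left")$mean, base,
               tolerance = 1e-12)
  df2 <- as.data.frame(tr$series); df2$z <- df2$z * 3
  tripled <- marker_series(df2, sample_rate = 100, belt_speed = 20)
  expect_equal(fluctuation_height(tripled, cyc, "knee", "left")$mean, 3 * base,
               tolerance = 1e-12)
})

test_that("kinematic metrics barely move when detected events replace ground truth (noiseless)", {
  tr <- preset_trial("snl_wk4")
  cyc_gt <- segment_cycles(tr$truth$events, 10)
  cyc_det <- segment_cycles(detect_events(tr$series), 10)
  for (j in c("hip", "knee")) for (s in c("left", "right")) {
    a <- fluctuation_height(tr$series, cyc_gt, j, s)$mean
    b <- fluctuation_height(tr$series, cyc_det, j, s)$mean
    expect_lt(abs(a - b), 1e-3)
  }
})

test_that("phase profile: identical cycles give zero SD; sham stance is flat", {
  tr <- preset_trial("sham")
  cyc <- segment_cycles(tr$truth$events, 10)
  pp <- phase_profile(tr$series, cyc, "hip", "left", n_grid = 101)
  expect_equal(max(pp$sd), 0, tolerance = 1e-9)
  stance <- pp$mean[pp$phase <= tr$truth$timing$duty_left - 0.01]
  expect_lt(diff(range(stance)), 0.05 * 1.0)   # flat stance line
  # profile is periodic: first and last grid points agree
  expect_lt(abs(pp$mean[1] - pp$mean[length(pp$mean)]), 1e-6)
  expect_error(phase_profile(tr$series, cyc, "hip", "left", n_grid = 5),
               class = "rg_parameter_error")
})

test_that("phase profile of the time-reversed series is the reversed profile", {
  tr <- preset_trial("sham", noise_sd = 0.05, seed = 23)
  cyc <- segment_cycles(tr$truth$events, 4)
  pp <- phase_profile(tr$series, cyc, "knee", "left", n_grid = 51)
  df <- as.data.frame(tr$series)
  tmax <- max(df$t)
  df$t <- tmax - df$t
  df <- df[order(df$t, df$side, df$marker), ]
  rev_s <- marker_series(df, sample_rate = 100, belt_speed = 20)
  rev_ev <- gait_events(
    left_touchdown = sort(tmax - c(cyc$left$touchdown[1], cyc$left$next_touchdown)),
    left_lift_off = sort(tmax - cyc$left$lift_off),
    right_touchdown = sort(tmax - c(cyc$right$touchdown[1], cyc$right$next_touchdown)),
    right_lift_off = sort(tmax - cyc$right$lift_off))
  rev_cyc <- segment_cycles(rev_ev, NULL)
  pp_rev <- phase_profile(rev_s, rev_cyc, "knee", "left", n_grid = 51)
  expect_equal(pp_rev$mean, rev(pp$mean), tolerance = 1e-6)
})

test_that("ankle swing-slope ratio: closed-form cases and preset separation", {
  # one swing 0..1 s sampled at 100 Hz
  t <- seq(0, 1.999, by = 0.01)
  u <- pmin(t, 1)
  ramp <- toy_series(t, overrides = list("ankle.left" = list(z = 2 + u)))
  ev <- gait_events(c(-0.5, 1.0), 0, c(0.2, 1.2), 1.1)
  cyc <- segment_cycles(ev, NULL)
  expect_equal(as.numeric(ankle_swing_slope_ratio(ramp, cyc, "left")), 1.0,
               tolerance = 1e-9)
  # piecewise slopes 1 then 3 -> ratio 3
  zpw <- 2 + ifelse(u <= 2 / 3, u, 2 / 3 + 3 * (u - 2 / 3))
  pw <- toy_series(t, overrides = list("ankle.left" = list(z = zpw)))
  expect_equal(as.numeric(ankle_swing_slope_ratio(pw, cyc, "left")), 3.0,
               tolerance = 1e-6)
  # SNL preset exceeds 2, sham does not
  snl <- preset_trial("snl_wk1"); sham <- preset_trial("sham")
  cs <- segment_cycles(snl$truth$events, 10)
  ch <- segment_cycles(sham$truth$events, 10)
  expect_gt(ankle_swing_slope_ratio(snl$series, cs, "left"), 2)
  expect_lte(ankle_swing_slope_ratio(sham$series, ch, "left"), 2)
})
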