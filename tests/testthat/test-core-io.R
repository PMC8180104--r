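test_that("trajectory CSV round-trips the generator output to 1e-9 cm", {
  tr <- preset_trial("sham", noise_sd = 0.05, seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr$series, path)
  back <- read_trajectory(path)
  expect_equal(attr(back, "sample_rate"), attr(tr$series, "sample_rate"))
  expect_equal(attr(back, "belt_speed"), attr(tr$series, "belt_speed"))
  expect_equal(attr(back, "session"), attr(tr$series, "session"))
  for (col in c("t", "x", "y", "z"))
    expect_lt(max(abs(back[[col]] - tr$series[[col]])), 1e-9)
  expect_identical(back$marker, tr$series$marker)
  # frame count = duration * sample_rate (+1 for the t = 0 frame)
  n <- tr$truth$timing$n_strides
  expect_equal(length(unique(back$t)),
               floor((n + 2) * tr$truth$timing$cycle_period * 100) + 1)
  # byte stability
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr$series, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("trajectory reader rejects malformed input", {
  t3 <- (0:2) / 100
  s <- toy_series(t3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(s, path)
  expect_s3_class(read_trajectory(path), "marker_series")

  # duplicated timestamp
  df <- as.data.frame(s)
  df$t[df$t == t3[2]] <- t3[1]
  expect_error(marker_series(df), class = "rg_validation_error")
  # unknown marker
  df2 <- as.data.frame(s); df2$marker[1] <- "heel"
  expect_error(marker_series(df2), class = "rg_validation_error")
  # malformed header
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("#sample_rate_hz=100", "#belt_speed_cm_s=20", "a,b,c", "1,2,3"), bad)
  expect_error(read_trajectory(bad), class = "rg_format_error")
  # missing metadata
  lines <- readLines(path)
  writeLines(lines[!grepl("belt_speed", lines)], bad)
  expect_error(read_trajectory(bad), class = "rg_config_error")
  # c3d unsupported in this build
  expect_error(read_trajectory(path, dialect = "c3d"), class = "rg_config_error")
  # empty series refuses to serialize
  expect_error(write_trajectory(s[0, ], path), "empty")
})

test_that("event CSV round-trips ground truth exactly and validates alternation", {
  tr <- preset_trial("snl_wk1", noise_sd = 0, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(tr$truth$events, path)
  back <- read_events(path)
  expect_equal(back$left, tr$truth$events$left, tolerance = 1e-12)
  expect_equal(back$right, tr$truth$events$right, tolerance = 1e-12)
  expect_identical(back$provenance, "ground_truth")

  # 4 alternating events per side -> 2 stance intervals each
  ev <- gait_events(c(0, 1), c(0.6, 1.6), c(0.5, 1.5), c(1.1, 2.1),
                    provenance = "manual")
  expect_equal(nrow(ratgait3d:::stance_intervals(ev, "left")), 2)
  expect_equal(nrow(ratgait3d:::stance_intervals(ev, "right")), 2)
  # two consecutive lift-offs name the offending times
  expect_error(gait_events(c(0), c(0.6, 0.8), c(0.5), c(1.1)),
               "lift_off.*0\\.6.*0\\.8", class = "rg_validation_error")
})

test_that("belt-frame map is the linear kinematic map and guards idempotence", {
  t <- seq(0, 1, by = 0.01)
  s <- toy_series(t, overrides = list("mtp5.left" = list(x = rep(0, length(t)))))
  b <- to_belt_frame(s)
  xl <- marker_track(b, "mtp5", "left")$x
  expect_equal(range(xl), c(0, 20))           # 20 cm/s for 1 s
  expect_equal(marker_track(b, "hip", "left")$z,
               marker_track(s, "hip", "left")$z)
  expect_error(to_belt_frame(b), class = "rg_config_error")
  # belt speed 0 is the identity on coordinates
  s0 <- toy_series(t, belt_speed = 0)
  b0 <- to_belt_frame(s0)
  expect_equal(b0$x, s0$x)
  expect_equal(b0$z, s0$z)
})

test_that("belt-frame stride of a stationary-on-average walker is v * T", {
  tr <- preset_trial("sham", noise_sd = 0)
  belt <- to_belt_frame(tr$series)
  expect_equal(stride_length(belt, tr$truth$events, "left"), 20 * 0.64,
               tolerance = 1e-9)
})

test_that("short marker dropouts are interpolated, long ones reject the trial", {
  t <- seq(0, 1, by = 0.01)
  z <- 5 + sin(2 * pi * t)
  z_na <- z; z_na[40:43] <- NA
  s <- toy_series(t, overrides = list("knee.left" = list(z = z_na)))
  filled <- fill_missing(s, max_gap = 5)
  # linear interpolation across a 4-frame gap of a 1 Hz sinusoid: curvature
  # bounds the error near (2*pi)^2 * (gap*dt)^2 / 8 ~ 0.01 cm
  expect_lt(max(abs(marker_track(filled, "knee", "left")$z - z)), 2e-2)
  z_na[40:50] <- NA
  s2 <- toy_series(t, overrides = list("knee.left" = list(z = z_na)))
  expect_error(fill_missing(s2, max_gap = 5), class = "rg_validation_error")
})

test_that("von Frey CSV round-trips and validates", {
  rec <- simulate_vonfrey_cohort(n_animals = 3, weeks = 1:2, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_vonfrey(rec, path)
  back <- read_vonfrey(path)
  rec_cmp <- rec
  attr(rec_cmp, "truth") <- NULL               # truth stays in memory only
  expect_equal(as.data.frame(back), as.data.frame(rec_cmp), tolerance = 1e-12)
  broken <- as.data.frame(rec)[-1, ]           # 2 trials for one combo
  expect_error(vonfrey_records(broken), class = "rg_validation_error")
  bad_t <- as.data.frame(rec); bad_t$threshold_time_s[1] <- 25
  expect_error(vonfrey_records(bad_t), class = "rg_validation_error")
})

test_that("randomized event tables round-trip through CSV (property)", {
  set.seed(42)
  for (i in 1:10) {
    ev <- periodic_events(T = runif(1, 0.4, 1), duty_left = runif(1, 0.55, 0.85),
                          duty_right = runif(1, 0.55, 0.85),
                          phase_offset = runif(1, 0.2, 0.8),
                          n = sample(3:8, 1), provenance = "manual")
    path <- withr::local_tempfile(fileext = ".csv")
    write_events(ev, path)
    back <- read_events(path)
    expect_equal(back$left, ev$left, tolerance = 1e-12)
    expect_equal(back$right, ev$right, tolerance = 1e-12)
  }
})
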