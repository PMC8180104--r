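test_that("both-foot contact: worked interval example and degenerate cases", {
  # L stance (0,0.42),(0.64,1.06); R stance (0.32,0.74),(0.96,1.38) -> 0.30 s
  ev <- gait_events(c(0, 0.64), c(0.42, 1.06), c(0.32, 0.96), c(0.74, 1.38))
  expect_equal(both_foot_contact_time(ev, NULL), 0.30, tolerance = 1e-12)
  # trot with aerial phase: stances never overlap -> 0
  trot <- gait_events(c(0, 1), c(0.3, 1.3), c(0.5, 1.5), c(0.8, 1.8))
  expect_equal(both_foot_contact_time(trot, NULL), 0)
  # per-cycle mean divides by the stride count
  ev10 <- periodic_events(duty_left = 0.6, duty_right = 0.6, n = 12)
  expect_equal(both_foot_contact_time(ev10, 10, mode = "per_cycle_mean"),
               both_foot_contact_time(ev10, 10) / 10, tolerance = 1e-12)
})

test_that("both-foot contact matches the dense-grid brute-force oracle (property)", {
  set.seed(7)
  for (i in 1:25) {
    T <- runif(1, 0.4, 1)
    ev <- periodic_events(T = T, duty_left = runif(1, 0.52, 0.88),
                          duty_right = runif(1, 0.52, 0.88),
                          phase_offset = runif(1, 0.15, 0.85),
                          n = 12, t0 = T)
    got <- both_foot_contact_time(ev, 10)
    span <- c(T, 11 * T)
    expect_equal(got, brute_force_overlap(ev, span), tolerance = 5e-4)
  }
})

test_that("both-foot contact is L/R symmetric, translation invariant, additive", {
  ev <- periodic_events(duty_left = 0.65, duty_right = 0.58,
                        phase_offset = 0.42, n = 12)
  v <- both_foot_contact_time(ev, 10)
  mirrored <- gait_events(ev$right$touchdown, ev$right$lift_off,
                          ev$left$touchdown, ev$left$lift_off)
  # windows anchor on the left limb, so compare over the full span instead
  expect_equal(both_foot_contact_time(ev, NULL),
               both_foot_contact_time(mirrored, NULL), tolerance = 1e-9)
  shift <- gait_events(ev$left$touchdown + 3, ev$left$lift_off + 3,
                       ev$right$touchdown + 3, ev$right$lift_off + 3)
  expect_equal(both_foot_contact_time(shift, 10), v, tolerance = 1e-9)
  # cumulative mode is additive over disjoint sub-windows: for a strictly
  # periodic gait, 10 strides carry exactly twice the overlap of 5
  expect_equal(both_foot_contact_time(ev, 10),
               2 * both_foot_contact_time(ev, 5), tolerance = 1e-9)
})

test_that("circular times: worked example and generator identity", {
  # lift-offs at 0,1,2; touchdowns at 0.3,1.3,2.3 -> mean swing 0.3 s
  ev <- gait_events(c(-0.6, 0.3, 1.3, 2.3), c(0, 1, 2),
                    c(-0.1, 0.8, 1.8), c(0.5, 1.5, 2.5))
  ct <- circular_times(ev, NULL)
  expect_equal(ct[["left"]], 0.3, tolerance = 1e-12)
  tr <- preset_trial("snl_wk4")
  ct4 <- circular_times(tr$truth$events, 10)
  expect_equal(ct4[["right"]] / ct4[["left"]], 0.62, tolerance = 1e-9)
})

test_that("R value: symmetric limit, printed ratio, mirror product, normalization", {
  expect_equal(r_value(c(left = 0.28, right = 0.28)), 1.0)
  expect_equal(r_value(c(left = 1.0, right = 0.62)), 0.62)
  # R of a gait and of its L-R mirror multiply to 1
  set.seed(11)
  for (i in 1:10) {
    ct <- c(left = runif(1, 0.1, 0.5), right = runif(1, 0.1, 0.5))
    mirrored <- c(left = ct[["right"]], right = ct[["left"]])
    expect_equal(r_value(ct) * r_value(mirrored), 1, tolerance = 1e-12)
  }
  expect_error(r_value(c(left = 0, right = 0.3)), class = "rg_parameter_error")
  expect_error(r_value(c(left = 0.3, right = 0.3), "sham_normalized"),
               class = "rg_config_error")
  sham_ref <- c(1.05, 0.95, 1.0)
  expect_equal(r_value(c(left = 0.3, right = 0.3), "sham_normalized", sham_ref),
               1 / mean(sham_ref), tolerance = 1e-12)
  # self-normalization: cohort mean of normalized sham values is exactly 1
  expect_equal(mean(sham_ref / mean(sham_ref)), 1, tolerance = 1e-12)
})

test_that("stride in the overground limit: belt 0, foot repositioned 5 cm per cycle", {
  t <- seq(0, 3.99, by = 0.01)
  cycle <- floor(t)                      # 1 s cycles
  u <- t - cycle
  # stance first 0.6 s at a fixed spot that advances 5 cm each cycle
  x <- ifelse(u < 0.6, 5 * cycle, 5 * cycle + 5 * (u - 0.6) / 0.4)
  z <- ifelse(u < 0.6, 0, 1)
  s <- toy_series(t, overrides = list("mtp5.left" = list(x = x, z = z),
                                      "mtp5.right" = list(z = z)),
                  belt_speed = 0)
  ev <- gait_events(c(0, 1, 2, 3) + 1e-9, c(0.6, 1.6, 2.6, 3.6),
                    c(0, 1, 2, 3) + 0.5, c(0.1, 1.1, 2.1, 3.1))
  belt <- to_belt_frame(s)               # identity at belt speed 0
  expect_equal(stride_length(belt, ev, "left", window_strides = 3), 5,
               tolerance = 1e-9)
})

test_that("step lengths split the stride by the phase offset", {
  tr <- preset_trial("snl_wk1")
  belt <- to_belt_frame(tr$series)
  ev <- tr$truth$events
  expect_equal(step_length(belt, ev, "left"), 8.1, tolerance = 1e-6)
  expect_equal(step_length(belt, ev, "right"), 4.7, tolerance = 1e-6)
  sham <- preset_trial("sham")
  beltsh <- to_belt_frame(sham$series)
  expect_equal(step_length(beltsh, sham$truth$events, "left"), 6.4,
               tolerance = 1e-6)
  # lab-frame series is rejected
  expect_error(step_length(tr$series, ev, "left"), class = "rg_config_error")
  # silent contralateral side
  lonely <- gait_events(c(0, 1, 2), c(0.6, 1.6, 2.6), 10, 10.6)
  expect_error(step_length(belt, lonely, "left", window_strides = 2),
               class = "rg_insufficient_data")
})
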