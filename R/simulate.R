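# Synthetic treadmill locomotion. One trial is built from a periodic
# timing skeleton (touchdowns/lift-offs per side) plus per-joint vertical
# waveforms evaluated on the sampled time grid. Waveforms are
# range-normalized per sampled cycle, so the measured per-cycle
# top-minus-bottom height equals the amplitude parameter exactly when
# noise_sd = 0 — the contract the fluctuation metric is tested against.

# -- raw waveforms as functions of cycle phase u in [0,1), stance [0,d) ----

.shape_limb <- function(u, d, dip) {
  r <- numeric(length(u))
  sw <- u >= d
  v <- (u[sw] - d) / (1 - d)
  r[sw] <- sin(pi * v)^2 -
    dip * ifelse(v > 0.5, sin(pi * (2 * v - 1))^2, 0)
  r
}

.shape_ankle <- function(u, d, s1, s2) {
  peak <- (2 / 3) * s1 + (1 / 3) * s2
  r <- numeric(length(u))
  st <- u < d
  r[st] <- peak * (1 + cos(pi * u[st] / d)) / 2    # settle back during stance
  v <- (u[!st] - d) / (1 - d)
  r[!st] <- s1 * pmin(v, 2 / 3) + s2 * pmax(0, v - 2 / 3)
  r
}

# Steep-edged swing arc: the toe leaves and meets the belt abruptly, so a
# height threshold crossed at 0.15 cm sits within ~2 ms of the true event.
.shape_toe <- function(u, d) {
  r <- numeric(length(u))
  sw <- u >= d
  v <- (u[sw] - d) / (1 - d)
  r[sw] <- sqrt(pmax(0, sin(pi * v)))
  r
}

# Lab-frame fore-aft foot position over one cycle, for a walker that is
# stationary on average: the stance foot rides backward with the belt and
# the swing foot returns with zero end-point velocity. Anchored so that
# every touchdown lands at x = 0 regardless of the side's duty factor —
# otherwise asymmetric duties would shift contact positions between feet
# and contaminate step lengths.
.foot_x <- function(u, d, stroke) {
  r <- numeric(length(u))
  st <- u < d
  r[st] <- -stroke * u[st] / d
  v <- (u[!st] - d) / (1 - d)
  r[!st] <- -stroke + stroke * (v - sin(2 * pi * v) / (2 * pi))
  r
}

.x_offset <- c(iliac = 4, hip = 3, knee = 2, ankle = 1, mtp5 = 0)
.y_width  <- c(iliac = 1.5, hip = 1.8, knee = 1.6, ankle = 1.2, mtp5 = 1.0)

#' Simulate one treadmill trial
#'
#' Generates lab-frame trajectories of all ten markers for one animal
#' walking at constant belt speed, together with the ground-truth event
#' table and the noiseless metric values implied by the parameters. The toe
#' is on the belt (z = 0) throughout stance and describes a steep swing
#' arc; hip/knee/iliac are flat in stance with a single swing bump (plus an
#' optional post-peak dip for SNL-like instability); the ankle rises
#' piecewise-linearly through swing. In the belt frame the stride length is
#' exactly `belt_speed * cycle_period`.
#'
#' @param timing a [gait_timing_params()].
#' @param shape a [joint_shape_params()].
#' @param noise_sd additive Gaussian marker noise SD, cm (0 = noiseless).
#' @param seed integer seed for the noise stream (ignored when
#'   `noise_sd = 0` unless set; fixed seed gives bitwise-identical output).
#' @param sample_rate Hz.
#' @param belt_speed cm/s.
#' @param animal_id,session metadata for the series.
#' @return list with elements `series` (a [marker_series()]) and `truth`
#'   (ground-truth `events`, realized `timing`/`shape`, and noiseless
#'   `metrics`).
#' @export
simulate_trial <- function(timing, shape, noise_sd = 0, seed = NULL,
                           sample_rate = 100, belt_speed = 20,
                           animal_id = "sim", session = "wk4") {
  stopifnot(inherits(timing, "gait_timing"), inherits(shape, "joint_shape"))
  if (!is.null(seed)) set.seed(seed)
  T0 <- timing$cycle_period
  n  <- timing$n_strides
  phi <- timing$phase_offset
  psi <- 1 - phi                       # right touchdown phase in left cycle
  duty <- c(left = timing$duty_left, right = timing$duty_right)
  t0 <- T0                             # lead-in before the first left cycle
  duration <- t0 + (n + 1) * T0
  nf <- floor(duration * sample_rate) + 1L
  tt <- (seq_len(nf) - 1L) / sample_rate
  anchor <- c(left = t0, right = t0 + psi * T0)

  # ground truth lists *every* event visible in the sampled span, including
  # the lead-in cycle, so detected events always have a true counterpart
  left_td  <- t0 + (-2:n) * T0
  left_lo  <- left_td + duty[["left"]] * T0
  right_td <- anchor[["right"]] + (-2:n) * T0
  right_lo <- right_td + duty[["right"]] * T0
  left_td  <- left_td[left_td >= 0]
  left_lo  <- left_lo[left_lo >= 0 & left_lo <= duration]
  right_td <- right_td[right_td >= 0 & right_td <= duration]
  right_lo <- right_lo[right_lo >= 0 & right_lo <= duration]
  truth_events <- gait_events(left_td, left_lo, right_td, right_lo,
                              provenance = "ground_truth")

  out <- vector("list", 10L)
  i <- 0L
  for (side in SIDES) {
    d <- duty[[side]]
    theta <- (tt - anchor[[side]]) / T0
    u <- theta - floor(theta)
    grp <- pmin(pmax(floor(theta + .time_eps), -1L), n)
    for (m in MARKERS) {
      raw <- switch(m,
        mtp5  = .shape_toe(u, d),
        ankle = .shape_ankle(u, d, shape$ankle_s1[[side]], shape$ankle_s2[[side]]),
        .shape_limb(u, d, shape$dip[[side]]))
      # per-cycle range normalization on the *sampled* values
      z <- numeric(nf)
      A <- shape$amplitude[[m]][[side]]
      for (k in unique(grp)) {
        sel <- grp == k
        rng <- range(raw[sel])
        den <- if (diff(rng) > 0) diff(rng) else 1
        z[sel] <- shape$base[[m]] + A * (raw[sel] - rng[1L]) / den
      }
      x <- if (m == "mtp5")
        .foot_x(u, d, belt_speed * d * T0)
      else
        .x_offset[[m]] + 0.3 * sin(2 * pi * u)
      y <- if (side == "left") .y_width[[m]] else -.y_width[[m]]
      i <- i + 1L
      out[[i]] <- data.frame(t = tt, marker = m, side = side,
                             x = x, y = y + numeric(nf), z = z)
    }
  }
  df <- do.call(rbind, out)
  if (noise_sd > 0) {
    df$x <- df$x + rnorm(nrow(df), 0, noise_sd)
    df$y <- df$y + rnorm(nrow(df), 0, noise_sd)
    df$z <- df$z + rnorm(nrow(df), 0, noise_sd)
    df$z[df$marker == "mtp5"] <- pmax(df$z[df$marker == "mtp5"], -0.45)
  }
  series <- marker_series(df, animal_id = animal_id, session = session,
                          sample_rate = sample_rate, belt_speed = belt_speed,
                          frame = "lab")

  ov <- stance_overlap_fraction(duty[["left"]], duty[["right"]], phi)
  metrics <- list(
    stride = belt_speed * T0,
    step_left = phi * belt_speed * T0,
    step_right = (1 - phi) * belt_speed * T0,
    circular_left = (1 - duty[["left"]]) * T0,
    circular_right = (1 - duty[["right"]]) * T0,
    r_value = (1 - duty[["right"]]) / (1 - duty[["left"]]),
    both_foot_contact_per_cycle = ov * T0,
    both_foot_contact_window10 = 10 * ov * T0,
    fluctuation = lapply(shape$amplitude, identity))
  list(series = series,
       truth = list(events = truth_events, timing = timing, shape = shape,
                    noise_sd = noise_sd, metrics = metrics))
}

#' Simulate a cohort of animals
#'
#' Draws per-animal gait parameters around the preset group means
#' (independent normals, truncated symmetrically about the mean so the
#' calibrated means are preserved) and simulates one trial per animal.
#' Between-animal variation in both-foot contact time and circular-time
#' ratio is realized by re-calibrating each animal's duty factors to its
#' drawn targets. Per-animal parameter draws and noise use deterministic
#' substreams of the cohort seed.
#'
#' @param spec a [gait_preset()] cohort specification.
#' @return list of per-animal lists as returned by [simulate_trial()], each
#'   with an added `params` element holding the realized draws.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_animals < 2L)
    rg_parameter_error("a cohort needs at least 2 animals for group statistics")
  base_t <- spec$timing; sdv <- spec$sd
  lapply(seq_len(spec$n_animals), function(a) {
    set.seed(derive_seed(spec$seed, a))
    T_a   <- rnorm_trunc_sym(1, base_t$cycle_period, sdv$cycle_period, 0.2, Inf)
    phi_a <- rnorm_trunc_sym(1, base_t$phase_offset, sdv$phase_offset, 0.05, 0.95)
    duties <- NULL
    rho0 <- spec$targets$r_value; bfc0 <- spec$targets$both_foot_contact
    for (try in 1:200) {
      rho_a <- rnorm_trunc_sym(1, rho0, sdv$swing_ratio, 0.05, 1.95)
      bfc_a <- rnorm_trunc_sym(1, bfc0, sdv$bfc, 0.02, Inf)
      duties <- tryCatch(
        calibrate_duty_factors(bfc_a, rho_a, phi_a, cycle_period = T_a,
                               window_strides = 10L),
        rg_parameter_error = function(e) NULL)
      if (!is.null(duties)) break
    }
    if (is.null(duties))
      rg_parameter_error("could not find feasible duty factors for animal %d", a)
    amp <- lapply(MARKERS, function(m) {
      mu <- spec$shape$amplitude[[m]]
      c(left  = rnorm_trunc_sym(1, mu[["left"]],  sdv$amplitude[[m]], 0.05, Inf),
        right = rnorm_trunc_sym(1, mu[["right"]], sdv$amplitude[[m]], 0.05, Inf))
    })
    names(amp) <- MARKERS
    dip_a <- c(left  = rnorm_trunc_sym(1, spec$shape$dip[["left"]],  sdv$dip, 0, Inf),
               right = spec$shape$dip[["right"]])
    s1_a <- vapply(SIDES, function(s)
      rnorm_trunc_sym(1, spec$shape$ankle_s1[[s]], sdv$slope, 0.05, Inf), 0)
    s2_a <- vapply(SIDES, function(s)
      rnorm_trunc_sym(1, spec$shape$ankle_s2[[s]], sdv$slope, 0.05, Inf), 0)
    timing_a <- gait_timing_params(T_a, duties[["duty_left"]],
                                   duties[["duty_right"]], phi_a,
                                   base_t$n_strides)
    shape_a <- joint_shape_params(amplitude = amp, base = spec$shape$base,
                                  dip = dip_a, ankle_s1 = s1_a, ankle_s2 = s2_a)
    trial <- simulate_trial(timing_a, shape_a, noise_sd = spec$noise_sd,
                            seed = derive_seed(spec$seed, 100000L + a),
                            sample_rate = spec$sample_rate,
                            belt_speed = spec$belt_speed,
                            animal_id = sprintf("%s_%02d", spec$name, a),
                            session = spec$session)
    trial$params <- list(cycle_period = T_a, phase_offset = phi_a,
                         swing_ratio = rho_a, bfc_window = bfc_a,
                         duty_left = duties[["duty_left"]],
                         duty_right = duties[["duty_right"]],
                         amplitude = amp, dip = dip_a, s1 = s1_a, s2 = s2_a)
    trial
  })
}
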