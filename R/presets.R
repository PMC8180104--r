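#' Gait timing parameters
#'
#' The timing skeleton of a simulated trial. Left touchdowns are spaced by
#' the cycle period `cycle_period`; the right touchdown falls
#' `(1 - phase_offset)` of a cycle after the left one, so that the left
#' step length is `phase_offset * stride` and the right step length is
#' `(1 - phase_offset) * stride` in the belt frame. Duty factors are the
#' stance fraction of the cycle per side; the swing (circular-phase)
#' duration of side s is `(1 - duty_s) * cycle_period`.
#'
#' @param cycle_period cycle period T in seconds (> 0).
#' @param duty_left,duty_right stance fraction per side, in (0.5, 0.9) —
#'   walking gaits keep each foot on the belt for more than half the cycle.
#' @param phase_offset left-step fraction of the stride, strictly in (0, 1);
#'   0.5 is a symmetric gait.
#' @param n_strides number of full gait cycles to simulate (>= 2).
#' @return an object of class `gait_timing`.
#' @export
gait_timing_params <- function(cycle_period = 0.64,
                               duty_left = 0.58046875,
                               duty_right = 0.58046875,
                               phase_offset = 0.5,
                               n_strides = 12L) {
  assert_scalar_number(cycle_period, "cycle_period", lower = 0, strict_lower = TRUE)
  for (d in c(duty_left = duty_left, duty_right = duty_right))
    if (d <= 0.5 || d >= 0.9)
      rg_parameter_error("duty factors must lie strictly in (0.5, 0.9); got %g", d)
  if (phase_offset <= 0 || phase_offset >= 1)
    rg_parameter_error("phase_offset must lie strictly in (0, 1)")
  if (n_strides < 2L) rg_parameter_error("n_strides must be >= 2")
  if ((1 - duty_left) * cycle_period <= 0 || (1 - duty_right) * cycle_period <= 0)
    rg_parameter_error("swing duration must be positive")
  structure(list(cycle_period = cycle_period, duty_left = duty_left,
                 duty_right = duty_right, phase_offset = phase_offset,
                 n_strides = as.integer(n_strides)),
            class = "gait_timing")
}

#' Joint trajectory shape parameters
#'
#' Vertical (sagittal) waveforms per joint. Each joint has a nominal height
#' offset `base` (cm above the belt) and a fluctuation amplitude `A` (cm):
#' the generator range-normalizes every sampled gait cycle so that the
#' per-cycle top-minus-bottom height equals `A` exactly in the noiseless
#' limit. Hip/knee-type joints are flat in stance with a single swing bump;
#' a positive `dip` weight adds a post-peak excursion below the stance
#' baseline in the second half of swing (the SNL instability signature).
#' The ankle rises piecewise-linearly through swing with slope `s1` on the
#' first two thirds of swing phase and `s2` on the last third (SNL preset:
#' `s2 > 2 * s1`), then settles back during stance. The toe (mtp5) stays on
#' the belt in stance and describes a steep-edged swing arc whose apex is
#' its amplitude.
#'
#' @param amplitude named list: per joint, a numeric `c(left=, right=)`
#'   amplitude in cm.
#' @param base named numeric vector of per-joint height offsets (cm).
#' @param dip per-side dip weight (dimensionless, >= 0; 0 disables).
#' @param ankle_s1,ankle_s2 per-side ankle swing slopes (cm per unit swing
#'   phase before range normalization; only their ratio is identifiable).
#' @return an object of class `joint_shape`.
#' @export
joint_shape_params <- function(amplitude = list(
                                 iliac = c(left = 0.5,  right = 0.5),
                                 hip   = c(left = 1.0,  right = 1.0),
                                 knee  = c(left = 1.28, right = 1.28),
                                 ankle = c(left = 1.5,  right = 1.5),
                                 mtp5  = c(left = 1.0,  right = 1.0)),
                               base = c(iliac = 8, hip = 6.5, knee = 4.5,
                                        ankle = 2, mtp5 = 0),
                               dip = c(left = 0, right = 0),
                               ankle_s1 = c(left = 1, right = 1),
                               ankle_s2 = c(left = 1, right = 1)) {
  if (!setequal(names(amplitude), MARKERS))
    rg_parameter_error("amplitude must be given for all of: %s",
                       paste(MARKERS, collapse = ", "))
  for (m in MARKERS) {
    a <- amplitude[[m]]
    if (any(a <= 0)) rg_parameter_error("amplitude for %s must be > 0", m)
  }
  if (any(dip < 0)) rg_parameter_error("dip weight must be >= 0")
  if (any(ankle_s1 <= 0)) rg_parameter_error("ankle_s1 must be > 0")
  structure(list(amplitude = amplitude, base = base, dip = dip,
                 ankle_s1 = ankle_s1, ankle_s2 = ankle_s2),
            class = "joint_shape")
}

# Overlap, per cycle, of left and right stance expressed as a fraction of
# the cycle. Left stance occupies phase [0, dl); right stance starts at
# psi = 1 - phase_offset and wraps. Closed-form interval arithmetic on the
# unit circle.
stance_overlap_fraction <- function(duty_left, duty_right, phase_offset) {
  psi <- 1 - phase_offset
  b_end <- psi + duty_right
  o1 <- max(0, min(duty_left, min(1, b_end)) - psi)
  o2 <- if (b_end > 1) min(duty_left, b_end - 1) else 0
  o1 + o2
}

#' Calibrate duty factors to a both-foot contact target
#'
#' Finds the pair of duty factors that reproduces a target cumulative
#' both-foot contact time over an analysis window, subject to a fixed
#' right/left swing-duration ratio (the circular-time ratio R) and phase
#' offset. The windowed overlap is an analytic function of the duties
#' (interval arithmetic on the unit circle), so the solve is a
#' one-dimensional root find in `duty_left`.
#'
#' @param bfc_window target cumulative both-foot contact time (s) over the
#'   window.
#' @param swing_ratio target ratio of right to left swing duration.
#' @param phase_offset left-step fraction of stride (see
#'   [gait_timing_params()]).
#' @param cycle_period cycle period T (s).
#' @param window_strides number of gait cycles in the analysis window.
#' @param bounds allowed duty-factor range.
#' @return `c(duty_left =, duty_right =)`.
#' @export
calibrate_duty_factors <- function(bfc_window, swing_ratio = 1,
                                   phase_offset = 0.5, cycle_period = 0.64,
                                   window_strides = 10L,
                                   bounds = c(0.5, 0.9)) {
  target <- bfc_window / (window_strides * cycle_period)
  # both duties must stay inside `bounds`: duty_right = 1 - ratio*(1 - duty_left)
  dmax <- min(bounds[2L], 1 - (1 - bounds[2L]) / swing_ratio) - 1e-9
  dmin <- max(bounds[1L], 1 - (1 - bounds[1L]) / swing_ratio) + 1e-9
  f <- function(dl)
    stance_overlap_fraction(dl, 1 - swing_ratio * (1 - dl), phase_offset) - target
  if (dmin >= dmax || f(dmin) > 0 || f(dmax) < 0)
    rg_parameter_error(
      "both-foot contact target %g s is not reachable with duties in (%g, %g)",
      bfc_window, bounds[1L], bounds[2L])
  dl <- uniroot(f, c(dmin, dmax), tol = 1e-12)$root
  c(duty_left = dl, duty_right = 1 - swing_ratio * (1 - dl))
}

# Printed group summaries (mean, SE over n = 10 animals) that calibrate the
# generator. Between-animal SDs are SE * sqrt(10), since the source values
# are reported as mean +/- SE.
.preset_table <- list(
  sham = list(  # post-operation week 4 sham group
    session = "wk4", group = "sham",
    bfc = 1.03, se_bfc = 0.15, swing_ratio = 1.0, se_swing_ratio = 0.08,
    step_left_frac = 0.5, hip = 1.0, se_hip = 0.25, knee = 1.28, se_knee = 0.45,
    hip_right = 1.0, knee_right = 1.28,
    stride = 12.8, se_stride = 0.7, dip = 0, s1 = 1, s2 = 1),
  sham_wk1 = list(
    session = "wk1", group = "sham",
    bfc = 1.0, se_bfc = 0.26, swing_ratio = 1.0, se_swing_ratio = 0.08,
    step_left_frac = 0.5, hip = 1.0, se_hip = 0.33, knee = 1.20, se_knee = 0.32,
    hip_right = 1.0, knee_right = 1.20,
    stride = 12.8, se_stride = 0.9, dip = 0, s1 = 1, s2 = 1),
  snl_wk1 = list(
    session = "wk1", group = "SNL",
    bfc = 2.0, se_bfc = 0.25, swing_ratio = 0.66, se_swing_ratio = 0.20,
    step_left_frac = 8.1 / 12.8, hip = 1.47, se_hip = 0.33,
    knee = 1.80, se_knee = 0.32, hip_right = 1.0, knee_right = 1.20,
    stride = 12.8, se_stride = 0.9, dip = 0.8, s1 = 0.4, s2 = 1.6),
  snl_wk4 = list(
    session = "wk4", group = "SNL",
    bfc = 1.9, se_bfc = 0.15, swing_ratio = 0.62, se_swing_ratio = 0.15,
    step_left_frac = 8.2 / 12.8, hip = 1.30, se_hip = 0.25,
    knee = 1.88, se_knee = 0.45, hip_right = 1.0, knee_right = 1.28,
    stride = 12.8, se_stride = 0.7, dip = 0.8, s1 = 0.4, s2 = 1.6))

#' Calibrated cohort presets
#'
#' Returns the generative parameters of one experimental group: sham
#' (week 4 by default; `"sham_wk1"` for the week-1 sham values), SNL week 1
#' or SNL week 4. Group means are calibrated so that the analysis pipeline
#' recovers the published group summaries — belt speed 20 cm/s (12 m/min),
#' cycle period 0.64 s (stride 12.8 cm), per-joint fluctuation amplitudes,
#' windowed both-foot contact time and circular-time ratio R. Between-animal
#' SDs equal the printed SE times sqrt(10).
#'
#' @param name preset name.
#' @param n_animals cohort size (default 10 per group).
#' @param noise_sd marker noise SD in cm (default 0.05).
#' @param n_strides simulated strides per trial.
#' @param seed cohort seed.
#' @return an object of class `cohort_spec`: list with `group`, `session`,
#'   `n_animals`, `timing`, `shape`, `sd` (between-animal SDs), `targets`
#'   and `recovery_se` (model-implied SE of each recovered group mean),
#'   `noise_sd`, `belt_speed`, `sample_rate`, `seed`.
#' @export
gait_preset <- function(name = c("sham", "sham_wk1", "snl_wk1", "snl_wk4"),
                        n_animals = 10L, noise_sd = 0.05, n_strides = 12L,
                        seed = 1L) {
  name <- match.arg(name)
  p <- .preset_table[[name]]
  T0 <- 0.64                       # stride 12.8 cm at belt speed 20 cm/s
  duties <- calibrate_duty_factors(p$bfc, p$swing_ratio, p$step_left_frac,
                                   cycle_period = T0, window_strides = 10L)
  timing <- gait_timing_params(cycle_period = T0,
                               duty_left = duties[["duty_left"]],
                               duty_right = duties[["duty_right"]],
                               phase_offset = p$step_left_frac,
                               n_strides = n_strides)
  shape <- joint_shape_params(
    amplitude = list(iliac = c(left = 0.5, right = 0.5),
                     hip   = c(left = p$hip,  right = p$hip_right),
                     knee  = c(left = p$knee, right = p$knee_right),
                     ankle = c(left = 1.5, right = 1.5),
                     mtp5  = c(left = 1.0, right = 1.0)),
    dip = c(left = p$dip, right = 0),
    ankle_s1 = c(left = p$s1, right = 1),
    ankle_s2 = c(left = p$s2, right = 1))

  rt10 <- sqrt(10)
  sigma <- list(
    cycle_period = p$se_stride * rt10 / 20,  # stride SD mapped through v = 20 cm/s
    phase_offset = 0.02,
    bfc          = p$se_bfc * rt10,
    swing_ratio  = p$se_swing_ratio * rt10,
    amplitude    = c(iliac = 0.1, hip = p$se_hip * rt10,
                     knee = p$se_knee * rt10, ankle = 0.3, mtp5 = 0),
    dip   = if (p$dip > 0) 0.1 else 0,
    slope = 0.05)

  stride_sd <- p$se_stride * rt10
  step_l_sd <- sqrt((p$step_left_frac * stride_sd)^2 +
                      (p$stride * sigma$phase_offset)^2)
  step_r_sd <- sqrt(((1 - p$step_left_frac) * stride_sd)^2 +
                      (p$stride * sigma$phase_offset)^2)

  targets <- list(
    stride = p$stride,
    step_left = p$step_left_frac * p$stride,
    step_right = (1 - p$step_left_frac) * p$stride,
    both_foot_contact = p$bfc,
    r_value = p$swing_ratio,
    hip_left = p$hip, knee_left = p$knee,
    hip_right = p$hip_right, knee_right = p$knee_right)
  recovery_se <- list(
    stride = p$se_stride,
    step_left = step_l_sd / rt10,
    step_right = step_r_sd / rt10,
    both_foot_contact = p$se_bfc,
    r_value = p$se_swing_ratio,
    hip_left = p$se_hip, knee_left = p$se_knee)

  structure(list(name = name, group = p$group, session = p$session,
                 n_animals = as.integer(n_animals), timing = timing,
                 shape = shape, sd = sigma, targets = targets,
                 recovery_se = recovery_se, noise_sd = noise_sd,
                 belt_speed = 20, sample_rate = 100, seed = seed),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %s (%s, %s): n = %d, noise %g cm, seed %d\n",
              x$name, x$group, x$session, x$n_animals, x$noise_sd, x$seed))
  invisible(x)
}
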