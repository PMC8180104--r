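# Gait-pattern parameters from events and belt-frame foot positions.
# Contact positions use the mtp5 (toe) marker: the published step/stride
# lengths are "heel" distances but the marker set carries no heel marker,
# so the toe x-position at contact is the heel proxy (documented choice).

require_belt <- function(series) {
  if (attr(series, "frame") != "belt")
    rg_config_error("this metric needs a belt-frame series; apply to_belt_frame() first")
  invisible(series)
}

# Belt-frame x of the contact foot, sampled `delay` seconds after
# touchdown. The short delay places the sample inside stance, clear of the
# landing transient, where belt-frame foot position is constant.
contact_x <- function(series, side, td, delay = 0.02) {
  tr <- marker_track(series, "mtp5", side)
  ok <- !is.na(tr$x)
  approx(tr$t[ok], tr$x[ok], xout = td + delay, rule = 2)$y
}

#' Stride length
#'
#' Mean belt-frame distance between consecutive contacts of the same limb
#' over the analysis window. On a treadmill with a stationary-on-average
#' walker this equals `belt_speed * cycle_period`.
#'
#' @param series a belt-frame [marker_series()] (see [to_belt_frame()]).
#' @param events a [gait_events()] table.
#' @param side `"left"` or `"right"`.
#' @param window_strides analysis window in strides (default 10).
#' @param contact_delay seconds after touchdown at which the contact
#'   position is sampled.
#' @return mean stride length in cm.
#' @export
stride_length <- function(series, events, side, window_strides = 10L,
                          contact_delay = 0.02) {
  require_belt(series)
  td <- windowed_touchdowns(events, side, window_strides)
  if (length(td) < 2L)
    rg_insufficient_data("need at least 2 touchdowns on side '%s'", side)
  x <- contact_x(series, side, td, contact_delay)
  mean(abs(diff(x)))
}

#' Step length
#'
#' For each touchdown of the leading side, the belt-frame fore-aft distance
#' to the immediately preceding contralateral contact; reported per leading
#' side and averaged over the window. In a noiseless symmetric gait both
#' sides equal half the stride; in the SNL gait the left (operated) step
#' lengthens at the expense of the right.
#'
#' @inheritParams stride_length
#' @return mean step length in cm for the given leading side.
#' @export
step_length <- function(series, events, side, window_strides = 10L,
                        contact_delay = 0.02) {
  require_belt(series)
  other <- setdiff(SIDES, side)
  td <- windowed_touchdowns(events, side, window_strides)
  td_o <- events[[other]]$touchdown
  td_o <- td_o[is.finite(td_o)]
  if (!length(td_o) || !length(td))
    rg_insufficient_data("step length needs touchdowns on both sides")
  pairs <- lapply(td, function(tk) {
    prev <- td_o[td_o < tk]
    if (!length(prev)) NULL else c(tk, max(prev))
  })
  pairs <- Filter(Negate(is.null), pairs)
  if (!length(pairs))
    rg_insufficient_data("touchdowns never interleave; step length undefined")
  d <- vapply(pairs, function(p)
    contact_x(series, side, p[1L], contact_delay) -
      contact_x(series, other, p[2L], contact_delay), 0)
  mean(d)
}

# Touchdowns of one side inside the left-anchored analysis window, plus
# the closing boundary touchdown so that `window_strides` same-side
# intervals are available for the left limb.
windowed_touchdowns <- function(events, side, window_strides) {
  cyc <- segment_cycles(events, window_strides)
  if (side == "left")
    c(cyc$left$touchdown, cyc$left$next_touchdown[nrow(cyc$left)])
  else {
    td <- events$right$touchdown
    td <- td[is.finite(td)]
    inwin <- td[td >= cyc$span[1L] - .time_eps & td < cyc$span[2L] - .time_eps]
    nxt <- td[td >= cyc$span[2L] - .time_eps]
    if (length(nxt)) c(inwin, nxt[1L]) else inwin
  }
}

#' Both-foot contact time
#'
#' Total overlap of left and right stance phases (double support) within
#' the analysis window. The default cumulative mode reports the summed
#' overlap across the whole window — the magnitudes published for this
#' assay (1–2 s against a 0.64 s cycle) are only consistent with a
#' cumulative reading. `per_cycle_mean` divides by the number of strides.
#'
#' @param events a [gait_events()] table.
#' @param window_strides strides in the window (default 10); `NULL` uses
#'   the full event span.
#' @param mode `"cumulative"` or `"per_cycle_mean"`.
#' @return time in seconds.
#' @export
both_foot_contact_time <- function(events, window_strides = 10L,
                                   mode = c("cumulative", "per_cycle_mean")) {
  mode <- match.arg(mode)
  st_l <- stance_intervals(events, "left")
  st_r <- stance_intervals(events, "right")
  if (nrow(st_l) == 0L || nrow(st_r) == 0L)
    rg_insufficient_data("no stance intervals on one or both sides")
  if (is.null(window_strides)) {
    all_t <- unlist(lapply(SIDES, function(s)
      c(events[[s]]$touchdown, events[[s]]$lift_off)))
    all_t <- all_t[is.finite(all_t)]
    span <- range(all_t)
    n_cycles <- max(1L, length(events$left$touchdown[is.finite(events$left$touchdown)]) - 1L)
  } else {
    cyc <- segment_cycles(events, window_strides)
    span <- cyc$span
    n_cycles <- nrow(cyc$left)
  }
  total <- interval_intersection_length(
    clip_intervals(st_l, span[1L], span[2L]),
    clip_intervals(st_r, span[1L], span[2L]))
  switch(mode, cumulative = total, per_cycle_mean = total / n_cycles)
}

#' Circular (swing) phase durations
#'
#' Mean per-side time from lift-off to the next touchdown of the same limb
#' over the analysis window — the interval used to quantify interlimb
#' coordination.
#'
#' @inheritParams both_foot_contact_time
#' @return `c(left =, right =)` mean swing durations in seconds.
#' @export
circular_times <- function(events, window_strides = 10L) {
  cyc <- segment_cycles(events, window_strides)
  if (nrow(cyc$left) < 2L || nrow(cyc$right) < 2L)
    rg_insufficient_data("circular times need at least 2 full cycles per side")
  c(left  = mean(cyc$left$next_touchdown - cyc$left$lift_off),
    right = mean(cyc$right$next_touchdown - cyc$right$lift_off))
}

#' Circular-time ratio R
#'
#' `R = mean right circular time / mean left circular time`; 1 indicates
#' symmetric coordination, values below 1 a shortened right swing relative
#' to the (operated) left. With `normalization = "sham_normalized"` each
#' value is divided by the mean raw R of a sham reference cohort so that
#' the sham group mean is 1 by construction; raw values should always be
#' reported alongside.
#'
#' @param circular `c(left =, right =)` as from [circular_times()], or a
#'   numeric length-2 vector.
#' @param normalization `"raw"` or `"sham_normalized"`.
#' @param sham_reference numeric vector of raw R values of the sham cohort
#'   (required for sham normalization).
#' @return dimensionless ratio.
#' @export
r_value <- function(circular, normalization = c("raw", "sham_normalized"),
                    sham_reference = NULL) {
  normalization <- match.arg(normalization)
  if (is.null(names(circular))) names(circular) <- c("left", "right")
  if (!circular[["left"]] > 0)
    rg_parameter_error("R value undefined: left circular time must be > 0")
  r <- circular[["right"]] / circular[["left"]]
  if (normalization == "sham_normalized") {
    if (is.null(sham_reference) || !length(sham_reference))
      rg_config_error("sham_normalized R needs a sham reference cohort")
    r <- r / mean(sham_reference)
  }
  unname(r)
}
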