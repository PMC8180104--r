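# Automatic gait event detection from toe (mtp5) height, with manual
# tables taking precedence everywhere downstream. The reference assay
# entered events by hand; the detector exists so synthetic cohorts and
# unannotated recordings can be processed without manual labels.

#' Detect touchdown and lift-off events from toe height
#'
#' Threshold-on-height detection against the known belt plane `z = 0`:
#' a lift-off is an upward crossing of `z_thr` with positive vertical
#' velocity, a touchdown a downward crossing with non-positive velocity.
#' Candidate phases must clear a hysteresis band (swing must rise at least
#' `hysteresis` above the threshold, stance must fall the same amount
#' below) and last at least `min_phase` seconds; phases failing either test
#' are merged into their neighbours. The toe track is lightly smoothed
#' (centered moving average over `smooth_frames` samples) before
#' thresholding, and event times are refined by linear interpolation of the
#' threshold crossing, so they are not quantized to the frame grid.
#'
#' @param series a [marker_series()] containing both mtp5 markers.
#' @param z_thr height threshold in cm (default 0.15).
#' @param hysteresis hysteresis band in cm (default 0.05).
#' @param min_phase minimum stance/swing duration in s (default 0.05).
#' @param smooth_frames moving-average width in frames (default 5).
#' @return a [gait_events()] table with provenance `"detected"`.
#' @export
detect_events <- function(series, z_thr = 0.15, hysteresis = 0.05,
                          min_phase = 0.05, smooth_frames = 5L) {
  assert_scalar_number(z_thr, "z_thr", lower = 0, strict_lower = TRUE)
  assert_scalar_number(hysteresis, "hysteresis", lower = 0)
  assert_scalar_number(min_phase, "min_phase", lower = 0)
  ev <- lapply(SIDES, function(side) {
    tr <- marker_track(series, "mtp5", side)
    if (anyNA(tr$z)) {
      filled <- fill_missing(series)
      tr <- marker_track(filled, "mtp5", side)
    }
    detect_side(tr$t, tr$z, z_thr, hysteresis, min_phase, smooth_frames, side)
  })
  names(ev) <- SIDES
  gait_events(ev$left$touchdown, ev$left$lift_off,
              ev$right$touchdown, ev$right$lift_off,
              provenance = "detected")
}

detect_side <- function(t, z, z_thr, hysteresis, min_phase, smooth_frames,
                        side) {
  zs <- moving_average(z, smooth_frames)
  n <- length(zs)
  above <- zs > z_thr
  flips <- which(above[-1L] != above[-n])        # crossing between i and i+1
  if (!length(flips))
    rg_insufficient_data("toe never crosses the height threshold on side '%s'", side)
  dirs <- ifelse(above[flips + 1L], "up", "down")
  times <- t[flips] + (z_thr - zs[flips]) / (zs[flips + 1L] - zs[flips]) *
    (t[flips + 1L] - t[flips])
  # velocity sign guard at the crossing
  vel <- (zs[pmin(flips + 1L, n)] - zs[pmax(flips - 1L, 1L)]) /
    (t[pmin(flips + 1L, n)] - t[pmax(flips - 1L, 1L)])
  keep <- (dirs == "up" & vel > 0) | (dirs == "down" & vel <= 0)
  dirs <- dirs[keep]; times <- times[keep]; flips <- flips[keep]

  # amplitude (hysteresis) and duration debouncing: repeatedly drop the
  # crossing pair bounding any phase that is too shallow or too brief.
  repeat {
    k <- length(times)
    if (k == 0L) break
    drop <- integer(0)
    for (i in seq_len(k - 1L)) {
      seg <- zs[(flips[i] + 1L):flips[i + 1L]]
      shallow <- if (dirs[i] == "up")
        max(seg) < z_thr + hysteresis else min(seg) > z_thr - hysteresis
      brief <- (times[i + 1L] - times[i]) < min_phase
      if (shallow || brief) { drop <- c(i, i + 1L); break }
    }
    if (!length(drop)) break
    keep <- setdiff(seq_len(k), drop)
    dirs <- dirs[keep]; times <- times[keep]; flips <- flips[keep]
  }
  touchdown <- times[dirs == "down"]
  lift_off  <- times[dirs == "up"]
  if (length(touchdown) < 3L)
    rg_insufficient_data(
      "fewer than 2 complete gait cycles detected on side '%s' (%d touchdowns)",
      side, length(touchdown))
  list(touchdown = touchdown, lift_off = lift_off)
}

#' Segment an event table into windowed gait cycles
#'
#' A cycle runs touchdown -> lift-off -> next touchdown of the same limb
#' (stance `[touchdown, lift_off)`, swing `[lift_off, next touchdown)`;
#' half-open so every instant belongs to exactly one phase). The analysis
#' window is anchored on the left limb: the first `window_strides` complete
#' left cycles are retained and the right-limb cycles are those whose
#' touchdown falls inside the same time span. Partial cycles at the trial
#' edges are discarded.
#'
#' @param events a [gait_events()] table.
#' @param window_strides number of left cycles to keep (default 10, the
#'   number of steps analyzed per animal); `NULL` keeps all complete
#'   cycles.
#' @return an object of class `gait_cycles`: per-side data.frames with
#'   columns `touchdown`, `lift_off`, `next_touchdown`, plus the window
#'   `span`.
#' @export
segment_cycles <- function(events, window_strides = 10L) {
  stopifnot(inherits(events, "gait_events"))
  cyc <- lapply(SIDES, function(side) {
    td <- events[[side]]$touchdown
    lo <- events[[side]]$lift_off
    td <- td[is.finite(td)]
    if (length(td) < 2L) return(data.frame(touchdown = numeric(0),
                                           lift_off = numeric(0),
                                           next_touchdown = numeric(0)))
    rows <- lapply(seq_len(length(td) - 1L), function(k) {
      l <- lo[lo > td[k] & lo < td[k + 1L]]
      if (length(l) != 1L) return(NULL)
      data.frame(touchdown = td[k], lift_off = l, next_touchdown = td[k + 1L])
    })
    do.call(rbind, Filter(Negate(is.null), rows))
  })
  names(cyc) <- SIDES
  if (!is.null(window_strides)) {
    if (window_strides < 2L)
      rg_parameter_error("analysis window must cover at least 2 strides")
    if (nrow(cyc$left) < window_strides)
      rg_insufficient_data(
        "only %d complete left cycles available, %d required",
        nrow(cyc$left), window_strides)
    cyc$left <- cyc$left[seq_len(window_strides), , drop = FALSE]
  }
  if (is.null(cyc$left) || nrow(cyc$left) == 0L)
    rg_insufficient_data("no complete left cycles in the event table")
  span <- c(cyc$left$touchdown[1L],
            cyc$left$next_touchdown[nrow(cyc$left)])
  cyc$right <- cyc$right[cyc$right$touchdown >= span[1L] - .time_eps &
                           cyc$right$touchdown < span[2L] - .time_eps, ,
                         drop = FALSE]
  structure(list(left = cyc$left, right = cyc$right, span = span,
                 window_strides = window_strides,
                 provenance = events$provenance),
            class = "gait_cycles")
}

#' @export
print.gait_cycles <- function(x, ...) {
  cat(sprintf("<gait_cycles> [%s] %d left / %d right cycles over [%.3f, %.3f] s\n",
              x$provenance, nrow(x$left), nrow(x$right), x$span[1L], x$span[2L]))
  invisible(x)
}
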