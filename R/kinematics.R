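# Sagittal joint-trajectory summaries. The sagittal plane is (x, z); y is
# ignored. The headline metric is the per-cycle top-minus-bottom height of
# a joint marker — the joint "fluctuation" that separates SNL from sham.

frames_in <- function(t, lo, hi) t >= lo - .time_eps & t < hi - .time_eps

#' Top-minus-bottom fluctuation height of a joint marker
#'
#' For each gait cycle of the given side, the vertical range
#' `max(z) - min(z)` of the marker; the animal-level value is the mean over
#' the analysis window. A per-cycle range is reported rather than a
#' whole-trial range because a trial-level max minus min conflates slow
#' postural drift with within-stride fluctuation; `scope = "trial"` is
#' available for the alternative reading.
#'
#' @param series a [marker_series()] (lab or belt frame; z is unaffected).
#' @param cycles a [segment_cycles()] result.
#' @param joint one of `"iliac"`, `"hip"`, `"knee"`, `"ankle"`, `"mtp5"`.
#' @param side `"left"` or `"right"`.
#' @param scope `"cycle"` (default) or `"trial"`.
#' @return an object of class `fluctuation_result`: list with `per_cycle`,
#'   `mean`, `sd`, `joint`, `side`, `scope`.
#' @export
fluctuation_height <- function(series, cycles, joint, side,
                               scope = c("cycle", "trial")) {
  scope <- match.arg(scope)
  stopifnot(inherits(cycles, "gait_cycles"))
  cyc <- cycles[[side]]
  if (nrow(cyc) < 1L)
    rg_insufficient_data("no complete cycles on side '%s'", side)
  tr <- marker_track(series, joint, side)
  if (scope == "trial") {
    sel <- frames_in(tr$t, cycles$span[1L], cycles$span[2L])
    z <- tr$z[sel]
    z <- z[!is.na(z)]
    if (!length(z)) rg_insufficient_data("marker %s/%s has no data in window", joint, side)
    h <- max(z) - min(z)
    return(structure(list(per_cycle = h, mean = h, sd = NA_real_,
                          joint = joint, side = side, scope = scope),
                     class = "fluctuation_result"))
  }
  per <- vapply(seq_len(nrow(cyc)), function(k) {
    sel <- frames_in(tr$t, cyc$touchdown[k], cyc$next_touchdown[k])
    z <- tr$z[sel]
    z <- z[!is.na(z)]
    if (length(z) < 2L) return(NA_real_)
    max(z) - min(z)
  }, 0)
  if (anyNA(per)) {
    warning(sprintf("%d cycle(s) skipped for %s/%s (missing marker data)",
                    sum(is.na(per)), joint, side))
    per <- per[!is.na(per)]
  }
  if (!length(per))
    rg_insufficient_data("all cycles skipped for %s/%s", joint, side)
  structure(list(per_cycle = per, mean = mean(per), sd = sd(per),
                 joint = joint, side = side, scope = scope),
            class = "fluctuation_result")
}

#' @export
print.fluctuation_result <- function(x, ...) {
  cat(sprintf("<fluctuation> %s/%s: %.3f cm (SD %.3f over %d cycles, %s scope)\n",
              x$joint, x$side, x$mean, x$sd %||% NA, length(x$per_cycle), x$scope))
  invisible(x)
}

#' Phase-normalized mean trajectory of a joint marker
#'
#' Each cycle's vertical trajectory is linearly resampled onto a common
#' grid of normalized cycle phase (0 = touchdown, 1 = next touchdown) and
#' averaged pointwise across cycles — the per-animal version of the
#' published sagittal trajectory panels.
#'
#' @inheritParams fluctuation_height
#' @param n_grid number of phase grid points (>= 10).
#' @return an object of class `phase_profile`: list with `phase`, `mean`,
#'   `sd`, `n_cycles`, `joint`, `side`.
#' @export
phase_profile <- function(series, cycles, joint, side, n_grid = 101L) {
  if (n_grid < 10L) rg_parameter_error("n_grid must be at least 10")
  cyc <- cycles[[side]]
  if (nrow(cyc) < 2L)
    rg_insufficient_data("phase profile needs at least 2 cycles")
  tr <- marker_track(series, joint, side)
  grid <- seq(0, 1, length.out = n_grid)
  mat <- vapply(seq_len(nrow(cyc)), function(k) {
    t0 <- cyc$touchdown[k]; t1 <- cyc$next_touchdown[k]
    sel <- tr$t >= t0 - 2 * .time_eps & tr$t <= t1 + 2 * .time_eps & !is.na(tr$z)
    approx((tr$t[sel] - t0) / (t1 - t0), tr$z[sel], xout = grid, rule = 2)$y
  }, numeric(n_grid))
  structure(list(phase = grid,
                 mean = rowMeans(mat),
                 sd = apply(mat, 1L, sd),
                 n_cycles = ncol(mat), joint = joint, side = side),
            class = "phase_profile")
}

#' Ankle swing-slope ratio
#'
#' Operationalizes the characteristic SNL ankle pattern — a shallow rise
#' over the first two thirds of swing followed by a rapid rise over the
#' last third — as the ratio of least-squares slopes of ankle height
#' against normalized swing phase, fitted on `u in [0, 2/3]` and
#' `u in [2/3, 1]`, averaged across cycles. Ratios near 1 indicate a
#' uniform rise (sham-like); SNL-like trials exceed 2.
#'
#' @inheritParams fluctuation_height
#' @param eps lower clip for the early-swing slope, to keep the ratio
#'   finite when the early swing is flat (clipping is reported with a
#'   warning).
#' @return mean ratio (dimensionless) with per-cycle values in attribute
#'   `"per_cycle"`.
#' @export
ankle_swing_slope_ratio <- function(series, cycles, side, eps = 1e-6) {
  cyc <- cycles[[side]]
  if (nrow(cyc) < 1L) rg_insufficient_data("no cycles on side '%s'", side)
  tr <- marker_track(series, "ankle", side)
  clipped <- 0L
  per <- vapply(seq_len(nrow(cyc)), function(k) {
    l <- cyc$lift_off[k]; t1 <- cyc$next_touchdown[k]
    sel <- tr$t >= l - .time_eps & tr$t <= t1 + .time_eps & !is.na(tr$z)
    if (sum(sel) < 4L) return(NA_real_)
    u <- (tr$t[sel] - l) / (t1 - l)
    z <- tr$z[sel]
    a <- u <= 2 / 3; b <- u >= 2 / 3
    if (sum(a) < 2L || sum(b) < 2L) return(NA_real_)
    s1 <- coef(lm(z[a] ~ u[a]))[[2L]]
    s2 <- coef(lm(z[b] ~ u[b]))[[2L]]
    if (s1 < eps) { clipped <<- clipped + 1L; s1 <- eps }
    s2 / s1
  }, 0)
  per <- per[!is.na(per)]
  if (!length(per)) rg_insufficient_data("no usable swing samples on side '%s'", side)
  if (clipped > 0L)
    warning(sprintf("early-swing slope clipped at %g in %d cycle(s)", eps, clipped))
  structure(mean(per), per_cycle = per)
}
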