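#' @import data.table
#' @importFrom stats approx lm coef rnorm sd pt pnorm pwilcox uniroot
#' @importFrom utils head tail
NULL

#' Marker and coordinate conventions
#'
#' Ten colored markers are tracked, five per hind-limb: iliac crest, hip,
#' knee, ankle and 5th metatarsophalangeal (toe) joint. Coordinates are in
#' centimetres with `x` the direction of animal progression, `y` lateral and
#' `z` vertical; the treadmill belt surface is `z = 0`. Times are in
#' seconds. Trajectories are recorded in the laboratory frame; for stride
#' and step distances they are mapped to the belt frame with
#' [to_belt_frame()].
#'
#' @name gait-conventions
NULL

MARKERS  <- c("iliac", "hip", "knee", "ankle", "mtp5")
SIDES    <- c("left", "right")
SESSIONS <- c("pre_op", "wk1", "wk2", "wk4")

#' Construct a marker trajectory series
#'
#' Bundles the long-form trajectory table of one treadmill trial with its
#' acquisition metadata and validates the container invariants: strictly
#' increasing, uniformly spaced timestamps; all ten markers present in every
#' frame (missing positions are explicit `NA`s); toe markers not materially
#' below the belt surface.
#'
#' @param frames data.frame with columns `t`, `marker`, `side`, `x`, `y`,
#'   `z` (long form, one row per marker per frame).
#' @param animal_id character scalar.
#' @param session one of `"pre_op"`, `"wk1"`, `"wk2"`, `"wk4"`.
#' @param sample_rate sampling rate in Hz (> 0).
#' @param belt_speed treadmill belt speed in cm/s (>= 0; 20 cm/s = 12 m/min,
#'   the training speed used for this model).
#' @param frame `"lab"` (camera frame) or `"belt"` (belt-fixed frame).
#' @return An object of class `marker_series` (a data.frame with metadata
#'   attributes).
#' @export
marker_series <- function(frames, animal_id = "unknown", session = "wk4",
                          sample_rate = 100, belt_speed = 20,
                          frame = c("lab", "belt")) {
  frame <- match.arg(frame)
  need <- c("t", "marker", "side", "x", "y", "z")
  if (!is.data.frame(frames) || !all(need %in% names(frames)))
    rg_format_error("trajectory table must have columns %s",
                    paste(need, collapse = ", "))
  frames <- as.data.frame(frames)[, need]
  bad_m <- setdiff(unique(frames$marker), MARKERS)
  if (length(bad_m))
    rg_validation_error("unknown marker name(s): %s", paste(bad_m, collapse = ", "))
  bad_s <- setdiff(unique(frames$side), SIDES)
  if (length(bad_s))
    rg_validation_error("unknown side(s): %s", paste(bad_s, collapse = ", "))
  if (!session %in% SESSIONS)
    rg_validation_error("unknown session '%s'", session)
  assert_scalar_number(sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  assert_scalar_number(belt_speed, "belt_speed", lower = 0)
  if (nrow(frames) == 0L)
    rg_validation_error("trajectory contains no frames")

  tt <- sort(unique(frames$t))
  if (length(tt) < length(frames$t) / 10)
    rg_validation_error("duplicated timestamp in trajectory (first at t = %g s)",
                        tt[which(tabulate(match(frames$t, tt)) > 10L)][1L])
  if (any(diff(tt) <= 0))
    rg_validation_error("timestamps are not strictly increasing")
  if (length(tt) > 1L) {
    dt <- diff(tt)
    if (max(dt) - min(dt) > 1e-9)
      rg_validation_error("timestamps are not uniformly spaced (max jitter %g s)",
                          max(dt) - min(dt))
  }
  counts <- table(frames$t)
  if (any(counts != length(MARKERS) * length(SIDES)))
    rg_validation_error(
      "every frame must carry all %d marker positions (first bad frame t = %g s)",
      length(MARKERS) * length(SIDES),
      as.numeric(names(counts))[which(counts != 10L)[1L]])
  toe_z <- frames$z[frames$marker == "mtp5"]
  if (any(toe_z < -0.5, na.rm = TRUE))
    rg_validation_error("mtp5 marker is below the belt surface (min z = %g cm)",
                        min(toe_z, na.rm = TRUE))

  o <- order(frames$t, frames$side, match(frames$marker, MARKERS))
  frames <- frames[o, , drop = FALSE]
  rownames(frames) <- NULL
  structure(frames,
            animal_id = as.character(animal_id), session = session,
            sample_rate = sample_rate, belt_speed = belt_speed,
            frame = frame,
            class = c("marker_series", "data.frame"))
}

#' @export
print.marker_series <- function(x, ...) {
  tt <- unique(x$t)
  cat(sprintf(
    "<marker_series> animal %s, session %s: %d frames @ %g Hz, belt %g cm/s [%s frame]\n",
    attr(x, "animal_id"), attr(x, "session"), length(tt),
    attr(x, "sample_rate"), attr(x, "belt_speed"), attr(x, "frame")))
  invisible(x)
}

series_meta <- function(s) {
  attributes(s)[c("animal_id", "session", "sample_rate", "belt_speed", "frame")]
}

#' Extract one marker track
#'
#' @param series a [marker_series()].
#' @param marker,side marker and side names.
#' @return data.frame with columns `t`, `x`, `y`, `z` ordered in time.
#' @export
marker_track <- function(series, marker, side) {
  sel <- series$marker == marker & series$side == side
  out <- as.data.frame(series)[sel, c("t", "x", "y", "z")]
  rownames(out) <- NULL
  out
}

#' Interpolate short marker dropouts
#'
#' Positions flagged `NA` are filled by linear interpolation in time when a
#' dropout run spans at most `max_gap` consecutive frames; longer runs
#' reject the trial, because interpolating across a substantial fraction of
#' a swing phase would fabricate kinematics.
#'
#' @param series a [marker_series()].
#' @param max_gap maximum run of consecutive missing frames to bridge.
#' @return the series with gaps filled.
#' @export
fill_missing <- function(series, max_gap = 5L) {
  df <- as.data.frame(series)
  for (m in MARKERS) for (sd_ in SIDES) {
    sel <- which(df$marker == m & df$side == sd_)
    for (col in c("x", "y", "z")) {
      v <- df[[col]][sel]
      if (!anyNA(v)) next
      r <- rle(is.na(v))
      if (any(r$values & r$lengths > max_gap))
        rg_validation_error(
          "marker %s/%s missing for %d consecutive frames (> %d): trial rejected",
          m, sd_, max(r$lengths[r$values]), max_gap)
      if (all(is.na(v)))
        rg_validation_error("marker %s/%s entirely missing", m, sd_)
      df[[col]][sel] <- approx(df$t[sel][!is.na(v)], v[!is.na(v)],
                               xout = df$t[sel], rule = 2)$y
    }
  }
  meta <- series_meta(series)
  marker_series(df, animal_id = meta$animal_id, session = meta$session,
                sample_rate = meta$sample_rate, belt_speed = meta$belt_speed,
                frame = meta$frame)
}

#' Map a trajectory into the treadmill belt frame
#'
#' On a treadmill the animal is stationary on average, so lab-frame foot
#' placements carry no distance information. Adding `belt_speed * t` to `x`
#' re-expresses the trajectory in the frame of the moving belt surface, in
#' which treadmill locomotion looks like overground walking and stride and
#' step lengths have their usual meaning.
#'
#' @param series a lab-frame [marker_series()].
#' @return the series with `x` replaced by `x + belt_speed * t` and the
#'   frame attribute set to `"belt"`.
#' @export
to_belt_frame <- function(series) {
  if (attr(series, "frame") == "belt")
    rg_config_error("series is already in the belt frame")
  df <- as.data.frame(series)
  df$x <- df$x + attr(series, "belt_speed") * df$t
  meta <- series_meta(series)
  marker_series(df, animal_id = meta$animal_id, session = meta$session,
                sample_rate = meta$sample_rate, belt_speed = meta$belt_speed,
                frame = "belt")
}

#' Read a trajectory CSV
#'
#' The canonical dialect is a long-form CSV with leading metadata comment
#' lines `#animal_id=`, `#session=`, `#sample_rate_hz=`, `#belt_speed_cm_s=`
#' (and optionally `#frame=`), followed by a `t,marker,side,x,y,z` table.
#' C3D import is not available in this build (no C3D reader in the R
#' toolchain); the argument is kept so scripts written against the richer
#' interface fail with a clear message.
#'
#' @param path file path.
#' @param dialect `"csv"` (canonical) or `"c3d"` (unsupported here).
#' @return a validated [marker_series()].
#' @export
read_trajectory <- function(path, dialect = c("csv", "c3d")) {
  dialect <- match.arg(dialect)
  if (dialect == "c3d")
    rg_config_error("C3D import is not available in this build; convert to the CSV dialect")
  if (!file.exists(path)) rg_config_error("file '%s' does not exist", path)
  meta <- read_meta_lines(path)
  for (k in c("sample_rate_hz", "belt_speed_cm_s"))
    if (is.null(meta$values[[k]]))
      rg_config_error("trajectory file is missing required metadata '#%s='", k)
  df <- as.data.frame(data.table::fread(path, skip = meta$n, header = TRUE))
  need <- c("t", "marker", "side", "x", "y", "z")
  if (!all(need %in% names(df)))
    rg_format_error("malformed trajectory header: expected columns %s",
                    paste(need, collapse = ", "))
  marker_series(df,
                animal_id  = meta$values$animal_id %||% "unknown",
                session    = meta$values$session %||% "wk4",
                sample_rate = as.numeric(meta$values$sample_rate_hz),
                belt_speed  = as.numeric(meta$values$belt_speed_cm_s),
                frame       = meta$values$frame %||% "lab")
}

#' Write a trajectory CSV
#'
#' Inverse of [read_trajectory()]: positions are serialized with 15
#' significant digits so a write/read round trip reproduces the series to
#' better than 1e-9 cm. Output is byte-stable for a fixed input.
#'
#' @param series a [marker_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(series, path) {
  if (nrow(series) == 0L) rg_validation_error("refusing to write an empty series")
  meta <- series_meta(series)
  hdr <- c(sprintf("#animal_id=%s", meta$animal_id),
           sprintf("#session=%s", meta$session),
           sprintf("#sample_rate_hz=%.15g", meta$sample_rate),
           sprintf("#belt_speed_cm_s=%.15g", meta$belt_speed),
           sprintf("#frame=%s", meta$frame))
  writeLines(hdr, path)
  data.table::fwrite(as.data.frame(series), path, append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

# Parse leading '#key=value' lines; returns the count and a named list.
read_meta_lines <- function(path) {
  lines <- readLines(path, n = 50L)
  is_meta <- grepl("^#", lines)
  n <- if (any(!is_meta)) which(!is_meta)[1L] - 1L else length(lines)
  vals <- list()
  for (ln in lines[seq_len(n)]) {
    kv <- sub("^#", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0)
      vals[[substr(kv, 1L, eq - 1L)]] <- substr(kv, eq + 1L, nchar(kv))
  }
  list(n = n, values = vals)
}
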