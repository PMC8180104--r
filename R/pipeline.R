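# End-to-end analysis: trial -> per-animal gait summary -> cohort tables
# -> group comparisons -> report files.

#' Analysis configuration
#'
#' @param window_strides strides per analysis window (>= 2; default 10).
#' @param z_thr,hysteresis,min_phase,smooth_frames event-detector settings
#'   (see [detect_events()]).
#' @param contact_mode both-foot contact reporting:
#'   `"cumulative"` (default) or `"per_cycle_mean"`.
#' @param r_normalization `"raw"` or `"sham_normalized"`.
#' @param contact_delay s after touchdown at which contact position is read.
#' @param fluctuation_scope `"cycle"` or `"trial"`.
#' @param seed optional integer seed recorded into reports.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(window_strides = 10L, z_thr = 0.15,
                            hysteresis = 0.05, min_phase = 0.05,
                            smooth_frames = 5L,
                            contact_mode = c("cumulative", "per_cycle_mean"),
                            r_normalization = c("raw", "sham_normalized"),
                            contact_delay = 0.02,
                            fluctuation_scope = c("cycle", "trial"),
                            seed = NULL) {
  if (window_strides < 2L)
    rg_parameter_error("window_strides must be at least 2")
  for (v in c(z_thr = z_thr, min_phase = min_phase, contact_delay = contact_delay))
    if (v <= 0) rg_parameter_error("detector thresholds must be positive")
  structure(list(window_strides = as.integer(window_strides), z_thr = z_thr,
                 hysteresis = hysteresis, min_phase = min_phase,
                 smooth_frames = as.integer(smooth_frames),
                 contact_mode = match.arg(contact_mode),
                 r_normalization = match.arg(r_normalization),
                 contact_delay = contact_delay,
                 fluctuation_scope = match.arg(fluctuation_scope),
                 seed = seed),
            class = "analysis_config")
}

#' Analyze one trial into a per-animal gait summary
#'
#' Detects events (unless a manual/ground-truth table is supplied, which
#' always takes precedence), segments the analysis window, and computes
#' every gait parameter: per-side stride and step lengths (belt frame),
#' cumulative both-foot contact time, circular times and raw R, per-joint
#' fluctuation heights and the ankle swing-slope ratio.
#'
#' @param series a lab-frame [marker_series()].
#' @param events optional [gait_events()]; `NULL` triggers detection.
#' @param config an [analysis_config()].
#' @return one-row data.frame of metrics plus identifying columns.
#' @export
analyze_trial <- function(series, events = NULL, config = analysis_config()) {
  if (is.null(events))
    events <- detect_events(series, z_thr = config$z_thr,
                            hysteresis = config$hysteresis,
                            min_phase = config$min_phase,
                            smooth_frames = config$smooth_frames)
  cycles <- segment_cycles(events, config$window_strides)
  belt <- if (attr(series, "frame") == "belt") series else to_belt_frame(series)
  circ <- circular_times(events, config$window_strides)
  fl <- function(j, s) fluctuation_height(series, cycles, j, s,
                                          scope = config$fluctuation_scope)$mean
  data.frame(
    animal_id = attr(series, "animal_id"),
    session = attr(series, "session"),
    event_provenance = events$provenance,
    stride_left  = stride_length(belt, events, "left",  config$window_strides,
                                 config$contact_delay),
    stride_right = stride_length(belt, events, "right", config$window_strides,
                                 config$contact_delay),
    step_left  = step_length(belt, events, "left",  config$window_strides,
                             config$contact_delay),
    step_right = step_length(belt, events, "right", config$window_strides,
                             config$contact_delay),
    both_foot_contact = both_foot_contact_time(events, config$window_strides,
                                               config$contact_mode),
    circular_left = circ[["left"]], circular_right = circ[["right"]],
    r_raw = r_value(circ),
    hip_left = fl("hip", "left"), hip_right = fl("hip", "right"),
    knee_left = fl("knee", "left"), knee_right = fl("knee", "right"),
    ankle_left = fl("ankle", "left"), ankle_right = fl("ankle", "right"),
    ankle_slope_ratio_left = as.numeric(ankle_swing_slope_ratio(series, cycles, "left")),
    ankle_slope_ratio_right = as.numeric(ankle_swing_slope_ratio(series, cycles, "right")))
}

#' Analyze a list of trials
#'
#' @param trials list of trials: each element either a [marker_series()] or
#'   a list with elements `series` and (optionally) `events` / `truth`
#'   (as produced by [simulate_cohort()]).
#' @param config an [analysis_config()].
#' @param use_truth_events if `TRUE` and a trial carries ground-truth
#'   events, use them instead of detection.
#' @return data.frame, one row per trial.
#' @export
analyze_cohort <- function(trials, config = analysis_config(),
                           use_truth_events = FALSE) {
  rows <- lapply(trials, function(tr) {
    if (inherits(tr, "marker_series")) tr <- list(series = tr)
    ev <- tr$events %||% (if (use_truth_events) tr$truth$events else NULL)
    analyze_trial(tr$series, events = ev, config = config)
  })
  do.call(rbind, rows)
}

GAIT_METRICS <- c("stride_left", "stride_right", "step_left", "step_right",
                  "both_foot_contact", "circular_left", "circular_right",
                  "r_raw", "hip_left", "hip_right", "knee_left", "knee_right",
                  "ankle_left", "ankle_right")

#' Run the full cohort pipeline on a directory
#'
#' Expects `manifest.csv` in `input_dir` with columns `animal_id`, `group`
#' (`sham` / `SNL`), `session`, `trajectory` (CSV path relative to the
#' directory) and optionally `events` (manual event CSV; empty to detect),
#' plus an optional `vonfrey.csv`. Produces per-animal metrics, SNL-vs-sham
#' Mann-Whitney comparisons for every gait metric, left-vs-right paired
#' t-tests within the SNL group, and (when von Frey data are present) the
#' allodynia summary. Writes `per_animal.csv`, `comparisons.csv` and
#' `report.json` to `output_dir`.
#'
#' @param input_dir input directory.
#' @param output_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @param config an [analysis_config()].
#' @return the report list, invisibly.
#' @export
run_pipeline <- function(input_dir, output_dir = NULL,
                         config = analysis_config()) {
  man_path <- file.path(input_dir, "manifest.csv")
  if (!dir.exists(input_dir) || !file.exists(man_path))
    rg_config_error("input directory '%s' has no manifest.csv", input_dir)
  man <- as.data.frame(data.table::fread(man_path, header = TRUE))
  need <- c("animal_id", "group", "session", "trajectory")
  if (!all(need %in% names(man)))
    rg_format_error("manifest must have columns %s", paste(need, collapse = ", "))
  if (any(!nzchar(man$group)) || any(is.na(man$group)))
    rg_validation_error("every manifest row needs a group label")
  if (!nrow(man)) rg_validation_error("manifest is empty")

  rows <- lapply(seq_len(nrow(man)), function(i) {
    s <- read_trajectory(file.path(input_dir, man$trajectory[i]))
    ev <- NULL
    if ("events" %in% names(man) && !is.na(man$events[i]) && nzchar(man$events[i]))
      ev <- read_events(file.path(input_dir, man$events[i]))
    cbind(analyze_trial(s, events = ev, config = config),
          group = man$group[i], sample_rate = attr(s, "sample_rate"))
  })
  per_animal <- do.call(rbind, rows)
  if (length(unique(per_animal$sample_rate)) > 1L)
    rg_validation_error("mixed sampling rates across trials: %s Hz",
                        paste(unique(per_animal$sample_rate), collapse = ", "))
  per_animal$sample_rate <- NULL

  snl  <- per_animal[per_animal$group == "SNL", ]
  sham <- per_animal[per_animal$group == "sham", ]
  comparisons <- NULL
  if (nrow(snl) >= 3L && nrow(sham) >= 3L)
    comparisons <- compare_groups(snl, sham, metrics = GAIT_METRICS)
  paired <- NULL
  if (nrow(snl) >= 3L) {
    paired <- do.call(rbind, lapply(
      list(c("step_left", "step_right"), c("stride_left", "stride_right"),
           c("hip_left", "hip_right"), c("knee_left", "knee_right")),
      function(pair) {
        res <- tryCatch(paired_t(snl[[pair[1L]]], snl[[pair[2L]]]),
                        rg_error = function(e) NULL)
        if (is.null(res)) return(NULL)
        data.frame(metric = sub("_left$", "", pair[1L]), t = res$t,
                   df = res$df, p = res$p, significant = res$p < 0.05)
      }))
  }
  allodynia <- NULL
  vf_path <- file.path(input_dir, "vonfrey.csv")
  if (file.exists(vf_path)) {
    vf <- read_vonfrey(vf_path)
    allodynia <- threshold_summary(vf)
  }
  report <- list(config = unclass(config),
                 n_animals = nrow(per_animal),
                 per_animal = per_animal,
                 comparisons = comparisons,
                 paired_left_right_snl = paired,
                 allodynia = if (!is.null(allodynia))
                   list(overall = allodynia$overall, weekly = allodynia$weekly))
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(per_animal, file.path(output_dir, "per_animal.csv"))
    if (!is.null(comparisons))
      data.table::fwrite(comparisons, file.path(output_dir, "comparisons.csv"))
    if (requireNamespace("jsonlite", quietly = TRUE))
      jsonlite::write_json(report, file.path(output_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
  }
  invisible(report)
}
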