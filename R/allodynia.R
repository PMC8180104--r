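# Von Frey mechanical allodynia: a probe ramps from 1 to 50 g over 20 s;
# the withdrawal threshold is recorded as the time (s) into the ramp at
# which the paw is withdrawn, three trials per paw at 5-min intervals.
# The headline statistic is the percent decrease of the operated (left)
# paw threshold relative to the intact right paw.

#' Construct / validate a von Frey record table
#'
#' @param df data.frame with columns `animal_id`, `week` (integer, 0 =
#'   pre-op), `side`, `trial` (1..3), `threshold_time_s` in (0, 20].
#' @return the validated table, class `vonfrey_records`.
#' @export
vonfrey_records <- function(df) {
  need <- c("animal_id", "week", "side", "trial", "threshold_time_s")
  if (!is.data.frame(df) || !all(need %in% names(df)))
    rg_format_error("von Frey table must have columns %s",
                    paste(need, collapse = ", "))
  df <- as.data.frame(df)[, need]
  if (any(!df$side %in% SIDES))
    rg_validation_error("unknown side in von Frey table")
  if (any(df$week < 0L | df$week > 8L))
    rg_validation_error("week must be in 0..8")
  if (any(df$threshold_time_s <= 0 | df$threshold_time_s > 20))
    rg_validation_error("withdrawal threshold times must lie in (0, 20] s")
  counts <- table(df$animal_id, df$week, df$side)
  if (any(counts != 0L & counts != 3L))
    rg_validation_error("each (animal, week, side) needs exactly 3 trials")
  df <- df[order(df$animal_id, df$week, df$side, df$trial), ]
  rownames(df) <- NULL
  structure(df, class = c("vonfrey_records", "data.frame"))
}

#' Read / write a von Frey CSV
#'
#' Plain CSV with columns `animal_id,week,side,trial,threshold_time_s`.
#'
#' @param path file path.
#' @return [vonfrey_records()] for the reader; `path` invisibly for the
#'   writer.
#' @export
read_vonfrey <- function(path) {
  if (!file.exists(path)) rg_config_error("file '%s' does not exist", path)
  vonfrey_records(as.data.frame(data.table::fread(path, header = TRUE)))
}

#' @rdname read_vonfrey
#' @param records a [vonfrey_records()] table.
#' @export
write_vonfrey <- function(records, path) {
  data.table::fwrite(as.data.frame(records), path)
  invisible(path)
}

#' Simulate a von Frey cohort with unilateral allodynia
#'
#' Right-paw thresholds are drawn per animal around `right_mean` with
#' between-animal SD `right_sd`; the per-animal-week percent decrease
#' `delta` is drawn around `delta_mean` (SD `delta_sd`, truncated
#' symmetrically so the mean is preserved) and the left paw threshold is
#' `right * (1 - delta)`. Three trials per side per week add small
#' within-animal noise. Defaults reproduce the published SNL effect: a 47%
#' mean decrease with a weekly cohort-mean SE of about 6 points
#' (`delta_sd = 0.061 * sqrt(10)`).
#'
#' @param n_animals cohort size.
#' @param weeks integer vector of post-operative weeks.
#' @param delta_mean mean fractional decrease, in (0, 1).
#' @param delta_sd between animal-week SD of the decrease.
#' @param right_mean,right_sd mean / between-animal SD of the intact-paw
#'   threshold time (s).
#' @param trial_sd within-animal trial noise SD (s).
#' @param seed integer seed.
#' @return a [vonfrey_records()] table; the realized per-animal-week
#'   decreases are attached as attribute `"truth"`.
#' @export
simulate_vonfrey_cohort <- function(n_animals = 10L, weeks = 1:8,
                                    delta_mean = 0.47,
                                    delta_sd = 0.061 * sqrt(10),
                                    right_mean = 10, right_sd = 1.5,
                                    trial_sd = 0.5, seed = 1L) {
  if (delta_mean <= 0 || delta_mean >= 1)
    rg_parameter_error("delta_mean must lie strictly in (0, 1)")
  rows <- list(); truth <- list()
  for (a in seq_len(n_animals)) {
    set.seed(derive_seed(seed, a))
    id <- sprintf("vf_%02d", a)
    right_base <- rnorm_trunc_sym(1, right_mean, right_sd, 1, 19)
    for (w in weeks) {
      delta <- rnorm_trunc_sym(1, delta_mean, delta_sd, 0, 1)
      r_tr <- rnorm_trunc_sym(3, right_base, trial_sd, 0.5, 19.9)
      l_tr <- rnorm_trunc_sym(3, right_base * (1 - delta), trial_sd, 0.1, 19.9)
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = id, week = as.integer(w),
        side = rep(SIDES, each = 3L), trial = rep(1:3, 2L),
        threshold_time_s = c(l_tr, r_tr))
      truth[[length(truth) + 1L]] <- data.frame(animal_id = id,
                                                week = as.integer(w),
                                                delta = delta)
    }
  }
  out <- vonfrey_records(do.call(rbind, rows))
  attr(out, "truth") <- do.call(rbind, truth)
  out
}

#' Summarize withdrawal thresholds into the percent-decrease statistic
#'
#' Per animal and week, each side's three trials are averaged and the
#' percent decrease `100 * (right - left) / right` computed; weekly cohort
#' means average over animals; the overall value averages the weekly
#' cohort means across post-operative weeks (weeks equally weighted), with
#' a normal-approximation 95% confidence interval from the between-week
#' spread (`mean +/- 1.96 * sd(weekly) / sqrt(n_weeks)`).
#'
#' @param records a [vonfrey_records()] table; pre-op rows (week 0) are
#'   excluded from the overall statistic.
#' @return an object of class `allodynia_summary`: list with `per_animal_week`,
#'   `weekly` (cohort means/SE), and `overall` (mean, se, ci, weekly_sd).
#' @export
threshold_summary <- function(records) {
  records <- vonfrey_records(as.data.frame(records))
  key <- unique(records[, c("animal_id", "week")])
  paw <- lapply(seq_len(nrow(key)), function(i) {
    sub <- records[records$animal_id == key$animal_id[i] &
                     records$week == key$week[i], ]
    ml <- mean(sub$threshold_time_s[sub$side == "left"])
    mr <- mean(sub$threshold_time_s[sub$side == "right"])
    if (is.na(ml) || is.na(mr))
      rg_validation_error("animal %s week %d is missing a side",
                          key$animal_id[i], key$week[i])
    if (mr <= 0)
      rg_parameter_error("percent decrease undefined: right mean <= 0 for %s week %d",
                         key$animal_id[i], key$week[i])
    data.frame(animal_id = key$animal_id[i], week = key$week[i],
               mean_left = ml, mean_right = mr,
               pct_decrease = 100 * (mr - ml) / mr)
  })
  paw <- do.call(rbind, paw)
  post <- paw[paw$week >= 1L, ]
  weekly <- do.call(rbind, lapply(sort(unique(post$week)), function(w) {
    v <- post$pct_decrease[post$week == w]
    data.frame(week = w, n = length(v), mean = mean(v),
               se = sd(v) / sqrt(length(v)))
  }))
  wm <- weekly$mean
  overall <- list(mean = mean(wm),
                  weekly_sd = if (length(wm) > 1L) sd(wm) else NA_real_,
                  se = if (length(wm) > 1L) sd(wm) / sqrt(length(wm)) else NA_real_)
  overall$ci <- overall$mean + c(-1, 1) * 1.96 * overall$se
  structure(list(per_animal_week = paw, weekly = weekly, overall = overall),
            class = "allodynia_summary")
}

#' @export
print.allodynia_summary <- function(x, ...) {
  cat(sprintf(
    "<allodynia_summary> overall decrease %.1f%% (95%% CI %.1f-%.1f), %d weeks\n",
    x$overall$mean, x$overall$ci[1L], x$overall$ci[2L], nrow(x$weekly)))
  invisible(x)
}

#' Weekly paired t-test, left vs right paw
#'
#' Two-sided paired t-test of the per-animal side means at one time point.
#'
#' @param records a [vonfrey_records()] table.
#' @param week week to test.
#' @return list `(t, df, p)` as from [paired_t()].
#' @export
weekly_paired_test <- function(records, week) {
  records <- vonfrey_records(as.data.frame(records))
  sub <- records[records$week == week, ]
  if (!nrow(sub)) rg_insufficient_data("no records for week %d", week)
  ids <- unique(sub$animal_id)
  ml <- vapply(ids, function(id)
    mean(sub$threshold_time_s[sub$animal_id == id & sub$side == "left"]), 0)
  mr <- vapply(ids, function(id)
    mean(sub$threshold_time_s[sub$animal_id == id & sub$side == "right"]), 0)
  paired_t(ml, mr)
}

#' Convert a ramp threshold time to grams
#'
#' The probe force ramps linearly from 1 to 50 g over 20 s; this maps a
#' withdrawal time to its gram equivalent. Provided as a labeled
#' convenience — all statistics in this package operate on times.
#'
#' @param time_s threshold time(s) in seconds.
#' @param ramp_from,ramp_to,ramp_duration ramp parameters.
#' @return force in grams.
#' @export
vonfrey_grams <- function(time_s, ramp_from = 1, ramp_to = 50,
                          ramp_duration = 20) {
  ramp_from + (ramp_to - ramp_from) * time_s / ramp_duration
}
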