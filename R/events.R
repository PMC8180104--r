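#' Gait event table
#'
#' Ordered touchdown and lift-off times per hind-limb. Within a side the
#' events must strictly alternate touchdown -> lift-off -> touchdown, which
#' makes the stance intervals disjoint by construction. Events may come from
#' a manually entered table (the reference method for this assay), from the
#' automatic toe-height detector, or from the synthetic generator's ground
#' truth.
#'
#' @param left_touchdown,left_lift_off,right_touchdown,right_lift_off
#'   numeric vectors of event times in seconds.
#' @param provenance `"manual"`, `"detected"` or `"ground_truth"`.
#' @return An object of class `gait_events`.
#' @export
gait_events <- function(left_touchdown, left_lift_off,
                        right_touchdown, right_lift_off,
                        provenance = c("manual", "detected", "ground_truth")) {
  provenance <- match.arg(provenance)
  ev <- list(
    left  = list(touchdown = sort(as.numeric(left_touchdown)),
                 lift_off  = sort(as.numeric(left_lift_off))),
    right = list(touchdown = sort(as.numeric(right_touchdown)),
                 lift_off  = sort(as.numeric(right_lift_off))))
  for (side in SIDES) validate_side_events(ev[[side]], side)
  structure(c(ev, list(provenance = provenance)), class = "gait_events")
}

validate_side_events <- function(e, side) {
  t_all <- c(e$touchdown, e$lift_off)
  lab <- c(rep("touchdown", length(e$touchdown)),
           rep("lift_off", length(e$lift_off)))
  if (length(t_all) == 0L)
    rg_validation_error("no events on side '%s'", side)
  o <- order(t_all)
  t_all <- t_all[o]; lab <- lab[o]
  if (any(diff(t_all) <= 0))
    rg_validation_error("duplicated or non-increasing event time %g s on side '%s'",
                        t_all[which(diff(t_all) <= 0)[1L] + 1L], side)
  rep_idx <- which(lab[-1L] == lab[-length(lab)])
  if (length(rep_idx))
    rg_validation_error(
      "events on side '%s' do not alternate: consecutive %ss at t = %g s and %g s",
      side, lab[rep_idx[1L]], t_all[rep_idx[1L]], t_all[rep_idx[1L] + 1L])
  invisible(e)
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> [%s] left: %d touchdowns / %d lift-offs; right: %d / %d\n",
              x$provenance,
              length(x$left$touchdown), length(x$left$lift_off),
              length(x$right$touchdown), length(x$right$lift_off)))
  invisible(x)
}

#' @export
as.data.frame.gait_events <- function(x, ...) {
  rows <- do.call(rbind, lapply(SIDES, function(s) {
    rbind(data.frame(side = s, event = "touchdown", t = x[[s]]$touchdown),
          data.frame(side = s, event = "lift_off",  t = x[[s]]$lift_off))
  }))
  rows <- rows[order(rows$side, rows$t), ]
  rownames(rows) <- NULL
  rows
}

# Paired (touchdown, lift_off) stance intervals for one side, as an n x 2
# matrix. A trailing touchdown without a matching lift-off is dropped.
stance_intervals <- function(events, side) {
  td <- events[[side]]$touchdown
  lo <- events[[side]]$lift_off
  # A leading lift-off means the limb was already in stance when the record
  # starts; open the interval at -Inf and let the caller clip it.
  if (length(lo) && (!length(td) || lo[1L] < td[1L])) td <- c(-Inf, td)
  n <- min(length(td), length(lo))
  if (n == 0L) return(matrix(numeric(0), ncol = 2L))
  cbind(td[seq_len(n)], lo[seq_len(n)])
}

#' Read a manually entered gait event CSV
#'
#' Expects columns `side,event,t` with `event` in
#' `{touchdown, lift_off}`; an optional `#provenance=` metadata line
#' overrides the default `"manual"`. The table is validated (per-side
#' alternation) on load.
#'
#' @param path file path.
#' @return a [gait_events()] table.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) rg_config_error("file '%s' does not exist", path)
  meta <- read_meta_lines(path)
  df <- as.data.frame(data.table::fread(path, skip = meta$n, header = TRUE))
  if (!all(c("side", "event", "t") %in% names(df)))
    rg_format_error("malformed event header: expected columns side,event,t")
  bad <- setdiff(unique(df$event), c("touchdown", "lift_off"))
  if (length(bad))
    rg_validation_error("unknown event type(s): %s", paste(bad, collapse = ", "))
  prov <- meta$values$provenance %||% "manual"
  gait_events(
    left_touchdown  = df$t[df$side == "left"  & df$event == "touchdown"],
    left_lift_off   = df$t[df$side == "left"  & df$event == "lift_off"],
    right_touchdown = df$t[df$side == "right" & df$event == "touchdown"],
    right_lift_off  = df$t[df$side == "right" & df$event == "lift_off"],
    provenance = prov)
}

#' Write a gait event CSV
#'
#' @param events a [gait_events()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  writeLines(sprintf("#provenance=%s", events$provenance), path)
  data.table::fwrite(as.data.frame(events), path, append = TRUE,
                     col.names = TRUE)
  invisible(path)
}
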