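# Group-comparison statistics: paired t for left/right within animals,
# Mann-Whitney for SNL vs sham between groups, two-sided, alpha = 0.05,
# no multiplicity correction by default (matching the per-metric
# reporting convention of this assay).

#' Paired t-test (closed form)
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on the paired differences
#' `d = x - y`, with `df = n - 1` and a two-sided p-value from the t
#' distribution.
#'
#' @param x,y paired numeric vectors of equal length (n >= 3).
#' @return list with `t`, `df`, `p`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y))
    rg_parameter_error("paired samples must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) rg_insufficient_data("paired t-test needs at least 3 pairs")
  d <- x - y
  s <- sd(d)
  if (s == 0)
    rg_degenerate_test("paired differences have zero variance; t undefined")
  tstat <- mean(d) / (s / sqrt(n))
  list(t = tstat, df = n - 1L, p = 2 * pt(-abs(tstat), df = n - 1L))
}

#' Mann-Whitney U test
#'
#' U statistic with midranks for ties. Without ties and with
#' `n_a + n_b <= 20` the two-sided p-value is exact
#' (`2 * min(P(U <= u), P(U >= u))`, capped at 1, from the exact U
#' distribution); with ties and small samples the exact conditional
#' permutation distribution is enumerated; otherwise a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param a,b numeric samples.
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact path;
#'   `NULL` (default) decides by sample size.
#' @return list with `U` (for sample `a`), `p`, and `method`.
#' @export
mann_whitney <- function(a, b, exact = NULL) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (!length(a) || !length(b))
    rg_insufficient_data("Mann-Whitney needs non-empty samples")
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))                      # midranks
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0L
  small <- n1 + n2 <= 20L
  use_exact <- exact %||% small
  if (use_exact && !ties) {
    p <- 2 * min(pwilcox(u, n1, n2), 1 - pwilcox(u - 1, n1, n2))
    return(list(U = u, p = min(1, p), method = "exact"))
  }
  if (use_exact && ties && small) {
    dist <- enumerate_u(r, n1)
    p <- 2 * min(mean(dist <= u + 1e-9), mean(dist >= u - 1e-9))
    return(list(U = u, p = min(1, p), method = "exact_permutation"))
  }
  mu <- n1 * n2 / 2
  tie_tab <- table(c(a, b))
  n <- n1 + n2
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sig2 <= 0) return(list(U = u, p = 1, method = "normal"))
  z <- (abs(u - mu) - 0.5) / sqrt(sig2)
  list(U = u, p = 2 * pnorm(-max(0, z)), method = "normal")
}

# Exact conditional distribution of U under label exchange: rank sums of
# all size-n1 subsets of the pooled midranks.
enumerate_u <- function(r, n1) {
  idx <- utils::combn(length(r), n1)
  colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
}

#' Compare two cohorts metric by metric
#'
#' Runs a two-sided Mann-Whitney test per metric column between two
#' per-animal summary tables (as produced by [analyze_cohort()]) and flags
#' significance at `alpha`. An optional Holm adjustment is available but
#' off by default, matching the per-metric alpha convention.
#'
#' @param df_a,df_b per-animal metric data.frames (groups A and B).
#' @param metrics metric column names; defaults to the shared numeric
#'   columns.
#' @param alpha significance level.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return data.frame with group summaries (n, mean, se), `U`, `p` and
#'   `significant` per metric.
#' @export
compare_groups <- function(df_a, df_b, metrics = NULL, alpha = 0.05,
                           adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  if (is.null(metrics)) {
    num <- intersect(names(df_a)[vapply(df_a, is.numeric, TRUE)],
                     names(df_b)[vapply(df_b, is.numeric, TRUE)])
    metrics <- num
  }
  rows <- lapply(metrics, function(m) {
    xa <- df_a[[m]]; xb <- df_b[[m]]
    mw <- mann_whitney(xa, xb)
    data.frame(metric = m,
               n_a = sum(is.finite(xa)), mean_a = mean(xa, na.rm = TRUE),
               se_a = sd(xa, na.rm = TRUE) / sqrt(sum(is.finite(xa))),
               n_b = sum(is.finite(xb)), mean_b = mean(xb, na.rm = TRUE),
               se_b = sd(xb, na.rm = TRUE) / sqrt(sum(is.finite(xb))),
               U = mw$U, p = mw$p)
  })
  out <- do.call(rbind, rows)
  p_adj <- if (adjust == "holm") stats::p.adjust(out$p, "holm") else out$p
  out$significant <- p_adj < alpha
  out
}
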