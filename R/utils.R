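# Internal helpers: classed conditions, interval arithmetic, truncated
# normals and deterministic seed substreams.

`%||%` <- function(a, b) if (is.null(a)) b else a

rg_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "rg_error", "error")))
}

rg_format_error       <- function(msg, ...) rg_stop("rg_format_error", msg, ...)
rg_validation_error   <- function(msg, ...) rg_stop("rg_validation_error", msg, ...)
rg_config_error       <- function(msg, ...) rg_stop("rg_config_error", msg, ...)
rg_parameter_error    <- function(msg, ...) rg_stop("rg_parameter_error", msg, ...)
rg_insufficient_data  <- function(msg, ...) rg_stop("rg_insufficient_data", msg, ...)
rg_degenerate_test    <- function(msg, ...) rg_stop("rg_degenerate_test", msg, ...)

#' @keywords internal
assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    rg_parameter_error("`%s` must be a single finite number", name)
  if (x < lower || (strict_lower && x <= lower) || x > upper)
    rg_parameter_error("`%s` = %g is outside its allowed range", name, x)
  invisible(x)
}

# Total length of the intersection of two interval sets. Each argument is a
# two-column matrix (start, end); intervals within a set are assumed
# disjoint (stance intervals of one limb never overlap).
interval_intersection_length <- function(a, b) {
  if (is.null(a) || is.null(b) || nrow(a) == 0L || nrow(b) == 0L) return(0)
  total <- 0
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a[i, 1L], b[, 1L])
    hi <- pmin(a[i, 2L], b[, 2L])
    total <- total + sum(pmax(0, hi - lo))
  }
  total
}

# Clip an interval set to [lo, hi], dropping empties.
clip_intervals <- function(m, lo, hi) {
  if (is.null(m) || nrow(m) == 0L) return(m)
  s <- pmax(m[, 1L], lo)
  e <- pmin(m[, 2L], hi)
  keep <- e > s
  cbind(s[keep], e[keep])
}

# Normal draws truncated to a window that is *symmetric about the mean*
# (the wider of the stated bounds is pulled in), so that truncation does
# not bias the calibrated group mean. Plain rejection sampling; the window
# always has positive probability mass.
rnorm_trunc_sym <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  half <- min(mean - lower, upper - mean)
  if (!is.finite(half)) return(rnorm(n, mean, sd))
  if (half <= 0)
    rg_parameter_error("truncation window around mean %g is empty", mean)
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- rnorm(length(need), mean, sd)
    ok <- abs(draw - mean) < half
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

# Deterministic substream seed (kept below 2^31 - 1 so it is a valid
# R integer seed for any small master seed).
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1009 + 97 * as.double(k)) %% 2147483629) + 1L
}

# Centered moving average with edge shrinkage (used to denoise toe height
# before thresholding).
moving_average <- function(x, width) {
  if (width <= 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- width %/% 2L
  i <- seq_len(n)
  lo <- pmax(1L, i - half)
  hi <- pmin(n, i + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Shared frame-to-cycle assignment rule. Boundaries are touchdown times;
# returns the index of the cycle containing each time (0-based relative to
# `anchor`, clamped), using a 1 ns guard so generator and metrics agree on
# boundary frames.
.time_eps <- 1e-9
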