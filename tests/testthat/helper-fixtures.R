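# Shared fixtures. Expensive objects (simulated cohorts) are built once per
# test run and cached; everything is generated in code, nothing on disk.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

preset_trial <- function(name, noise_sd = 0, seed = NULL) {
  key <- sprintf("trial_%s_%g_%s", name, noise_sd, seed %||% "null")
  cached(key, {
    p <- gait_preset(name)
    simulate_trial(p$timing, p$shape, noise_sd = noise_sd, seed = seed,
                   session = p$session)
  })
}

preset_cohort <- function(name, seed) {
  cached(sprintf("cohort_%s_%d", name, seed),
         simulate_cohort(gait_preset(name, seed = seed)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A minimal valid series: all ten markers, constant positions except where
# overridden. `overrides` is a named list "marker.side" -> data.frame or
# list with any of x, y, z vectors of length(t).
toy_series <- function(t, overrides = list(), sample_rate = NULL,
                       belt_speed = 20, frame = "lab") {
  sample_rate <- sample_rate %||% (1 / diff(t[1:2]))
  rows <- list()
  for (side in c("left", "right")) for (m in c("iliac", "hip", "knee", "ankle", "mtp5")) {
    df <- data.frame(t = t, marker = m, side = side,
                     x = 0, y = ifelse(side == "left", 1, -1),
                     z = ifelse(m == "mtp5", 0, 5))
    ov <- overrides[[paste(m, side, sep = ".")]]
    if (!is.null(ov)) for (col in names(ov)) df[[col]] <- ov[[col]]
    rows[[length(rows) + 1L]] <- df
  }
  marker_series(do.call(rbind, rows), sample_rate = sample_rate,
                belt_speed = belt_speed, frame = frame)
}

# Strictly periodic event table for interval-arithmetic tests.
periodic_events <- function(T = 0.64, duty_left = 0.6, duty_right = 0.6,
                            phase_offset = 0.5, n = 12, t0 = T,
                            provenance = "ground_truth") {
  psi <- 1 - phase_offset
  ltd <- t0 + (0:n) * T
  rtd <- t0 + (psi + (-1:(n - 1))) * T
  gait_events(ltd, ltd + duty_left * T, rtd, rtd + duty_right * T,
              provenance = provenance)
}

# Dense-grid brute-force both-foot overlap counter: the independent oracle
# for the interval-arithmetic implementation.
brute_force_overlap <- function(events, span, dt = 1e-4) {
  grid <- seq(span[1L], span[2L] - dt / 2, by = dt)
  on_belt <- function(side) {
    st <- ratgait3d:::stance_intervals(events, side)
    res <- rep(FALSE, length(grid))
    for (i in seq_len(nrow(st)))
      res <- res | (grid >= st[i, 1L] & grid < st[i, 2L])
    res
  }
  sum(on_belt("left") & on_belt("right")) * dt
}

# Full-enumeration Mann-Whitney oracle (independent of the implementation
# path): two-sided p = 2 * min tail of the exact permutation distribution.
mw_enum_oracle <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n1 <- length(a)
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2L, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}
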