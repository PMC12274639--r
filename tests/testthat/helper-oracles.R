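# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# median by explicit sort, rectangle-sum integral
oracle_msi <- function(v) {
  s <- sort(v)
  n <- length(s)
  med <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  tot <- 0
  for (x in v) tot <- tot + (x - med) * 1
  tot
}

# all-pairs window labeler: evaluates every window against every event
# independently, then combines by the documented precedence
oracle_label <- function(ends, onsets, mode, rejected = numeric(0),
                         night_sweats = numeric(0)) {
  vapply(ends, function(e) {
    z1 <- z2 <- z0 <- zx <- FALSE
    for (o in onsets) {
      d <- e - o
      if (mode == "train") {
        if (d >= -30 && d < 120) z1 <- TRUE
        else if (d >= 120 && d < 240) z2 <- TRUE
        else if (d >= -240 && d < -30) z0 <- TRUE
      } else {
        if (d >= -60 && d < 0) z1 <- TRUE
        else if (d >= 0 && d < 30) z2 <- TRUE
        else if (d >= 30 && d < 1200) zx <- TRUE
      }
    }
    if (mode == "train") {
      for (r in rejected) if (e - r >= -240 && e - r < 240) z0 <- TRUE
    }
    for (s in night_sweats) {
      if (e - s >= -240 && e - s < 3600) zx <- TRUE
    }
    if (z1) "1"
    else if (z2) "2"
    else if (mode == "train") {
      if (zx) "excluded" else if (z0) "0" else "excluded"
    } else {
      if (zx) "excluded" else "0"
    }
  }, "")
}

# per-event outcome by exhaustive enumeration of (event, positive) pairs
oracle_outcomes <- function(pos_ends, onsets, pre = 60, post = 30) {
  out <- data.frame(onset_s = onsets, outcome = "missed",
                    latency_s = NA_real_)
  for (i in seq_along(onsets)) {
    cands <- c()
    for (p in pos_ends) {
      if (p < onsets[i] - pre || p > onsets[i] + post) next
      # among events whose candidate interval holds p, the nearer onset wins
      elig <- which(p >= onsets - pre & p <= onsets + post)
      if (elig[which.min(abs(onsets[elig] - p))] != i) next
      cands <- c(cands, p)
    }
    if (length(cands) == 0) next
    lat <- min(cands) - onsets[i]
    out$latency_s[i] <- lat
    out$outcome[i] <- if (lat < 0) "predicted" else "detected"
  }
  out
}

# finite-difference derivatives of the biexponential on the full dense grid:
# central differences inside, third-order one-sided stencils at the ends
# (the steepest admissible curves need better than O(h^2) at the boundary,
# where the extrema usually sit)
oracle_curvefit_fd <- function(A, B, C, n = 10001) {
  x <- seq(0, 1, length.out = n)
  y <- A * exp(B * x^2 + C * x)
  h <- x[2] - x[1]
  d1 <- c((-11 * y[1] + 18 * y[2] - 9 * y[3] + 2 * y[4]) / (6 * h),
          (y[3:n] - y[1:(n - 2)]) / (2 * h),
          (11 * y[n] - 18 * y[n - 1] + 9 * y[n - 2] - 2 * y[n - 3]) / (6 * h))
  d2 <- c((35 * y[1] - 104 * y[2] + 114 * y[3] - 56 * y[4] + 11 * y[5]) /
            (12 * h^2),
          (y[3:n] - 2 * y[2:(n - 1)] + y[1:(n - 2)]) / h^2,
          (35 * y[n] - 104 * y[n - 1] + 114 * y[n - 2] - 56 * y[n - 3] +
             11 * y[n - 4]) / (12 * h^2))
  # roundoff floors of the stencils themselves: dividing cancelling sums by
  # h (1e-4) and h^2 (1e-8) amplifies machine epsilon; coefficient = sum of
  # absolute stencil weights
  eps <- .Machine$double.eps * max(abs(y))
  floor_d1 <- 7 * eps / h
  floor_d2 <- 27 * eps / h^2
  floor_d12 <- max(abs(d1)) * floor_d2 + max(abs(d2)) * floor_d1
  list(d1 = d1, d2 = d2, d12 = d1 * d2,
       floors = c(floor_d1, floor_d1, floor_d2, floor_d2,
                  floor_d12, floor_d12))
}

# quick gapless 1 Hz trace from a numeric vector
mk_trace <- function(v, t0 = 0) {
  sc_trace(seq(t0, by = 1, length.out = length(v)), v, 1)
}

# noiseless, artifact-free generator settings for deterministic checks
clean_config <- function(...) {
  synth_config(noise_sd_uS = 0, drift_amplitude_uS = 0,
               artifact_rate_per_h = 0, scr_rate_per_h = 0,
               night_sweat_rate_per_h = 0, ...)
}
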