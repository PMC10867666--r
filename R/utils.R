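# Internal helpers shared across modules.

# Run body with a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Counter-based splitter: derive a per-recording seed from a master seed so
# cohorts are reproducible regardless of generation order. Stays below 2^31.
derive_seed <- function(master, counter) {
  as.integer((as.numeric(master) * 1009 + as.numeric(counter) * 9176) %%
               2147483647) + 1L
}

# Normal draw truncated to [lo, hi] by resampling (vectorised).
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  guard <- 0L
  while (length(bad) > 0L && guard < 100L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
    guard <- guard + 1L
  }
  pmin(pmax(x, lo), hi)
}

# Wrapped-normal approximation to a von Mises draw, in degrees.
rdirection <- function(n, bias_deg, concentration) {
  sd_deg <- (1 / sqrt(concentration)) * 180 / pi
  (bias_deg + stats::rnorm(n, 0, sd_deg)) %% 360
}

# Centred running mean with shrinking windows at the edges, so the output has
# no NA padding. `k` is the full window width in samples.
runmean <- function(x, k) {
  n <- length(x)
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  h <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Planar angular distance between two gaze points, in degrees.
gaze_distance <- function(az1, el1, az2, el2) {
  sqrt((az2 - az1)^2 + (el2 - el1)^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
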