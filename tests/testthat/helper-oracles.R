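# Independent reference implementations used as oracles. These are written
# as plain sample-by-sample loops and textbook formulas on purpose: they
# share no code with the package's vectorised implementations.

# Naive saccade detector: recompute velocities, dot products, the session
# median and candidate runs with explicit loops.
naive_detect_saccades <- function(gaze, cfg = detector_config()) {
  n <- nrow(gaze)
  vaz <- vel_ <- rep(NA_real_, max(n - 1L, 0L))
  ok <- rep(FALSE, max(n - 1L, 0L))
  for (i in seq_len(n - 1L)) {
    if (gaze$valid[i] && gaze$valid[i + 1L]) {
      dt <- gaze$t[i + 1L] - gaze$t[i]
      vaz[i] <- (gaze$az[i + 1L] - gaze$az[i]) / dt
      vel_[i] <- (gaze$el[i + 1L] - gaze$el[i]) / dt
      ok[i] <- TRUE
    }
  }
  dots <- rep(NA_real_, max(n - 2L, 0L))
  for (i in seq_len(n - 2L)) {
    if (ok[i] && ok[i + 1L]) {
      dots[i] <- vaz[i] * vaz[i + 1L] + vel_[i] * vel_[i + 1L]
    }
  }
  dd <- dots[!is.na(dots)]
  empty <- data.frame(onset_s = numeric(), offset_s = numeric(),
                      amplitude_deg = numeric(), direction_deg = numeric(),
                      peak_speed = numeric())
  if (length(dd) == 0L) return(empty)
  thr <- cfg$threshold_multiplier * stats::median(abs(dd))
  supra <- !is.na(dots) & dots > thr
  ev <- empty
  i <- 1L
  while (i <= length(supra)) {
    if (supra[i]) {
      j <- i
      while (j < length(supra) && supra[j + 1L]) j <- j + 1L
      if (j - i + 1L >= cfg$min_run) {
        a <- i
        b <- j + 2L
        d_az <- gaze$az[b] - gaze$az[a]
        d_el <- gaze$el[b] - gaze$el[a]
        amp <- sqrt(d_az^2 + d_el^2)
        peak <- 0
        for (k in i:(j + 1L)) {
          peak <- max(peak, sqrt(vaz[k]^2 + vel_[k]^2))
        }
        ev <- rbind(ev, data.frame(
          onset_s = gaze$t[a], offset_s = gaze$t[b], amplitude_deg = amp,
          direction_deg = if (amp > 0) (atan2(d_az, d_el) * 180 / pi) %% 360
                          else NA_real_,
          peak_speed = peak))
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  ev <- ev[ev$amplitude_deg >= cfg$min_amplitude_deg, , drop = FALSE]
  # refractory: scan pairs in time order, drop the slower, restart
  repeat {
    if (nrow(ev) < 2L) break
    ev <- ev[order(ev$onset_s), , drop = FALSE]
    removed <- FALSE
    for (i in seq_len(nrow(ev) - 1L)) {
      if (ev$onset_s[i + 1L] - ev$offset_s[i] < cfg$min_interval_s) {
        drop_i <- if (ev$peak_speed[i] < ev$peak_speed[i + 1L]) i else i + 1L
        ev <- ev[-drop_i, , drop = FALSE]
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }
  rownames(ev) <- NULL
  ev
}

# Textbook split-plot sums-of-squares decomposition for the 2 (between) x
# 2 (within) design, from cell, subject and marginal means.
oracle_mixed_anova <- function(d) {
  subj <- tapply(d$y, d$participant, mean)
  grand <- mean(d$y)
  N <- length(subj)
  grp_of <- tapply(as.character(d$group), d$participant, function(x) x[1L])
  ng <- table(grp_of)
  gmean <- tapply(d$y, d$group, mean)
  dmean <- tapply(d$y, d$direction, mean)
  ss_subj_tot <- 2 * sum((subj - grand)^2)
  ss_group <- 2 * sum(ng * (tapply(subj, grp_of, mean) - grand)^2)
  ss_subj_err <- ss_subj_tot - ss_group
  ss_total <- sum((d$y - grand)^2)
  ss_within <- ss_total - ss_subj_tot
  ss_dir <- N * sum((dmean - grand)^2)
  cmean <- tapply(d$y, list(d$group, d$direction), mean)
  ss_int <- 0
  for (g in rownames(cmean)) {
    for (dd in colnames(cmean)) {
      ss_int <- ss_int +
        ng[[g]] * (cmean[g, dd] - gmean[[g]] - dmean[[dd]] + grand)^2
    }
  }
  ss_werr <- ss_within - ss_dir - ss_int
  df_den <- N - 2L
  Fs <- c(group = ss_group / (ss_subj_err / df_den),
          direction = ss_dir / (ss_werr / df_den),
          `group:direction` = ss_int / (ss_werr / df_den))
  data.frame(effect = names(Fs), F = unname(Fs), df_den = df_den,
             p = stats::pf(unname(Fs), 1, df_den, lower.tail = FALSE))
}

# Random gaze trace with injected fast consistent-direction ramps and
# optional blink gaps, for detector oracle-equivalence checks.
random_trace <- function(n = 1000L, n_jumps = 3L, blink = TRUE) {
  t <- seq(0, by = 0.005, length.out = n)
  az <- cumsum(stats::rnorm(n, 0, 0.05))
  el <- cumsum(stats::rnorm(n, 0, 0.05))
  for (k in seq_len(n_jumps)) {
    at <- sample.int(n - 20L, 1L)
    len <- sample(4:12, 1L)
    amp <- stats::runif(1, 1, 8)
    th <- stats::runif(1, 0, 2 * pi)
    ramp <- seq(0, 1, length.out = len)
    az[at:n] <- az[at:n] + amp * sin(th) * c(ramp, rep(1, n - at - len + 1L))
    el[at:n] <- el[at:n] + amp * cos(th) * c(ramp, rep(1, n - at - len + 1L))
  }
  g <- data.frame(t = t, az = az, el = el, valid = TRUE)
  if (blink && stats::runif(1) < 0.7) {
    b0 <- stats::runif(1, 0.1, max(t) - 0.3)
    g$valid[g$t >= b0 & g$t <= b0 + 0.15] <- FALSE
  }
  g
}

# Frame-label stream at 30 Hz from a compact label vector.
frames_from_labels <- function(labels) {
  data.frame(t = (seq_along(labels) - 1L) / 30, label = labels)
}

# Bare fixation sequence (kind/step) for sequence-statistics tests;
# NA means an "elsewhere" fixation.
seq_of <- function(steps) {
  data.frame(kind = ifelse(is.na(steps), "elsewhere", "step"),
             step = steps)
}

# Noise-free generator parameters: no gaze jitter, no blinks, no imu noise.
noiseless_params <- function(seed, ...) {
  generator_params(seed = seed, gaze_noise_sd_deg = 0, blink_rate_hz = 0,
                   imu_noise_m = 0, ...)
}

# Fraction-of-fixated-steps for one recording via the event pipeline
# (gait -> coding -> sequence), without saccade detection.
pipeline_fraction <- function(rec, cfg = run_config()) {
  stride <- rec$meta$stride_period_s
  placements <- lapply(rec$meta$stair_spans, function(sp) {
    detect_foot_placements(rec$imu, stride, sp)
  })
  windows <- lapply(placements, function(p) {
    analysis_window(min(p$t), max(p$t), cfg$pre_window_s)
  })
  events <- label_fixations(rec$frames, cfg$min_frames)
  seqs <- lapply(1:2, function(i) {
    restrict_to_staircase(events, windows[[i]], i)
  })
  fraction_fixated(seqs, rec$meta$staircases)
}
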