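# Synthetic gaze + gait walk generator.
#
# A walk is laid out as an ordered list of fixation events (roaming before
# and between staircases, step fixations, "elsewhere" detours) joined by
# saccades with a minimum-jerk displacement profile. Foot placements are
# scheduled on a stride grid per staircase and drive both the analysis
# windows and the vertical head-displacement trace (one oscillation cycle,
# hence one lowest head position, per step). Everything the downstream
# pipeline is supposed to recover is recorded as ground truth.

MINJERK <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

saccade_duration_s <- function(amplitude_deg) 0.020 + 0.002 * amplitude_deg

# Visit plan for one staircase: which steps get fixated, in walking order,
# with optional backward re-fixations and "elsewhere" detours.
plan_stair_visits <- function(n_steps, p_fix, p_ind, offset_weights) {
  fixated <- which(stats::runif(n_steps) < p_fix)
  if (length(fixated) == 0L) {
    return(data.frame(kind = character(), step = integer()))
  }
  visits <- fixated
  offs <- as.integer(names(offset_weights))
  neg_mass <- sum(offset_weights[offs <= 0L])
  if (neg_mass > 0 && length(fixated) >= 2L) {
    out <- visits[1L]
    for (i in 2:length(visits)) {
      out <- c(out, visits[i])
      if (stats::runif(1) < neg_mass) {
        out <- c(out, visits[i - 1L], visits[i])
      }
    }
    visits <- out
  }
  kind <- rep("step", length(visits))
  step <- visits
  if (length(visits) >= 2L) {
    detour <- stats::runif(length(visits) - 1L) < p_ind
    kind <- c("step", as.vector(rbind(ifelse(detour, "elsewhere", NA),
                                      rep("step", length(visits) - 1L))))
    step <- c(visits[1L], as.vector(rbind(ifelse(detour, NA, NA),
                                          visits[-1L])))
    keep <- !is.na(kind)
    kind <- kind[keep]
    step <- step[keep]
  }
  data.frame(kind = kind, step = as.integer(step))
}

# Draw the landing point of one saccade from the current gaze position,
# steering back toward `anchor` when the walk would drift out of bounds.
draw_landing <- function(pos, amp, theta_deg, anchor, radius = 30) {
  th <- theta_deg * pi / 180
  cand <- pos + amp * c(sin(th), cos(th))
  if (sqrt(sum((cand - anchor)^2)) > radius) {
    th <- th + pi
    cand <- pos + amp * c(sin(th), cos(th))
  }
  if (sqrt(sum((cand - anchor)^2)) > radius) {
    u <- (anchor - pos) / max(sqrt(sum((anchor - pos)^2)), 1e-9)
    cand <- pos + amp * u
  }
  cand
}

#' Generate one synthetic walk over a pair of staircases
#'
#' Produces a complete recording (gaze trace at the nominal gaze rate, blink
#' intervals, per-frame area-of-interest labels at the nominal frame rate,
#' and a vertical head-displacement trace) together with the ground truth
#' (true saccades, the true fixation sequence, true foot placements) for one
#' participant walking one direction over two staircases.
#'
#' Step numbering is direction-relative: step 1 is always the first step the
#' walker meets, and staircase 1 is the first flight traversed, so for
#' ascending walks the staircase order is reversed internally.
#'
#' @param params A [generator_params()] object (its `seed` fixes the walk).
#' @param staircases List of two [make_staircase()] geometries in
#'   *descending* traversal order.
#' @param direction `"descending"` or `"ascending"`.
#' @param participant Participant identifier stored in the metadata.
#'
#' @return A list with elements `recording` (class `walk_recording`: `gaze`,
#'   `blinks`, `frames`, `imu`, `meta`) and `truth` (class `walk_truth`:
#'   `true_saccades`, `true_fixations`, `true_foot_placements`, `params`).
#' @examples
#' w <- generate_walk(generator_params(seed = 42))
#' nrow(w$truth$true_foot_placements) # 21 steps walked
#' @export
generate_walk <- function(params,
                          staircases = default_staircases(),
                          direction = c("descending", "ascending"),
                          participant = "P01") {
  stopifnot(inherits(params, "generator_params"))
  validate_generator_params(params)
  direction <- match.arg(direction)
  if (length(staircases) != 2L ||
      !all(vapply(staircases, inherits, logical(1), "staircase"))) {
    stop("`staircases` must be a list of two staircase geometries",
         call. = FALSE)
  }
  if (direction == "ascending") staircases <- rev(staircases)

  with_local_seed(params$seed, {
    T_stride <- params$stride_period_s *
      if (direction == "ascending") params$ascend_slowdown else 1
    lead_s <- 1.8    # sequence starts this long before the first placement
    pre_roam <- 3    # roaming before the first staircase
    gap_roam <- 4    # landing between the staircases
    post_roam <- 2

    anchor <- c(0, -15)
    pos <- c(0, 0)

    # event accumulators (parallel vectors; one data.frame built at the end)
    ev_kind <- character(0); ev_stair <- integer(0); ev_step <- integer(0)
    ev_b <- numeric(0); ev_e <- numeric(0)
    ev_az <- numeric(0); ev_el <- numeric(0)
    sc_on <- numeric(0); sc_off <- numeric(0)
    sc_amp <- numeric(0); sc_dir <- numeric(0)
    placements <- list()
    stair_spans <- list()
    add_event <- function(kind, staircase, step, b, e) {
      ev_kind[length(ev_kind) + 1L] <<- kind
      ev_stair[length(ev_stair) + 1L] <<- staircase
      ev_step[length(ev_step) + 1L] <<- step
      ev_b[length(ev_b) + 1L] <<- b
      ev_e[length(ev_e) + 1L] <<- e
      ev_az[length(ev_az) + 1L] <<- pos[1]
      ev_el[length(ev_el) + 1L] <<- pos[2]
    }
    # Move gaze to a new fixation target; returns the saccade duration.
    jump <- function(onset) {
      amp <- rnorm_trunc(1, params$saccade_amp_mean_deg,
                         params$saccade_amp_sd_deg, params$amp_floor_deg, 25)
      th <- rdirection(1, params$direction_bias_deg,
                       params$direction_concentration)
      new_pos <- draw_landing(pos, amp, th, anchor)
      d <- new_pos - pos
      dur <- saccade_duration_s(sqrt(sum(d^2)))
      i <- length(sc_on) + 1L
      sc_on[i] <<- onset
      sc_off[i] <<- onset + dur
      sc_amp[i] <<- sqrt(sum(d^2))
      sc_dir[i] <<- saccade_direction(d[1], d[2])
      pos <<- new_pos
      dur
    }

    cursor <- 0
    add_event("none", NA, NA, 0, pre_roam) # initial roaming; e fixed later
    cursor <- pre_roam

    for (i in 1:2) {
      geom <- staircases[[i]]
      n <- geom$n_steps
      plan <- plan_stair_visits(n, params$p_fixate_step, params$p_indirect,
                                params$step_offset_weights)
      m <- nrow(plan)
      seq_start <- cursor
      fp1 <- seq_start + lead_s
      T_i <- T_stride
      if (m > 0L) {
        # keep every fixation schedulable inside [seq_start, last placement]
        need <- m * params$fixation_min_s + m * 0.06
        if (n > 1L && need > lead_s + (n - 1L) * T_i) {
          T_i <- (need - lead_s + 0.2) / (n - 1L)
        }
      }
      fp_t <- fp1 + (seq_len(n) - 1L) * T_i
      placements[[i]] <- data.frame(staircase = i, step = seq_len(n),
                                    t = fp_t)
      # coarse staircase localization with a one-stride margin either side
      stair_spans[[i]] <- c(fp1 - T_i, fp_t[n] + T_i)

      if (m > 0L) {
        # entry saccade eats into the preceding roam
        d0 <- jump(seq_start - 0.05)
        ev_e[length(ev_e)] <- seq_start - 0.05
        b <- seq_start - 0.05 + d0
        span_end <- fp_t[n]
        # provisional saccade durations between stair events (re-measured
        # per jump, but a nominal value is enough to budget the span)
        nominal_d <- saccade_duration_s(params$saccade_amp_mean_deg)
        fix_dur <- (span_end - b - (m - 1L) * nominal_d) / m
        fix_dur <- min(max(fix_dur, params$fixation_min_s), 1.3)
        for (k in seq_len(m)) {
          add_event(plan$kind[k], if (plan$kind[k] == "step") i else NA,
                    plan$step[k], b, b + fix_dur)
          b <- b + fix_dur
          if (k < m) b <- b + jump(b)
        }
        cursor <- b
      } else {
        ev_e[length(ev_e)] <- fp_t[n]
        cursor <- fp_t[n]
      }
      # roam to the next segment (or out)
      tail_roam <- if (i == 1L) max(cursor, fp_t[n]) + gap_roam
                   else max(cursor, fp_t[n]) + post_roam
      d_exit <- jump(cursor)
      add_event("none", NA, NA, cursor + d_exit, tail_roam)
      cursor <- tail_roam
    }
    t_end <- cursor
    ev_e[length(ev_e)] <- t_end + 0.01

    ev <- data.frame(kind = ev_kind, staircase = ev_stair, step = ev_step,
                     onset = ev_b, offset = ev_e, az = ev_az, el = ev_el)
    sc <- data.frame(onset = sc_on, offset = sc_off,
                     amplitude_deg = sc_amp, direction_deg = sc_dir)

    # ---- gaze trace ------------------------------------------------------
    t <- seq(0, t_end, by = 1 / params$gaze_rate_hz)
    if (params$timing_jitter && length(t) > 2L) {
      t[-c(1L, length(t))] <- t[-c(1L, length(t))] +
        stats::runif(length(t) - 2L, -5e-4, 5e-4)
    }
    K <- nrow(ev)
    brk <- as.vector(rbind(ev$onset, ev$offset)) # b1 e1 b2 e2 ...
    idx <- findInterval(t, brk)
    idx[idx < 1L] <- 1L
    idx[idx > 2L * K - 1L] <- 2L * K - 1L
    evk <- (idx + 1L) %/% 2L       # owning/preceding event
    az <- ev$az[evk]
    el <- ev$el[evk]
    in_sacc <- idx %% 2L == 0L     # between offset of evk and onset of evk+1
    if (any(in_sacc)) {
      k <- evk[in_sacc]
      tau <- (t[in_sacc] - ev$offset[k]) / (ev$onset[k + 1L] - ev$offset[k])
      s <- MINJERK(pmin(pmax(tau, 0), 1))
      az[in_sacc] <- ev$az[k] + s * (ev$az[k + 1L] - ev$az[k])
      el[in_sacc] <- ev$el[k] + s * (ev$el[k + 1L] - ev$el[k])
    }
    if (params$gaze_noise_sd_deg > 0) {
      az <- az + stats::rnorm(length(t), 0, params$gaze_noise_sd_deg)
      el <- el + stats::rnorm(length(t), 0, params$gaze_noise_sd_deg)
    }
    gaze <- data.frame(t = t, az = az, el = el, valid = TRUE)

    # ---- blinks ----------------------------------------------------------
    n_blinks <- stats::rpois(1, params$blink_rate_hz * t_end)
    blinks <- data.frame(start = numeric(), end = numeric())
    if (n_blinks > 0L) {
      st <- sort(stats::runif(n_blinks, 0, max(t_end - params$blink_dur_s, 0)))
      en <- st + params$blink_dur_s
      keep_from <- c(TRUE, st[-1L] > en[-n_blinks])
      # merge overlapping blinks
      grp <- cumsum(keep_from)
      blinks <- data.frame(
        start = tapply(st, grp, min),
        end = tapply(en, grp, max),
        row.names = NULL
      )
    }

    # ---- frame labels ----------------------------------------------------
    tf <- seq(0, t_end, by = 1 / params$frame_rate_hz)
    fidx <- findInterval(tf, brk)
    fidx[fidx < 1L] <- 1L
    fidx[fidx > 2L * K - 1L] <- 2L * K - 1L
    fk <- (fidx + 1L) %/% 2L
    lab <- rep("none", length(tf))
    in_fix <- fidx %% 2L == 1L
    kk <- fk[in_fix]
    lab[in_fix] <- ifelse(
      ev$kind[kk] == "step",
      sprintf("s%d_step%02d", ev$staircase[kk], ev$step[kk]),
      ifelse(ev$kind[kk] == "elsewhere", "elsewhere", "none"))
    frames <- data.frame(t = tf, label = lab)

    # ---- vertical head displacement -------------------------------------
    ti <- seq(0, t_end, by = 1 / params$imu_rate_hz)
    rise_m <- vapply(staircases, function(g) g$rise_cm / 100, numeric(1))
    sgn <- if (direction == "descending") -1 else 1
    h1 <- sgn * staircases[[1]]$n_steps * rise_m[1]
    h2 <- h1 + sgn * staircases[[2]]$n_steps * rise_m[2]
    p1 <- placements[[1]]$t
    p2 <- placements[[2]]$t
    # the head keeps rising/sinking for about half a stride after the last
    # placement while the walker steps onto the landing
    knots_t <- c(0, p1[1] - T_stride, p1[length(p1)] + T_stride / 2,
                 p2[1] - T_stride, p2[length(p2)] + T_stride / 2, t_end)
    knots_z <- c(0, 0, h1, h1, h2, h2)
    z <- stats::approx(knots_t, knots_z, xout = ti, rule = 2)$y
    for (i in 1:2) {
      fp <- placements[[i]]$t
      Ti <- if (length(fp) > 1L) fp[2] - fp[1] else T_stride
      # start and end the oscillation at its ascending zero crossings so
      # the displacement trace is continuous at the staircase boundaries
      on_stair <- ti >= fp[1] - 3 * Ti / 4 & ti <= fp[length(fp)] + Ti / 4
      z[on_stair] <- z[on_stair] -
        params$head_osc_amp * cos(2 * pi * (ti[on_stair] - fp[1]) / Ti)
    }
    if (params$imu_noise_m > 0) {
      z <- z + stats::rnorm(length(ti), 0, params$imu_noise_m)
    }
    imu <- data.frame(t = ti, z = z)

    recording <- structure(list(
      gaze = gaze, blinks = blinks, frames = frames, imu = imu,
      meta = list(participant = participant, group = params$group_label,
                  direction = direction, staircases = staircases,
                  stair_spans = stair_spans,
                  stride_period_s = T_stride,
                  gaze_rate_hz = params$gaze_rate_hz,
                  frame_rate_hz = params$frame_rate_hz,
                  imu_rate_hz = params$imu_rate_hz)
    ), class = "walk_recording")

    truth <- structure(list(
      true_saccades = sc,
      true_fixations = ev[ev$kind != "none",
                          c("kind", "staircase", "step", "onset", "offset",
                            "az", "el")],
      true_foot_placements = do.call(rbind, placements),
      aoi_halfwidth_deg = 2.5,
      params = params
    ), class = "walk_truth")
    rownames(truth$true_fixations) <- NULL

    list(recording = recording, truth = truth)
  })
}

#' @export
print.walk_recording <- function(x, ...) {
  cat(sprintf(
    "<walk_recording: %s, %s, %s | %.1f s gaze @%g Hz, %d frames, %d blinks>\n",
    x$meta$participant, x$meta$group, x$meta$direction,
    max(x$gaze$t), x$meta$gaze_rate_hz, nrow(x$frames), nrow(x$blinks)))
  invisible(x)
}

#' True fixation sequence of a generated walk
#'
#' Returns the generator's ground-truth gaze sequence for one staircase:
#' the ordered step and "elsewhere" fixations the walk was built from.
#'
#' @param truth A `walk_truth` object from [generate_walk()].
#' @param staircase Staircase index (1 or 2, in traversal order).
#' @return Data frame with columns `kind`, `step`, `onset`, `offset`.
#' @export
true_sequence <- function(truth, staircase) {
  fx <- truth$true_fixations
  keep <- fx$kind == "elsewhere" | (fx$kind == "step" &
                                      !is.na(fx$staircase) &
                                      fx$staircase == staircase)
  fx <- fx[keep, c("kind", "step", "onset", "offset")]
  # elsewhere fixations belong to the staircase whose step fixations they
  # interleave; trim to the span of this staircase's step fixations
  st <- which(fx$kind == "step")
  if (length(st) == 0L) return(fx[0L, ])
  fx <- fx[min(st):max(st), ]
  rownames(fx) <- NULL
  fx
}

#' Generate a cohort of synthetic walks
#'
#' Generates `n_per_group` participants per group, each walking both
#' directions (descending and ascending), with per-recording seeds derived
#' from the master seed by a counter-based splitter so the cohort is
#' reproducible.
#'
#' @param group_params Named list mapping group label to a
#'   [generator_params()] object (defaults to the two built-in groups).
#' @param n_per_group Participants per group (a single count, or a vector
#'   with one count per group, e.g. `c(18, 16)`).
#' @param seed Master integer seed.
#' @param staircases Staircase pair passed to [generate_walk()].
#' @return A list of `list(recording, truth)` entries (one per walk), with a
#'   `roster` attribute: a data frame of participant, group.
#' @examples
#' ch <- generate_cohort(n_per_group = 2, seed = 7)
#' length(ch) # 2 groups x 2 participants x 2 directions
#' @export
generate_cohort <- function(group_params = list(
                              stairs_relevant = default_group_params("stairs_relevant"),
                              stairs_irrelevant = default_group_params("stairs_irrelevant")),
                            n_per_group = 2L, seed = 1L,
                            staircases = default_staircases()) {
  if (is.null(names(group_params)) ||
      !all(names(group_params) %in% c("stairs_relevant", "stairs_irrelevant"))) {
    stop("unknown group label in `group_params`", call. = FALSE)
  }
  n_per_group <- rep_len(as.integer(n_per_group), length(group_params))
  if (any(n_per_group < 1L)) stop("`n_per_group` must be >= 1", call. = FALSE)
  out <- list()
  roster <- list()
  counter <- 0L
  for (gi in seq_along(group_params)) {
    gp <- group_params[[gi]]
    for (j in seq_len(n_per_group[gi])) {
      pid <- sprintf("%s_%02d",
                     if (gp$group_label == "stairs_relevant") "rel" else "irr",
                     j)
      roster[[length(roster) + 1L]] <- data.frame(participant = pid,
                                                  group = gp$group_label)
      for (dir in c("descending", "ascending")) {
        counter <- counter + 1L
        gp_j <- gp
        gp_j$seed <- derive_seed(seed, counter)
        out[[length(out) + 1L]] <- generate_walk(gp_j, staircases, dir, pid)
      }
    }
  }
  attr(out, "roster") <- do.call(rbind, roster)
  out
}
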