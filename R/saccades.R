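# Velocity-based saccade detection with a session-adaptive threshold.
#
# Gaze samples inside blinks are invalidated first; velocities are two-point
# finite differences between consecutive valid samples; the detection
# statistic is the dot product of consecutive velocity vectors, which is
# large and positive only when gaze moves fast in a consistent direction.
# A section belongs to a saccade when that dot product exceeds ten times
# its median absolute value over the whole session (one walk).

#' Detector configuration
#'
#' Holds the detector's constants: the threshold multiplier applied to the
#' session median of the absolute velocity dot product (10), the minimum
#' saccade amplitude retained (3 degrees), the minimum interval between
#' saccades (100 ms; when two are closer, the slower is removed), and the
#' minimum number of consecutive supra-threshold dot products a candidate
#' needs (2, i.e. at least three samples of consistent fast motion).
#'
#' @param threshold_multiplier Multiplier on the session median.
#' @param min_amplitude_deg Amplitude floor in degrees.
#' @param min_interval_s Refractory interval in seconds.
#' @param min_run Minimum consecutive supra-threshold dot products.
#' @param slower_means `"peak_speed"` (default) or `"amplitude"`: which
#'   reading of "the slower of the two" the refractory rule uses.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(threshold_multiplier = 10,
                            min_amplitude_deg = 3,
                            min_interval_s = 0.100,
                            min_run = 2L,
                            slower_means = c("peak_speed", "amplitude")) {
  stopifnot(threshold_multiplier > 0, min_amplitude_deg > 0,
            min_interval_s > 0, min_run >= 1)
  structure(list(threshold_multiplier = threshold_multiplier,
                 min_amplitude_deg = min_amplitude_deg,
                 min_interval_s = min_interval_s,
                 min_run = as.integer(min_run),
                 slower_means = match.arg(slower_means)),
            class = "detector_config")
}

#' Invalidate gaze samples inside blink intervals
#'
#' Marks every gaze sample whose timestamp falls inside any blink interval
#' (closed bounds) as invalid. Velocities are never computed across the
#' resulting gaps.
#'
#' @param gaze Data frame with columns `t`, `az`, `el` and optionally
#'   `valid`.
#' @param blinks Data frame with columns `start`, `end` (seconds), or NULL.
#' @return The gaze data frame with its `valid` column updated.
#' @export
remove_blinks <- function(gaze, blinks = NULL) {
  if (is.null(gaze$valid)) gaze$valid <- TRUE
  if (is.null(blinks) || nrow(blinks) == 0L) return(gaze)
  if (any(blinks$end < blinks$start)) {
    stop("blink intervals must have end >= start", call. = FALSE)
  }
  o <- order(blinks$start)
  bs <- blinks$start[o]
  be <- blinks$end[o]
  if (any(bs[-1L] < be[-length(be)])) {
    stop("blink intervals must not overlap", call. = FALSE)
  }
  for (k in seq_along(bs)) {
    gaze$valid[gaze$t >= bs[k] & gaze$t <= be[k]] <- FALSE
  }
  gaze
}

#' Gaze velocity and consecutive-sample dot product
#'
#' Two-point finite-difference velocity between consecutive valid samples,
#' plus the dot product of consecutive velocity vectors (`dot_next`,
#' deg^2/s^2). Both are only defined within contiguous runs of valid
#' samples; `dot_next` is `NA` on the last velocity sample of each run.
#'
#' @param gaze Gaze data frame (`t`, `az`, `el`, `valid`).
#' @return Data frame with columns `i1` (index of the left gaze sample),
#'   `t_mid`, `v_az`, `v_el`, `speed`, `dot_next`. Empty when fewer than two
#'   consecutive valid samples exist.
#' @export
compute_velocity <- function(gaze) {
  n <- nrow(gaze)
  empty <- data.frame(i1 = integer(), t_mid = numeric(), v_az = numeric(),
                      v_el = numeric(), speed = numeric(),
                      dot_next = numeric())
  if (n < 2L) return(empty)
  ok <- gaze$valid & is.finite(gaze$az) & is.finite(gaze$el)
  pair_ok <- ok[-n] & ok[-1L]
  if (!any(pair_ok)) return(empty)
  i1 <- which(pair_ok)
  dt <- gaze$t[i1 + 1L] - gaze$t[i1]
  v_az <- (gaze$az[i1 + 1L] - gaze$az[i1]) / dt
  v_el <- (gaze$el[i1 + 1L] - gaze$el[i1]) / dt
  m <- length(i1)
  dot_next <- rep(NA_real_, m)
  if (m >= 2L) {
    consec <- i1[-1L] == i1[-m] + 1L
    j <- which(consec)
    dot_next[j] <- v_az[j] * v_az[j + 1L] + v_el[j] * v_el[j + 1L]
  }
  data.frame(i1 = i1, t_mid = gaze$t[i1] + dt / 2, v_az = v_az, v_el = v_el,
             speed = sqrt(v_az^2 + v_el^2), dot_next = dot_next)
}

#' Session median of the absolute velocity dot product
#'
#' The session statistic the detector threshold adapts to: the median of
#' `|dot_next|` over all defined consecutive-velocity dot products of one
#' walk (after blink removal).
#'
#' @param vel A velocity series from [compute_velocity()].
#' @return A single number (deg^2/s^2), `NA` when no dot product is defined.
#' @export
session_median_dot <- function(vel) {
  d <- vel$dot_next[is.finite(vel$dot_next)]
  if (length(d) == 0L) return(NA_real_)
  stats::median(abs(d))
}

#' Detect saccades in a gaze trace
#'
#' Candidate saccades are maximal runs of at least `min_run` consecutive
#' velocity dot products exceeding `threshold_multiplier` times the session
#' median of the absolute dot product. A candidate's amplitude is the
#' angular distance between gaze at the start and end of the run; candidates
#' below `min_amplitude_deg` are discarded. Finally, whenever two retained
#' saccades are separated by less than `min_interval_s`, the slower of the
#' two (lower peak speed by default) is removed, iterating from the earliest
#' offending pair until all gaps comply.
#'
#' @param gaze Gaze data frame (`t`, `az`, `el`, `valid`), blink-removed.
#' @param cfg A [detector_config()].
#' @param vel Optional precomputed [compute_velocity()] series.
#' @return Data frame of events: `onset_s`, `offset_s`, `amplitude_deg`,
#'   `direction_deg`, `peak_speed`, plus an `m_session` attribute holding
#'   the session median.
#' @export
detect_saccades <- function(gaze, cfg = detector_config(), vel = NULL) {
  if (is.null(vel)) vel <- compute_velocity(gaze)
  empty <- data.frame(onset_s = numeric(), offset_s = numeric(),
                      amplitude_deg = numeric(), direction_deg = numeric(),
                      peak_speed = numeric())
  if (nrow(vel) == 0L) {
    attr(empty, "m_session") <- NA_real_
    return(empty)
  }
  m_session <- session_median_dot(vel)
  if (is.na(m_session)) {
    attr(empty, "m_session") <- NA_real_
    return(empty)
  }
  if (m_session == 0) {
    warning("session median dot product is zero; threshold degenerates to 0",
            call. = FALSE)
  }
  thr <- cfg$threshold_multiplier * m_session
  supra <- !is.na(vel$dot_next) & vel$dot_next > thr
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= cfg$min_run
  if (!any(keep)) {
    attr(empty, "m_session") <- m_session
    return(empty)
  }
  ev <- do.call(rbind, lapply(which(keep), function(q) {
    r1 <- starts[q]
    r2 <- ends[q]
    a <- vel$i1[r1]
    b <- vel$i1[r2] + 2L
    d_az <- gaze$az[b] - gaze$az[a]
    d_el <- gaze$el[b] - gaze$el[a]
    amp <- sqrt(d_az^2 + d_el^2)
    data.frame(
      onset_s = gaze$t[a], offset_s = gaze$t[b],
      amplitude_deg = amp,
      direction_deg = if (amp > 0) saccade_direction(d_az, d_el) else NA_real_,
      peak_speed = max(vel$speed[r1:min(r2 + 1L, nrow(vel))]))
  }))
  ev <- ev[ev$amplitude_deg >= cfg$min_amplitude_deg, , drop = FALSE]
  ev <- prune_refractory(ev, cfg$min_interval_s, cfg$slower_means)
  rownames(ev) <- NULL
  attr(ev, "m_session") <- m_session
  ev
}

# Iteratively enforce the minimum inter-saccade interval: find the earliest
# pair closer than `min_interval_s` and drop its slower member (lower peak
# speed, or smaller amplitude under the alternative reading; ties drop the
# later event). Reaches a fixed point where all gaps comply.
prune_refractory <- function(ev, min_interval_s,
                             slower_means = "peak_speed") {
  if (nrow(ev) < 2L) return(ev)
  ev <- ev[order(ev$onset_s), , drop = FALSE]
  speed_of <- function(e) {
    if (slower_means == "amplitude") e$amplitude_deg else e$peak_speed
  }
  repeat {
    n <- nrow(ev)
    if (n < 2L) break
    gaps <- ev$onset_s[-1L] - ev$offset_s[-n]
    bad <- which(gaps < min_interval_s)
    if (length(bad) == 0L) break
    i <- bad[1L]
    s <- speed_of(ev)
    drop_idx <- if (s[i] < s[i + 1L]) i
                else if (s[i] > s[i + 1L]) i + 1L
                else i + 1L # tie: remove the later event
    ev <- ev[-drop_idx, , drop = FALSE]
  }
  ev
}

#' Saccade direction from a gaze displacement
#'
#' Direction of a displacement in head-fixed gaze coordinates, measured
#' from the upward direction and increasing clockwise toward rightward:
#' up = 0, right = 90, down = 180, left = 270 degrees.
#'
#' @param d_az,d_el Displacement components in degrees (+right, +up).
#' @return Angle(s) in `[0, 360)`.
#' @examples
#' saccade_direction(0, 2)   # 0
#' saccade_direction(2, 0)   # 90
#' saccade_direction(-1, -1) # 225
#' @export
saccade_direction <- function(d_az, d_el) {
  if (any(d_az == 0 & d_el == 0)) {
    stop("direction undefined for zero displacement", call. = FALSE)
  }
  (atan2(d_az, d_el) * 180 / pi) %% 360
}

#' Bin saccade directions into a fixed-width circular histogram
#'
#' Groups directions into `360 / bin_width_deg` half-open bins
#' `[k * w, (k + 1) * w)`. With the default 9-degree width this yields 40
#' bins. Optionally stratifies the counts by minimum amplitude classes
#' (counting, for each threshold, the saccades at least that large).
#'
#' @param directions_deg Vector of directions in degrees.
#' @param bin_width_deg Bin width; must divide 360.
#' @param amplitudes_deg Optional amplitudes matching `directions_deg`.
#' @param amp_min_deg Optional vector of minimum-amplitude thresholds for
#'   stratified counts (requires `amplitudes_deg`).
#' @return Data frame with `bin_start_deg`, `count`, and one
#'   `count_ge_<a>` column per stratification threshold.
#' @export
bin_directions <- function(directions_deg, bin_width_deg = 9,
                           amplitudes_deg = NULL, amp_min_deg = NULL) {
  if (bin_width_deg <= 0 || 360 %% bin_width_deg != 0) {
    stop("`bin_width_deg` must divide 360", call. = FALSE)
  }
  nb <- as.integer(360 / bin_width_deg)
  bin_of <- function(d) floor((d %% 360) / bin_width_deg) + 1L
  out <- data.frame(bin_start_deg = (seq_len(nb) - 1L) * bin_width_deg,
                    count = tabulate(bin_of(directions_deg), nbins = nb))
  if (!is.null(amp_min_deg)) {
    if (is.null(amplitudes_deg)) {
      stop("`amp_min_deg` requires `amplitudes_deg`", call. = FALSE)
    }
    for (a in amp_min_deg) {
      sel <- amplitudes_deg >= a
      out[[sprintf("count_ge_%g", a)]] <-
        tabulate(bin_of(directions_deg[sel]), nbins = nb)
    }
  }
  out
}

#' Per-participant mean saccade amplitude across the two staircases
#'
#' The per-participant, per-direction amplitude summary: the mean of the two
#' per-staircase mean amplitudes when both staircases contributed saccades,
#' otherwise the mean of the staircase that did. With no saccades on either
#' staircase the value is missing.
#'
#' @param amps_by_staircase List of two numeric vectors of amplitudes.
#' @return A single number (degrees) or `NA`.
#' @examples
#' mean_saccade_amplitude(list(4, 6))          # 5
#' mean_saccade_amplitude(list(numeric(), c(6, 8))) # 7
#' @export
mean_saccade_amplitude <- function(amps_by_staircase) {
  stopifnot(is.list(amps_by_staircase), length(amps_by_staircase) == 2L)
  m <- vapply(amps_by_staircase, function(a) {
    if (length(a) == 0L) NA_real_ else mean(a)
  }, numeric(1))
  if (all(is.na(m))) return(NA_real_)
  mean(m, na.rm = TRUE)
}
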