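# Gait events from the head's vertical displacement.
#
# While walking on stairs the head oscillates once per step; the lowest head
# position within each stride marks the moment the foot is placed stably.
# The trace is detrended with a one-stride running mean (stair walking
# superimposes the oscillation on a large monotonic height change), lightly
# smoothed, segmented into stride cycles at upward zero crossings, and the
# minimum of the detrended signal within each cycle is taken.

#' Detect foot placements from vertical head displacement
#'
#' @param imu Data frame with columns `t` (s, strictly increasing) and `z`
#'   (vertical head displacement, any consistent length unit).
#' @param expected_stride_period_s Approximate stride period (s); sets the
#'   detrending window (one stride) and the smoothing window (a quarter
#'   stride).
#' @param span Optional `c(start, end)` time window to restrict the search
#'   to: the coarse extent of one staircase, assumed to enclose every
#'   placement with at least one stride period to spare on each side.
#'   Minima closer than 0.7 stride periods to a span edge are treated as
#'   boundary artifacts and discarded.
#' @return Data frame with columns `t` (placement times, increasing) and
#'   `step_index`.
#' @export
detect_foot_placements <- function(imu, expected_stride_period_s,
                                   span = NULL) {
  stopifnot(expected_stride_period_s > 0)
  if (!is.null(span)) {
    imu <- imu[imu$t >= span[1] & imu$t <= span[2], , drop = FALSE]
  }
  n <- nrow(imu)
  if (n < 4L || diff(range(imu$t)) < 2 * expected_stride_period_s) {
    stop("trace too short: need at least two stride periods", call. = FALSE)
  }
  dt <- stats::median(diff(imu$t))
  w_trend <- max(3L, round(expected_stride_period_s / dt))
  w_smooth <- max(3L, round(expected_stride_period_s / 4 / dt))
  w_fine <- max(3L, round(expected_stride_period_s / 8 / dt))
  # coarse detrend + smooth, used only to delimit stride cycles
  resid <- imu$z - runmean(imu$z, w_trend)
  sm <- runmean(resid, w_smooth)
  if (all(abs(sm - sm[1L]) < 1e-12)) {
    stop("no strides found: flat or monotonic displacement trace",
         call. = FALSE)
  }
  up <- which(sm[-n] < 0 & sm[-1L] >= 0)
  bounds <- unique(c(1L, up, n))
  min_len <- round(expected_stride_period_s / 2 / dt)
  min_depth <- 0.2 * stats::sd(sm)
  q <- (w_smooth - 1L) %/% 2L
  # local mean of z centred on a sample (cycle-boundary height estimate)
  endpoint_z <- function(i) mean(imu$z[max(1L, i - q):min(n, i + q)])
  times <- numeric(0)
  edge <- max(2L, (w_fine - 1L) %/% 2L)
  for (k in seq_len(length(bounds) - 1L)) {
    a <- bounds[k]
    b <- bounds[k + 1L]
    if (b - a + 1L < min_len) next
    # chord detrend within the cycle: the two boundaries sit at the same
    # oscillation phase, so the chord slope is the local trend slope
    chord <- endpoint_z(a) +
      (endpoint_z(b) - endpoint_z(a)) * (imu$t[a:b] - imu$t[a]) /
        (imu$t[b] - imu$t[a])
    rc <- runmean(imu$z[a:b] - chord, w_fine)
    j <- which.min(rc)
    # a real trough is interior to its cycle and has some depth
    if (j <= edge || j >= (b - a + 1L) - edge) next
    if (rc[j] > -min_depth) next
    times <- c(times, imu$t[a - 1L + j])
  }
  if (!is.null(span)) {
    margin <- 0.7 * expected_stride_period_s
    times <- times[times >= span[1] + margin & times <= span[2] - margin]
  }
  if (length(times) == 0L) {
    stop("no strides found: flat or monotonic displacement trace",
         call. = FALSE)
  }
  data.frame(t = times, step_index = seq_along(times))
}

#' Total time spent on the staircases
#'
#' Per staircase, the time between stepping onto the first step and reaching
#' the last step; the per-participant, per-direction value is the sum over
#' the two staircases. A staircase with fewer than two placements yields a
#' missing value, which propagates to the sum.
#'
#' @param placements_by_staircase List of per-staircase foot-placement data
#'   frames (or numeric time vectors).
#' @return Total time in seconds, or `NA`.
#' @examples
#' time_on_staircase(list(c(10, 12, 16), c(20, 24.5))) # 6 + 4.5
#' @export
time_on_staircase <- function(placements_by_staircase) {
  per <- vapply(placements_by_staircase, function(p) {
    tt <- if (is.data.frame(p)) p$t else p
    if (length(tt) < 2L) return(NA_real_)
    max(tt) - min(tt)
  }, numeric(1))
  sum(per)
}

#' Analysis window for one staircase
#'
#' Gaze analyses for a staircase consider the closed interval from 2 seconds
#' before the first foot placement up to the last foot placement.
#'
#' @param first_step_t,last_step_t First and last placement times (s).
#' @param pre_s Pre-staircase margin, default 2 s.
#' @return Numeric `c(start, end)`.
#' @export
analysis_window <- function(first_step_t, last_step_t, pre_s = 2) {
  if (last_step_t <= first_step_t) {
    stop("`last_step_t` must exceed `first_step_t`", call. = FALSE)
  }
  c(first_step_t - pre_s, last_step_t)
}
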