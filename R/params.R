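#' Parameters of the synthetic walk generator
#'
#' Bundles every knob of the synthetic gaze-and-gait generator. The defaults
#' returned by [default_group_params()] define the two study conditions the
#' package emulates: a group for whom the staircase is the explicit task
#' ("stairs_relevant") and a group for whom it is incidental
#' ("stairs_irrelevant"). The groups differ in per-step fixation probability,
#' the rate of indirect gaze shifts (detours via "elsewhere"), the saccade
#' amplitude distribution, its directional bias, and how much they slow down
#' when ascending.
#'
#' @param group_label `"stairs_relevant"` or `"stairs_irrelevant"`.
#' @param p_fixate_step Probability that a given step receives at least one
#'   fixation during a traversal.
#' @param p_indirect Probability that the gaze shift between two successively
#'   fixated steps detours via an "elsewhere" fixation.
#' @param step_offset_weights Named numeric vector over signed step offsets
#'   for direct shifts; names are offsets (e.g. `"1"`), values sum to 1 and
#'   the `+1` offset must carry mass. Mass on offsets `<= 0` is realised as
#'   backward re-fixations injected into the forward visiting order.
#' @param saccade_amp_mean_deg,saccade_amp_sd_deg Mean and SD (degrees) of the
#'   normal distribution from which saccade amplitudes are drawn; draws are
#'   truncated to `[amp_floor_deg, 25]`.
#' @param amp_floor_deg Lower truncation of generated amplitudes. Kept above
#'   the detector's 3-degree floor so generated events are unambiguous.
#' @param direction_bias_deg,direction_concentration Circular bias of saccade
#'   directions (degrees clockwise from head-fixed "up") and a von
#'   Mises-style concentration; directions are drawn from a wrapped normal
#'   with SD `1/sqrt(concentration)` radians.
#' @param stride_period_s Stride period when descending, seconds per step.
#' @param ascend_slowdown Multiplier applied to the stride period when
#'   ascending (people climb more slowly than they descend).
#' @param head_osc_amp Amplitude (m) of the stride-locked vertical head
#'   oscillation; one oscillation cycle per step.
#' @param gaze_noise_sd_deg SD of white within-fixation gaze jitter, degrees.
#' @param imu_noise_m SD of white noise on the vertical displacement trace.
#' @param blink_rate_hz,blink_dur_s Blink rate (events/s) and duration.
#' @param gaze_rate_hz,frame_rate_hz,imu_rate_hz Nominal sampling rates of
#'   the gaze trace (200 Hz), the scene-frame label stream (30 Hz) and the
#'   vertical-displacement trace.
#' @param fixation_min_s Minimum fixation duration the scheduler will emit;
#'   must comfortably exceed two scene frames so every fixation is codable.
#' @param timing_jitter Logical; add uniform +/-0.5 ms jitter to gaze
#'   timestamps to exercise non-uniform sampling. Off by default.
#' @param seed Integer RNG seed for one generated walk.
#'
#' @return An object of class `generator_params` (a validated list).
#' @seealso [generate_walk()], [generate_cohort()]
#' @export
generator_params <- function(group_label = "stairs_relevant",
                             p_fixate_step = 0.8,
                             p_indirect = 0.09,
                             step_offset_weights = c("1" = 1),
                             saccade_amp_mean_deg = 5.5,
                             saccade_amp_sd_deg = 1.5,
                             amp_floor_deg = 3.5,
                             direction_bias_deg = 190,
                             direction_concentration = 1.5,
                             stride_period_s = 0.7,
                             ascend_slowdown = 1.15,
                             head_osc_amp = 0.04,
                             gaze_noise_sd_deg = 0.15,
                             imu_noise_m = 0.003,
                             blink_rate_hz = 0.1,
                             blink_dur_s = 0.15,
                             gaze_rate_hz = 200,
                             frame_rate_hz = 30,
                             imu_rate_hz = 100,
                             fixation_min_s = 0.2,
                             timing_jitter = FALSE,
                             seed = 1L) {
  p <- list(
    group_label = match.arg(group_label,
                            c("stairs_relevant", "stairs_irrelevant")),
    p_fixate_step = p_fixate_step,
    p_indirect = p_indirect,
    step_offset_weights = step_offset_weights,
    saccade_amp_mean_deg = saccade_amp_mean_deg,
    saccade_amp_sd_deg = saccade_amp_sd_deg,
    amp_floor_deg = amp_floor_deg,
    direction_bias_deg = direction_bias_deg %% 360,
    direction_concentration = direction_concentration,
    stride_period_s = stride_period_s,
    ascend_slowdown = ascend_slowdown,
    head_osc_amp = head_osc_amp,
    gaze_noise_sd_deg = gaze_noise_sd_deg,
    imu_noise_m = imu_noise_m,
    blink_rate_hz = blink_rate_hz,
    blink_dur_s = blink_dur_s,
    gaze_rate_hz = gaze_rate_hz,
    frame_rate_hz = frame_rate_hz,
    imu_rate_hz = imu_rate_hz,
    fixation_min_s = fixation_min_s,
    timing_jitter = isTRUE(timing_jitter),
    seed = as.integer(seed)
  )
  validate_generator_params(p)
  class(p) <- "generator_params"
  p
}

validate_generator_params <- function(p) {
  probs <- c(p_fixate_step = p$p_fixate_step, p_indirect = p$p_indirect)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("generator probabilities must lie in [0, 1]", call. = FALSE)
  }
  pos <- c(p$saccade_amp_mean_deg, p$saccade_amp_sd_deg, p$amp_floor_deg,
           p$direction_concentration, p$stride_period_s, p$ascend_slowdown,
           p$head_osc_amp, p$blink_dur_s, p$gaze_rate_hz, p$frame_rate_hz,
           p$imu_rate_hz, p$fixation_min_s)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    stop("generator rates, periods and spreads must be strictly positive",
         call. = FALSE)
  }
  nonneg <- c(p$gaze_noise_sd_deg, p$imu_noise_m, p$blink_rate_hz)
  if (any(!is.finite(nonneg)) || any(nonneg < 0)) {
    stop("noise levels and blink rate must be non-negative", call. = FALSE)
  }
  w <- p$step_offset_weights
  if (is.null(names(w)) || any(!is.finite(w)) || any(w < 0) ||
      abs(sum(w) - 1) > 1e-8) {
    stop("`step_offset_weights` must be a named non-negative vector summing to 1",
         call. = FALSE)
  }
  offs <- suppressWarnings(as.integer(names(w)))
  if (any(is.na(offs))) {
    stop("`step_offset_weights` names must be signed integer offsets",
         call. = FALSE)
  }
  if (!any(offs == 1L & w > 0)) {
    stop("`step_offset_weights` must assign nonzero mass to offset +1",
         call. = FALSE)
  }
  invisible(p)
}

#' @export
print.generator_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<generator_params: %s>\n",
    "  p_fixate_step = %.2f, p_indirect = %.2f\n",
    "  saccade amplitude ~ N(%.1f, %.1f) deg (floor %.1f)\n",
    "  stride %.2f s (x%.2f ascending), head oscillation %.3f m\n",
    "  gaze %g Hz, frames %g Hz, imu %g Hz, seed %d\n"),
    x$group_label, x$p_fixate_step, x$p_indirect,
    x$saccade_amp_mean_deg, x$saccade_amp_sd_deg, x$amp_floor_deg,
    x$stride_period_s, x$ascend_slowdown, x$head_osc_amp,
    x$gaze_rate_hz, x$frame_rate_hz, x$imu_rate_hz, x$seed))
  invisible(x)
}

#' Default generator parameters for the two instruction groups
#'
#' The built-in study conditions. The stairs-relevant group fixates more
#' steps (`p_fixate_step = 0.8` vs `0.6`), makes fewer indirect gaze shifts
#' (`p_indirect = 0.09` vs `0.21`), makes smaller saccades (mean 5.5 vs
#' 7.5 degrees) and slows down less when ascending (stride period multiplier
#' 1.15 vs 1.45).
#'
#' @param group `"stairs_relevant"` or `"stairs_irrelevant"`.
#' @param ... Overrides passed on to [generator_params()].
#' @return A `generator_params` object.
#' @export
default_group_params <- function(group = c("stairs_relevant",
                                           "stairs_irrelevant"), ...) {
  group <- match.arg(group)
  base <- switch(group,
    stairs_relevant = list(
      group_label = "stairs_relevant",
      p_fixate_step = 0.8,
      p_indirect = 0.09,
      saccade_amp_mean_deg = 5.5,
      direction_bias_deg = 190,
      direction_concentration = 1.5,
      ascend_slowdown = 1.15
    ),
    stairs_irrelevant = list(
      group_label = "stairs_irrelevant",
      p_fixate_step = 0.6,
      p_indirect = 0.21,
      saccade_amp_mean_deg = 7.5,
      direction_bias_deg = 225,
      direction_concentration = 1.0,
      ascend_slowdown = 1.45
    )
  )
  do.call(generator_params, utils::modifyList(base, list(...)))
}
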