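# The umbrella pipeline: one walk in, one summary row out; a cohort in,
# the full set of group statistics out.

#' Pipeline configuration
#'
#' Collects every analysis constant in one place. The defaults are the
#' canonical values used throughout: detector threshold multiplier 10,
#' 3-degree amplitude floor, 100 ms refractory interval, two-frame minimum
#' fixation, 2 s pre-staircase window, 9-degree direction bins, and a 0.05
#' significance level.
#'
#' @param detector A [detector_config()].
#' @param min_frames Minimum frames per fixation.
#' @param pre_window_s Pre-staircase analysis margin (s).
#' @param bin_width_deg Direction histogram bin width.
#' @param alpha Significance level for the ANOVA layer.
#' @param stride_period_s Expected stride period for foot-placement
#'   detection when the recording metadata does not provide one.
#' @return An object of class `run_config`.
#' @export
run_config <- function(detector = detector_config(),
                       min_frames = 2L,
                       pre_window_s = 2,
                       bin_width_deg = 9,
                       alpha = 0.05,
                       stride_period_s = 0.7) {
  structure(list(detector = detector, min_frames = as.integer(min_frames),
                 pre_window_s = pre_window_s, bin_width_deg = bin_width_deg,
                 alpha = alpha, stride_period_s = stride_period_s),
            class = "run_config")
}

#' Read a pipeline configuration from a JSON or YAML file
#'
#' Loads a flat key-value file overriding the [run_config()] and
#' [detector_config()] defaults. Recognised keys: `threshold_multiplier`,
#' `min_amplitude_deg`, `min_interval_s`, `min_run`, `slower_means`,
#' `min_frames`, `pre_window_s`, `bin_width_deg`, `alpha`,
#' `stride_period_s`. Unknown keys are an error, so typos cannot silently
#' fall back to defaults. YAML files need the `yaml` package.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  det_keys <- c("threshold_multiplier", "min_amplitude_deg",
                "min_interval_s", "min_run", "slower_means")
  run_keys <- c("min_frames", "pre_window_s", "bin_width_deg", "alpha",
                "stride_period_s")
  unknown <- setdiff(names(vals), c(det_keys, run_keys))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config key: %s", unknown[1L]), call. = FALSE)
  }
  det <- do.call(detector_config, vals[intersect(names(vals), det_keys)])
  do.call(run_config, c(list(detector = det),
                        vals[intersect(names(vals), run_keys)]))
}

#' Analyse one walk recording
#'
#' Runs the full event-level pipeline on one walk: blink removal, velocity
#' and saccade detection with the session-adaptive threshold, foot
#' placement detection per staircase, fixation coding from frame labels,
#' per-staircase gaze sequences, and the participant-level dependent
#' variables.
#'
#' @param rec A `walk_recording`.
#' @param cfg A [run_config()].
#' @param keep_events Also return the detected events and sequences.
#' @return A one-row data frame with `participant`, `group`, `direction`,
#'   `fraction_fixated`, `mean_amp_deg`, `time_on_stairs_s`,
#'   `indirect_share`, `m_session`, `n_saccades`. With
#'   `keep_events = TRUE`, a list with that row plus `saccades`,
#'   `placements`, `sequences`, `transitions`, `windows`.
#' @export
analyze_recording <- function(rec, cfg = run_config(), keep_events = FALSE) {
  meta <- rec$meta
  stride <- meta$stride_period_s %||% cfg$stride_period_s

  gaze <- remove_blinks(rec$gaze, rec$blinks)
  vel <- compute_velocity(gaze)
  sac <- detect_saccades(gaze, cfg$detector, vel)
  m_session <- attr(sac, "m_session")

  spans <- meta$stair_spans
  placements <- lapply(seq_along(spans), function(i) {
    tryCatch(detect_foot_placements(rec$imu, stride, spans[[i]]),
             error = function(e) data.frame(t = numeric(),
                                            step_index = integer()))
  })
  windows <- lapply(placements, function(p) {
    if (nrow(p) < 2L) return(NULL)
    analysis_window(min(p$t), max(p$t), cfg$pre_window_s)
  })
  time_on <- time_on_staircase(placements)

  events <- label_fixations(rec$frames, cfg$min_frames)
  seqs <- lapply(seq_along(windows), function(i) {
    if (is.null(windows[[i]])) {
      return(restrict_to_staircase(events[0L, , drop = FALSE], c(0, 1), i))
    }
    restrict_to_staircase(events, windows[[i]], i)
  })
  frac <- fraction_fixated(seqs, meta$staircases)
  trans <- combine_transitions(lapply(seqs, transition_distribution))
  ind <- indirect_share(trans)

  # saccade amplitudes per staircase, inside [first step fixation from 2 s
  # before the first placement, last placement]
  amps <- lapply(seq_along(windows), function(i) {
    w <- windows[[i]]
    s <- seqs[[i]]
    if (is.null(w) || nrow(s) == 0L) return(numeric(0))
    first_fix <- min(s$start_s[s$kind == "step"])
    lo <- max(w[1], first_fix)
    sac$amplitude_deg[sac$onset_s >= lo & sac$onset_s <= w[2]]
  })
  mean_amp <- mean_saccade_amplitude(amps)

  row <- data.frame(participant = meta$participant, group = meta$group,
                    direction = meta$direction,
                    fraction_fixated = frac, mean_amp_deg = mean_amp,
                    time_on_stairs_s = time_on, indirect_share = ind,
                    m_session = m_session, n_saccades = nrow(sac))
  if (!keep_events) return(row)
  list(summary = row, saccades = sac, placements = placements,
       sequences = seqs, transitions = trans, windows = windows)
}

#' Run the full pipeline on a cohort
#'
#' Analyses every walk, assembles the participant summary table, and runs
#' the inferential layer: a mixed ANOVA (Group between, Direction within)
#' on the fraction of fixated steps, the mean saccade amplitude and the
#' time on stairs; Pearson correlations between time on stairs and
#' fraction fixated (across both groups, separately per direction); and
#' the detector-threshold group diagnostic.
#'
#' @param cohort List of walks (from [generate_cohort()]) or of
#'   `walk_recording` objects (e.g. from [read_cohort()]).
#' @param cfg A [run_config()].
#' @param exclusions Optional exclusion-record data frame (see
#'   [apply_exclusions()]); the matching rows are removed from the summary
#'   table before the statistics.
#' @return A list with `summaries` (one row per walk), `anova` (named list
#'   of [mixed_anova()] results per dependent variable), `correlations`
#'   (per direction), `diagnostics` (threshold comparison), `counts`
#'   (included participants per group and direction) and `config`.
#' @export
run_pipeline <- function(cohort, cfg = run_config(), exclusions = NULL) {
  recs <- lapply(cohort, function(w) {
    if (inherits(w, "walk_recording")) w else w$recording
  })
  summaries <- do.call(rbind, lapply(recs, analyze_recording, cfg = cfg))
  if (!is.null(exclusions) && nrow(exclusions) > 0L) {
    drop <- rep(FALSE, nrow(summaries))
    for (i in seq_len(nrow(exclusions))) {
      hit <- summaries$participant == exclusions$participant[i]
      if (exclusions$scope[i] == "descending_only") {
        hit <- hit & summaries$direction == "descending"
      }
      drop <- drop | hit
    }
    summaries <- summaries[!drop, , drop = FALSE]
  }
  counts <- stats::aggregate(participant ~ group + direction,
                             data = summaries,
                             FUN = function(x) length(unique(x)))
  names(counts)[3L] <- "n"

  dvs <- c("fraction_fixated", "mean_amp_deg", "time_on_stairs_s")
  anovas <- lapply(dvs, function(dv) {
    tryCatch(suppressMessages(mixed_anova(summaries, dv)),
             error = function(e) NULL)
  })
  names(anovas) <- dvs

  correlations <- lapply(split(summaries, summaries$direction), function(d) {
    tryCatch(pearson_r(d$time_on_stairs_s, d$fraction_fixated),
             error = function(e) NULL)
  })

  diag <- tryCatch(threshold_diagnostics(summaries$m_session,
                                         summaries$group),
                   error = function(e) NULL)

  list(summaries = summaries, anova = anovas, correlations = correlations,
       diagnostics = diag, counts = counts, config = cfg)
}
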