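# Frame-level fixation coding.
#
# The per-frame area-of-interest label stream (one label per scene frame at
# a nominal 30 Hz: a specific step, "elsewhere", or "none" for uncoded
# spans) is turned into fixation events: a step counts as fixated when gaze
# stays on the same part of it for at least two frames; sequential
# fixations on the same step merge under one step number, and all non-step
# fixations pool under the single label "elsewhere".

parse_frame_label <- function(label) {
  m <- regmatches(label, regexec("^s([0-9]+)_step([0-9]+)$", label))
  kind <- ifelse(label == "elsewhere", "elsewhere",
                 ifelse(label == "none", "none", NA))
  staircase <- rep(NA_integer_, length(label))
  step <- rep(NA_integer_, length(label))
  for (i in seq_along(label)) {
    if (length(m[[i]]) == 3L) {
      kind[i] <- "step"
      staircase[i] <- as.integer(m[[i]][2L])
      step[i] <- as.integer(m[[i]][3L])
    }
  }
  if (any(is.na(kind))) {
    bad <- which(is.na(kind))[1L]
    stop(sprintf("unknown frame label '%s' (frame %d)", label[bad], bad),
         call. = FALSE)
  }
  data.frame(kind = kind, staircase = staircase, step = step)
}

#' Code fixation events from frame labels
#'
#' Maximal runs of identical labels lasting at least `min_frames` frames
#' become fixation events; shorter runs are discarded. After discarding,
#' adjacent events with the same label merge (so a one-frame intrusion does
#' not split a fixation), unless `strict_breaks = TRUE`, in which case any
#' discarded run breaks a fixation. Runs of `"none"` (uncoded frames) never
#' become events, and retained `"none"` runs always separate their
#' neighbours.
#'
#' @param frames Data frame with columns `t` (s) and `label` (`"s<i>_step<k>"`,
#'   `"elsewhere"` or `"none"`).
#' @param min_frames Minimum run length in frames (default 2).
#' @param strict_breaks Treat sub-threshold intrusions as fixation breaks.
#' @return Data frame of events: `label`, `kind`, `staircase`, `step`,
#'   `start_s`, `end_s`, `last_frame_s`, `n_frames`. `end_s` extends one
#'   nominal frame interval past the last frame.
#' @examples
#' f <- data.frame(t = (0:6) / 30,
#'                 label = c("s1_step04", "s1_step04", "s1_step04",
#'                           "elsewhere", "elsewhere",
#'                           "s1_step05", "s1_step05"))
#' label_fixations(f)$label
#' @export
label_fixations <- function(frames, min_frames = 2L, strict_breaks = FALSE) {
  stopifnot(nrow(frames) > 0L, min_frames >= 1L)
  dt_frame <- if (nrow(frames) > 1L) stats::median(diff(frames$t)) else 1 / 30
  r <- rle(frames$label)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  keep <- r$lengths >= min_frames
  lab <- r$values[keep]
  rs <- run_start[keep]
  re <- run_end[keep]
  rl <- r$lengths[keep]
  nk <- length(lab)
  empty <- data.frame(label = character(), kind = character(),
                      staircase = integer(), step = integer(),
                      start_s = numeric(), end_s = numeric(),
                      last_frame_s = numeric(), n_frames = integer())
  if (nk == 0L) return(empty)
  # merge adjacent kept runs with the same label (none never merges into an
  # event; a retained none run separates its neighbours by construction);
  # under strict_breaks a discarded run also separates its neighbours
  new_grp <- c(TRUE, lab[-1L] != lab[-nk])
  if (strict_breaks && nk > 1L) {
    new_grp[-1L] <- new_grp[-1L] | rs[-1L] != re[-nk] + 1L
  }
  grp <- cumsum(new_grp)
  first_i <- which(new_grp)
  last_i <- c(first_i[-1L] - 1L, nk)
  ev <- data.frame(label = lab[first_i], start = rs[first_i],
                   end = re[last_i],
                   n = as.integer(rowsum(rl, grp)[, 1L]))
  ev <- ev[ev$label != "none", , drop = FALSE]
  if (nrow(ev) == 0L) return(empty)
  parsed <- parse_frame_label(ev$label)
  res <- data.frame(label = ev$label, kind = parsed$kind,
                    staircase = parsed$staircase, step = parsed$step,
                    start_s = frames$t[ev$start],
                    end_s = frames$t[ev$end] + dt_frame,
                    last_frame_s = frames$t[ev$end],
                    n_frames = ev$n)
  rownames(res) <- NULL
  res
}

#' Restrict coded fixations to one staircase's analysis window
#'
#' Keeps the fixation events relevant to one staircase: step fixations on
#' that staircase and "elsewhere" fixations, restricted to the analysis
#' window (closed on both sides; an event straddling a boundary is kept
#' when at least two of its frames fall inside). The sequence is then
#' trimmed to start at the first step fixation and end at the last one, so
#' leading and trailing "elsewhere" periods drop out.
#'
#' @param events Coded events from [label_fixations()].
#' @param window `c(start, end)` from [analysis_window()].
#' @param staircase Staircase index the sequence is for.
#' @param min_frames_inside Frames an event must have inside the window.
#' @return A `gaze_sequence`: the filtered, trimmed event data frame.
#' @export
restrict_to_staircase <- function(events, window, staircase,
                                  min_frames_inside = 2L) {
  keep <- events$kind == "elsewhere" |
    (events$kind == "step" & !is.na(events$staircase) &
       events$staircase == staircase)
  ev <- events[keep, , drop = FALSE]
  if (nrow(ev) > 0L) {
    inside <- vapply(seq_len(nrow(ev)), function(i) {
      ft <- seq(ev$start_s[i], ev$last_frame_s[i],
                length.out = max(ev$n_frames[i], 1L))
      sum(ft >= window[1] & ft <= window[2])
    }, numeric(1))
    ev <- ev[inside >= min_frames_inside, , drop = FALSE]
  }
  st <- which(ev$kind == "step")
  if (length(st) == 0L) {
    ev <- ev[0L, , drop = FALSE]
  } else {
    ev <- ev[min(st):max(st), , drop = FALSE]
  }
  rownames(ev) <- NULL
  class(ev) <- c("gaze_sequence", class(ev))
  ev
}
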