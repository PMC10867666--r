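# Gaze-sequence statistics: step-offset transition distributions (direct vs
# indirect), the indirect share, and the fraction of fixated steps.

#' Step-offset transition distribution of a gaze sequence
#'
#' For each ordered pair of successively fixated steps, the offset is the
#' later step number minus the earlier one (step numbering is
#' direction-relative, so +1 always means the next step in the direction of
#' travel). A transition is *direct* when no "elsewhere" fixation
#' intervenes and *indirect* otherwise; only indirect transitions can have
#' offset 0 (gaze shifting away from a step and back to it).
#'
#' @param seq A `gaze_sequence` from [restrict_to_staircase()], or any data
#'   frame with columns `kind` and `step` in time order.
#' @return An object of class `transition_histogram`: a list with named
#'   count vectors `direct` and `indirect` (names are signed offsets).
#' @examples
#' s <- data.frame(kind = c("step", "step", "step", "elsewhere", "step",
#'                          "step"),
#'                 step = c(1, 2, 3, NA, 3, 5))
#' transition_distribution(s)
#' @export
transition_distribution <- function(seq) {
  direct <- integer(0)
  indirect <- integer(0)
  add <- function(tab, off) {
    key <- as.character(off)
    tab[key] <- (if (key %in% names(tab)) tab[[key]] else 0L) + 1L
    tab
  }
  prev_step <- NA_integer_
  pending_elsewhere <- FALSE
  for (i in seq_len(nrow(seq))) {
    if (seq$kind[i] == "elsewhere") {
      pending_elsewhere <- TRUE
    } else if (seq$kind[i] == "step") {
      if (!is.na(prev_step)) {
        off <- seq$step[i] - prev_step
        if (pending_elsewhere) indirect <- add(indirect, off)
        else direct <- add(direct, off)
      }
      prev_step <- seq$step[i]
      pending_elsewhere <- FALSE
    }
  }
  structure(list(direct = direct, indirect = indirect),
            class = "transition_histogram")
}

#' Combine transition histograms
#'
#' Sums the direct and indirect counts of several histograms (e.g. the two
#' staircases of one walk, or a whole group).
#'
#' @param ... `transition_histogram` objects (or one list of them).
#' @return A `transition_histogram`.
#' @export
combine_transitions <- function(...) {
  hs <- list(...)
  if (length(hs) == 1L && !inherits(hs[[1L]], "transition_histogram")) {
    hs <- hs[[1L]]
  }
  merge_tab <- function(a, b) {
    keys <- union(names(a), names(b))
    out <- vapply(keys, function(k) {
      (if (k %in% names(a)) a[[k]] else 0L) +
        (if (k %in% names(b)) b[[k]] else 0L)
    }, integer(1))
    out
  }
  res <- list(direct = integer(0), indirect = integer(0))
  for (h in hs) {
    res$direct <- merge_tab(res$direct, h$direct)
    res$indirect <- merge_tab(res$indirect, h$indirect)
  }
  structure(res, class = "transition_histogram")
}

#' @export
print.transition_histogram <- function(x, ...) {
  cat("<transition_histogram>\n  direct:  ",
      if (length(x$direct)) paste(names(x$direct), x$direct, sep = ":",
                                  collapse = " ") else "(none)",
      "\n  indirect:",
      if (length(x$indirect)) paste(names(x$indirect), x$indirect, sep = ":",
                                    collapse = " ") else "(none)", "\n")
  invisible(x)
}

#' Share of indirect transitions
#'
#' The fraction of all step-to-step transitions that detoured via an
#' "elsewhere" fixation. Missing when the sequence has no transitions.
#'
#' @param h A `transition_histogram`.
#' @return A fraction in `[0, 1]`, or `NA`.
#' @export
indirect_share <- function(h) {
  tot <- sum(h$direct) + sum(h$indirect)
  if (tot == 0L) return(NA_real_)
  sum(h$indirect) / tot
}

#' Fraction of fixated steps
#'
#' Per staircase, the number of distinct steps that received at least one
#' fixation divided by the staircase's step count; the per-participant,
#' per-direction value is the mean of the two staircase fractions. Steps
#' fixated within the 2-second pre-staircase window count, because the
#' sequences passed in already include them.
#'
#' @param seqs List of two `gaze_sequence` objects (one per staircase).
#' @param staircases List of two [make_staircase()] geometries, in the same
#'   order.
#' @return A fraction in `[0, 1]` (0 when no steps were fixated).
#' @export
fraction_fixated <- function(seqs, staircases) {
  stopifnot(length(seqs) == length(staircases))
  per <- vapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    steps <- unique(s$step[s$kind == "step"])
    length(steps[!is.na(steps)]) / staircases[[i]]$n_steps
  }, numeric(1))
  mean(per)
}
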