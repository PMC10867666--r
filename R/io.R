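# Readers and writers for the on-disk recording layout.
#
# One directory per walk: gaze.csv (t_s, az_deg, el_deg), imu.csv (t_s,
# z_disp), frames.csv (t_s, label), blinks.csv (start_s, end_s), meta.json,
# and optionally ground_truth.json. A cohort directory holds one such
# directory per walk plus manifest.json. All CSVs are comma-delimited UTF-8
# with a header row; timestamps are seconds as floating point, written at
# full precision.

write_num_csv <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) {
    if (is.numeric(df2[[j]])) df2[[j]] <- sprintf("%.15g", df2[[j]])
  }
  utils::write.csv(df2, path, row.names = FALSE, quote = FALSE)
}

#' Write one recording (and optionally its ground truth) to a directory
#'
#' @param walk A `list(recording, truth)` pair from [generate_walk()], or a
#'   bare `walk_recording`.
#' @param dir Output directory (created if needed).
#' @param with_truth Also write `ground_truth.json`.
#' @return `dir`, invisibly.
#' @export
write_recording <- function(walk, dir, with_truth = TRUE) {
  rec <- if (inherits(walk, "walk_recording")) walk else walk$recording
  truth <- if (inherits(walk, "walk_recording")) NULL else walk$truth
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_num_csv(data.frame(t_s = rec$gaze$t, az_deg = rec$gaze$az,
                           el_deg = rec$gaze$el),
                file.path(dir, "gaze.csv"))
  write_num_csv(data.frame(t_s = rec$imu$t, z_disp = rec$imu$z),
                file.path(dir, "imu.csv"))
  write_num_csv(data.frame(t_s = rec$frames$t, label = rec$frames$label),
                file.path(dir, "frames.csv"))
  write_num_csv(data.frame(start_s = rec$blinks$start,
                           end_s = rec$blinks$end),
                file.path(dir, "blinks.csv"))
  meta <- rec$meta
  meta$staircases <- lapply(meta$staircases, unclass)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (with_truth && !is.null(truth)) {
    tr <- truth
    tr$params <- unclass(tr$params)
    jsonlite::write_json(unclass(tr), file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

read_csv_checked <- function(path, cols) {
  if (!file.exists(path)) {
    stop(sprintf("missing file: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(cols %in% names(df))) {
    stop(sprintf("%s: expected columns %s", basename(path),
                 paste(cols, collapse = ", ")), call. = FALSE)
  }
  df
}

check_increasing <- function(t, file) {
  bad <- which(diff(t) <= 0)
  if (length(bad) > 0L) {
    stop(sprintf("%s: timestamps not strictly increasing at row %d",
                 file, bad[1L] + 1L), call. = FALSE)
  }
}

#' Read one recording from a directory
#'
#' Reads and validates the CSV/JSON layout written by [write_recording()]:
#' strictly increasing timestamps (violations are reported with the file
#' and row), known frame labels, step numbers within each staircase's step
#' count, and non-overlapping blink intervals.
#'
#' @param dir Directory containing `gaze.csv`, `imu.csv`, `frames.csv`,
#'   `blinks.csv` and `meta.json`.
#' @return A `walk_recording`.
#' @export
read_recording <- function(dir) {
  gz <- read_csv_checked(file.path(dir, "gaze.csv"),
                         c("t_s", "az_deg", "el_deg"))
  check_increasing(gz$t_s, "gaze.csv")
  im <- read_csv_checked(file.path(dir, "imu.csv"), c("t_s", "z_disp"))
  check_increasing(im$t_s, "imu.csv")
  fr <- read_csv_checked(file.path(dir, "frames.csv"), c("t_s", "label"))
  check_increasing(fr$t_s, "frames.csv")
  bl <- read_csv_checked(file.path(dir, "blinks.csv"),
                         c("start_s", "end_s"))
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) {
    stop(sprintf("missing file: %s", meta_path), call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  meta$staircases <- lapply(seq_len(nrow(meta$staircases)), function(i) {
    g <- meta$staircases[i, ]
    make_staircase(g$n_steps, g$run_cm, g$rise_cm)
  })
  if (is.matrix(meta$stair_spans) || is.data.frame(meta$stair_spans)) {
    meta$stair_spans <- lapply(seq_len(nrow(meta$stair_spans)),
                               function(i) as.numeric(meta$stair_spans[i, ]))
  }
  parsed <- parse_frame_label(fr$label) # errors on unknown labels
  n_steps <- vapply(meta$staircases, `[[`, numeric(1), "n_steps")
  bad <- which(parsed$kind == "step" &
                 (parsed$staircase > length(n_steps) |
                    parsed$step > n_steps[pmin(parsed$staircase,
                                               length(n_steps))]))
  if (length(bad) > 0L) {
    stop(sprintf("frames.csv: label '%s' (row %d) exceeds staircase layout",
                 fr$label[bad[1L]], bad[1L] + 1L), call. = FALSE)
  }
  blinks <- data.frame(start = bl$start_s, end = bl$end_s)
  if (nrow(blinks) > 1L) {
    o <- order(blinks$start)
    if (any(blinks$start[o][-1L] < blinks$end[o][-nrow(blinks)])) {
      stop("blinks.csv: overlapping blink intervals", call. = FALSE)
    }
  }
  structure(list(
    gaze = data.frame(t = gz$t_s, az = gz$az_deg, el = gz$el_deg,
                      valid = TRUE),
    blinks = blinks,
    frames = data.frame(t = fr$t_s, label = fr$label),
    imu = data.frame(t = im$t_s, z = im$z_disp),
    meta = meta
  ), class = "walk_recording")
}

#' Write a cohort of walks with a manifest
#'
#' @param cohort List of walks from [generate_cohort()].
#' @param dir Output directory; each walk goes in
#'   `<participant>_<direction>/`.
#' @param with_truth Include per-walk ground truth.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, with_truth = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(cohort, function(w) {
    m <- w$recording$meta
    sub <- sprintf("%s_%s", m$participant, m$direction)
    write_recording(w, file.path(dir, sub), with_truth = with_truth)
    list(participant = m$participant, group = m$group,
         direction = m$direction, path = sub)
  })
  jsonlite::write_json(list(walks = entries),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory containing `manifest.json`.
#' @return List of `walk_recording` objects.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  lapply(manifest$walks$path, function(p) read_recording(file.path(dir, p)))
}
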