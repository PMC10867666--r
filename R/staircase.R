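#' Staircase geometry
#'
#' Describes one flight of stairs by its step count and the tread/riser
#' dimensions. The steepness follows from the rise-to-run ratio,
#' `atan(rise / run)` in degrees. The staircases studied by the package's
#' default cohort have a run of 30 cm and a rise of 16 cm, i.e. a steepness
#' of about 28 degrees.
#'
#' @param n_steps Number of steps (positive integer).
#' @param run_cm Tread depth per step, in centimetres.
#' @param rise_cm Riser height per step, in centimetres.
#'
#' @return An object of class `staircase`: a list with elements `n_steps`,
#'   `run_cm`, `rise_cm` and `steepness_deg`.
#' @examples
#' make_staircase(12, 30, 16)$steepness_deg # about 28
#' @export
make_staircase <- function(n_steps, run_cm, rise_cm) {
  if (length(n_steps) != 1L || !is.finite(n_steps) || n_steps < 1 ||
      n_steps != round(n_steps)) {
    stop("invalid staircase geometry: `n_steps` must be a positive integer",
         call. = FALSE)
  }
  if (length(run_cm) != 1L || !is.finite(run_cm) || run_cm <= 0 ||
      length(rise_cm) != 1L || !is.finite(rise_cm) || rise_cm <= 0) {
    stop("invalid staircase geometry: `run_cm` and `rise_cm` must be positive",
         call. = FALSE)
  }
  structure(
    list(
      n_steps = as.integer(n_steps),
      run_cm = as.numeric(run_cm),
      rise_cm = as.numeric(rise_cm),
      steepness_deg = atan2(rise_cm, run_cm) * 180 / pi
    ),
    class = "staircase"
  )
}

#' @export
print.staircase <- function(x, ...) {
  cat(sprintf("<staircase: %d steps, run %.1f cm, rise %.1f cm, steepness %.1f deg>\n",
              x$n_steps, x$run_cm, x$rise_cm, x$steepness_deg))
  invisible(x)
}

#' Default pair of long staircases
#'
#' The two long flights used throughout the package: a 12-step and a 9-step
#' staircase, both with a 30 cm run and a 16 cm rise. They are returned in
#' descending traversal order (the 12-step flight is met first when walking
#' down); [generate_walk()] reverses the order for ascending walks.
#'
#' @return A list of two `staircase` objects.
#' @export
default_staircases <- function() {
  list(make_staircase(12, 30, 16), make_staircase(9, 30, 16))
}
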