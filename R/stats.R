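# Inferential layer: exclusion bookkeeping, 2x2 mixed-design ANOVA with
# partial eta squared, Pearson correlation, and the detector-threshold
# group diagnostic.

#' Apply exclusion records to a cohort roster
#'
#' Removes excluded participants from the per-group, per-direction counts.
#' A record with scope `"both_directions"` removes the participant from
#' both directions; `"descending_only"` removes only their descending data.
#'
#' @param roster Data frame with columns `participant` and `group`.
#' @param records Data frame with columns `participant`, `reason`, `scope`
#'   (scope in `"both_directions"`, `"descending_only"`); may have 0 rows.
#' @return Data frame with columns `group`, `direction`, `n`.
#' @examples
#' roster <- data.frame(
#'   participant = c(sprintf("rel_%02d", 1:18), sprintf("irr_%02d", 1:16)),
#'   group = rep(c("stairs_relevant", "stairs_irrelevant"), c(18, 16)))
#' recs <- data.frame(
#'   participant = c("rel_01", "irr_01", "irr_02"),
#'   reason = c("ran", "phone_use", "others_present_descending"),
#'   scope = c("both_directions", "both_directions", "descending_only"))
#' apply_exclusions(roster, recs) # 17/14 descending, 17/15 ascending
#' @export
apply_exclusions <- function(roster, records) {
  stopifnot(all(c("participant", "group") %in% names(roster)))
  if (nrow(records) > 0L) {
    if (anyDuplicated(records$participant)) {
      stop("each participant may have at most one exclusion record",
           call. = FALSE)
    }
    unknown <- setdiff(records$participant, roster$participant)
    if (length(unknown) > 0L) {
      stop(sprintf("exclusion record for unknown participant '%s'",
                   unknown[1L]), call. = FALSE)
    }
    if (!all(records$scope %in% c("both_directions", "descending_only"))) {
      stop("exclusion scope must be 'both_directions' or 'descending_only'",
           call. = FALSE)
    }
  }
  out <- list()
  for (dir in c("descending", "ascending")) {
    excl <- records$participant[
      records$scope == "both_directions" |
        (records$scope == "descending_only" & dir == "descending")]
    kept <- roster[!(roster$participant %in% excl), , drop = FALSE]
    tab <- table(kept$group)
    out[[dir]] <- data.frame(group = names(tab), direction = dir,
                             n = as.integer(tab))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mixed-design ANOVA (Group between, Direction within)
#'
#' Classical split-plot analysis of variance for a design with one
#' two-level between-subjects factor and one two-level within-subjects
#' factor, fitted with [stats::aov()] using an `Error(participant)`
#' stratum. Only complete cases enter (participants contributing both
#' directions); incomplete participants are dropped with a message, which
#' makes the between-effect denominator degrees of freedom equal the number
#' of complete participants minus two. Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)` with the error term of the
#' effect's own stratum. No sphericity correction is needed with only two
#' within-subject levels.
#'
#' @param data Long-format data frame.
#' @param dv Name of the dependent-variable column.
#' @param participant,group,direction Column names of the design factors.
#' @return An object of class `mixed_anova_result`: a data frame with one
#'   row per effect (`group`, `direction`, `group:direction`) and columns
#'   `effect`, `df_num`, `df_den`, `F`, `p`, `eta_p2`, plus an
#'   `n_complete` attribute.
#' @export
mixed_anova <- function(data, dv, participant = "participant",
                        group = "group", direction = "direction") {
  d <- data.frame(participant = factor(data[[participant]]),
                  group = factor(data[[group]]),
                  direction = factor(data[[direction]]),
                  y = as.numeric(data[[dv]]))
  d <- d[is.finite(d$y), , drop = FALSE]
  if (anyDuplicated(d[, c("participant", "direction")])) {
    stop("at most one value per participant x direction", call. = FALSE)
  }
  n_dir <- table(d$participant)
  complete <- names(n_dir)[n_dir == nlevels(d$direction)]
  dropped <- length(n_dir) - length(complete)
  if (dropped > 0L) {
    message(sprintf("mixed_anova: dropped %d incomplete participant(s)",
                    dropped))
  }
  d <- d[d$participant %in% complete, , drop = FALSE]
  d$participant <- droplevels(d$participant)
  if (nlevels(d$group) < 2L || min(table(unique(d[, 1:2])$group)) < 2L) {
    stop("need at least two complete participants per group", call. = FALSE)
  }
  fit <- stats::aov(y ~ group * direction + Error(participant), data = d)
  s <- summary(fit)
  between <- s[["Error: participant"]][[1L]]
  within <- s[["Error: Within"]][[1L]]
  pick <- function(tab, name) {
    i <- which(trimws(rownames(tab)) == name)
    r <- which(trimws(rownames(tab)) == "Residuals")
    ss_eff <- tab[i, "Sum Sq"]
    ss_err <- tab[r, "Sum Sq"]
    f <- tab[i, "F value"]
    p <- tab[i, "Pr(>F)"]
    tot <- ss_eff + ss_err
    if (ss_eff == 0 || (tot > 0 && ss_eff / tot < 1e-12)) {
      # nothing explained: F = 0 regardless of the error term
      f <- 0
      p <- 1
    } else if (ss_err / tot < 1e-12) {
      f <- NA_real_ # zero error variance with a nonzero effect
      p <- NA_real_
    }
    data.frame(effect = name, df_num = tab[i, "Df"], df_den = tab[r, "Df"],
               F = f, p = p,
               eta_p2 = if (ss_eff + ss_err > 0) ss_eff / (ss_eff + ss_err)
                        else 0)
  }
  res <- rbind(pick(between, "group"),
               pick(within, "direction"),
               pick(within, "group:direction"))
  if (any(!is.finite(res$F))) {
    warning("zero error variance: F is undefined for some effect",
            call. = FALSE)
  }
  rownames(res) <- NULL
  attr(res, "n_complete") <- nlevels(d$participant)
  class(res) <- c("mixed_anova_result", class(res))
  res
}

#' @export
print.mixed_anova_result <- function(x, ...) {
  cat(sprintf("Mixed ANOVA (%d complete participants)\n",
              attr(x, "n_complete")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-16s F(%d,%d) = %.2f, p = %.4g, eta_p2 = %.3f\n",
                x$effect[i], x$df_num[i], x$df_den[i], x$F[i], x$p[i],
                x$eta_p2[i]))
  }
  invisible(x)
}

#' Pearson correlation with its test
#'
#' Product-moment correlation between two variables, e.g. time on stairs vs
#' fraction of fixated steps across participants of both groups within one
#' direction.
#'
#' @param x,y Numeric vectors; pairs with missing values are dropped.
#' @return A list with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Compare session detection thresholds between groups
#'
#' The saccade detector's threshold adapts to each session's median
#' absolute velocity dot product; this diagnostic checks that those session
#' medians do not differ systematically between the groups (a systematic
#' difference would make the detector differentially sensitive).
#'
#' @param m_session Numeric vector of per-session median statistics.
#' @param group Group label per session.
#' @return A list with a per-group summary data frame (`group`, `n`,
#'   `mean`, `sd`), the mean difference, and the Welch t-test p value.
#' @export
threshold_diagnostics <- function(m_session, group) {
  ok <- is.finite(m_session)
  m_session <- m_session[ok]
  group <- factor(group[ok])
  if (nlevels(group) < 2L) {
    stop("need sessions from at least two groups", call. = FALSE)
  }
  if (min(table(group)) < 2L) {
    stop("need at least two sessions per group", call. = FALSE)
  }
  by_group <- data.frame(
    group = levels(group),
    n = as.integer(table(group)),
    mean = as.numeric(tapply(m_session, group, mean)),
    sd = as.numeric(tapply(m_session, group, stats::sd)))
  diff_means <- by_group$mean[1L] - by_group$mean[2L]
  p <- if (all(by_group$sd == 0)) {
    if (diff_means == 0) 1 else 0
  } else {
    stats::t.test(m_session ~ group)$p.value
  }
  list(by_group = by_group, diff = diff_means, p = p)
}
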