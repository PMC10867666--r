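study_roster <- function() {
  data.frame(
    participant = c(sprintf("rel_%02d", 1:18), sprintf("irr_%02d", 1:16)),
    group = rep(c("stairs_relevant", "stairs_irrelevant"), c(18, 16)))
}

study_exclusions <- function() {
  data.frame(
    participant = c("rel_01", "irr_01", "irr_02"),
    reason = c("ran", "phone_use", "others_present_descending"),
    scope = c("both_directions", "both_directions", "descending_only"))
}

test_that("exclusion arithmetic reproduces the included group sizes", {
  counts <- apply_exclusions(study_roster(), study_exclusions())
  get_n <- function(g, d) counts$n[counts$group == g & counts$direction == d]
  expect_equal(get_n("stairs_relevant", "descending"), 17L)
  expect_equal(get_n("stairs_irrelevant", "descending"), 14L)
  expect_equal(get_n("stairs_relevant", "ascending"), 17L)
  expect_equal(get_n("stairs_irrelevant", "ascending"), 15L)
  # empty record list leaves the roster untouched
  c0 <- apply_exclusions(study_roster(),
                         study_exclusions()[0, , drop = FALSE])
  expect_true(all(c0$n[c0$group == "stairs_relevant"] == 18L))
  expect_true(all(c0$n[c0$group == "stairs_irrelevant"] == 16L))
})

test_that("exclusion records are validated", {
  expect_error(apply_exclusions(study_roster(), data.frame(
    participant = "nobody", reason = "x", scope = "both_directions")),
    "unknown participant")
  expect_error(apply_exclusions(study_roster(), data.frame(
    participant = c("rel_01", "rel_01"), reason = c("a", "b"),
    scope = rep("both_directions", 2))), "at most one")
  expect_error(apply_exclusions(study_roster(), data.frame(
    participant = "rel_01", reason = "x", scope = "sideways")), "scope")
})

random_cohort_table <- function(n1, n2, effect = 0.5) {
  ids <- c(sprintf("a%02d", seq_len(n1)), sprintf("b%02d", seq_len(n2)))
  d <- expand.grid(participant = ids,
                   direction = c("descending", "ascending"),
                   stringsAsFactors = FALSE)
  d$group <- rep(rep(c("g1", "g2"), c(n1, n2)), 2)
  d$y <- rnorm(nrow(d)) + (d$group == "g1") * effect +
    (d$direction == "ascending") * 0.3
  d
}

test_that("mixed ANOVA agrees with the sums-of-squares oracle", {
  set.seed(13)
  for (rep in 1:10) {
    d <- random_cohort_table(sample(4:10, 1), sample(4:10, 1))
    fit <- mixed_anova(d, "y")
    orc <- oracle_mixed_anova(d)
    expect_equal(fit$F, orc$F, tolerance = 1e-10)
    expect_equal(fit$p, orc$p, tolerance = 1e-10)
    expect_equal(fit$df_den, orc$df_den)
    expect_equal(fit$df_num, rep(1L, 3))
  }
})

test_that("2x2 equivalences: between F = t^2 on subject means, within F = paired t^2", {
  set.seed(29)
  d <- random_cohort_table(8, 8)
  fit <- mixed_anova(d, "y")
  subj <- tapply(d$y, d$participant, mean)
  grp <- tapply(as.character(d$group), d$participant, function(x) x[1])
  tt <- t.test(subj ~ grp, var.equal = TRUE)
  expect_equal(fit$F[fit$effect == "group"], unname(tt$statistic)^2,
               tolerance = 1e-10)
  wide <- reshape(d[, c("participant", "direction", "y")],
                  idvar = "participant", timevar = "direction",
                  direction = "wide")
  # paired t on the direction differences; with a group factor present the
  # matching error term centres the differences within each group
  di <- wide$y.ascending - wide$y.descending
  g_of <- grp[as.character(wide$participant)]
  N <- length(di)
  s2_centred <- sum((di - ave(di, g_of))^2) / (N - 2)
  t2 <- N * mean(di)^2 / s2_centred
  expect_equal(fit$F[fit$effect == "direction"], t2, tolerance = 1e-10)
})

test_that("incomplete participants are dropped, fixing the denominator df", {
  set.seed(31)
  d <- random_cohort_table(17, 15)
  # one g2 participant loses their descending row
  d <- d[!(d$participant == "b01" & d$direction == "descending"), ]
  expect_message(fit <- mixed_anova(d, "y"), "dropped 1")
  expect_equal(attr(fit, "n_complete"), 31L)
  expect_true(all(fit$df_den == 29L))
})

test_that("identical values yield F = 0 and zero effect size", {
  d <- random_cohort_table(4, 4)
  d$y <- 1
  fit <- mixed_anova(d, "y")
  expect_true(all(fit$F == 0))
  expect_true(all(fit$p == 1))
  expect_true(all(fit$eta_p2 == 0))
})

test_that("a nonzero effect with zero error variance is flagged", {
  d <- random_cohort_table(4, 4)
  d$y <- as.numeric(d$group == "g1") # perfect group separation, no noise
  expect_warning(fit <- mixed_anova(d, "y"), "zero error variance")
  expect_true(is.na(fit$F[fit$effect == "group"]))
})

test_that("mixed ANOVA input validation", {
  d <- random_cohort_table(3, 3)
  d2 <- rbind(d, d[1, ])
  expect_error(mixed_anova(d2, "y"), "at most one value")
  d3 <- random_cohort_table(1, 4)
  expect_error(suppressMessages(mixed_anova(d3, "y")), "at least two")
})

test_that("pearson correlation behaves on the canonical cases", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1))$r, -1, tolerance = 1e-12)
  set.seed(21)
  a <- rnorm(500)
  b <- rnorm(500)
  expect_lt(abs(pearson_r(a, b)$r), 0.15)
  expect_error(pearson_r(1:2, 2:3), "at least 3")
  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")
})

test_that("threshold diagnostics compare session medians across groups", {
  m <- c(1, 1, 1, 1)
  g <- rep(c("a", "b"), each = 2)
  d0 <- threshold_diagnostics(m, g)
  expect_equal(d0$diff, 0)
  set.seed(2)
  m2 <- c(rnorm(20, 10, 1), rnorm(20, 10, 1))
  g2 <- rep(c("a", "b"), each = 20)
  d2 <- threshold_diagnostics(m2, g2)
  sem <- sqrt(d2$by_group$sd[1]^2 / 20 + d2$by_group$sd[2]^2 / 20)
  expect_lt(abs(d2$diff), 2 * sem + 1e-9)
  expect_error(threshold_diagnostics(m2, rep("a", 40)), "two groups")
})
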