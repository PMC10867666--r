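make_gaze <- function(t, az, el) data.frame(t = t, az = az, el = el,
                                            valid = TRUE)

test_that("blink removal invalidates exactly the covered samples", {
  g <- make_gaze(seq(0, 2, by = 0.005), 0, 0)
  expect_identical(remove_blinks(g, NULL), g)
  expect_identical(remove_blinks(g, data.frame(start = numeric(),
                                               end = numeric())), g)
  b <- data.frame(start = 1.0, end = 1.2)
  g2 <- remove_blinks(g, b)
  expect_identical(!g2$valid, g$t >= 1.0 & g$t <= 1.2)
  expect_equal(sum(!g2$valid), sum(vapply(g$t, function(t) {
    t >= 1.0 && t <= 1.2
  }, logical(1))))
  # whole-trace blink kills all downstream detection
  g3 <- remove_blinks(g, data.frame(start = -1, end = 3))
  expect_false(any(g3$valid))
  expect_equal(nrow(detect_saccades(g3)), 0)
  expect_error(remove_blinks(g, data.frame(start = c(0.1, 0.15),
                                           end = c(0.2, 0.3))), "overlap")
  expect_error(remove_blinks(g, data.frame(start = 0.5, end = 0.4)),
               "end >= start")
})

test_that("velocity and dot product match their definitions", {
  t <- seq(0, 1, by = 0.005)
  g <- make_gaze(t, 5, -3)
  v <- compute_velocity(g)
  expect_true(all(v$v_az == 0 & v$v_el == 0))
  expect_true(all(v$dot_next[!is.na(v$dot_next)] == 0))
  # linear motion: az at 40 deg/s, uniform 5 ms sampling
  g2 <- make_gaze(t, 40 * t, 0)
  v2 <- compute_velocity(g2)
  expect_equal(v2$v_az, rep(40, nrow(v2)), tolerance = 1e-9)
  expect_equal(v2$dot_next[-nrow(v2)], rep(1600, nrow(v2) - 1L),
               tolerance = 1e-9)
  expect_true(is.na(v2$dot_next[nrow(v2)]))
  # randomized trace: dot_next equals an independently recomputed v_i.v_i+1
  set.seed(3)
  g3 <- make_gaze(t, cumsum(rnorm(length(t))), cumsum(rnorm(length(t))))
  v3 <- compute_velocity(g3)
  for (i in seq_len(nrow(v3) - 1L)) {
    expect_equal(v3$dot_next[i],
                 v3$v_az[i] * v3$v_az[i + 1L] + v3$v_el[i] * v3$v_el[i + 1L])
  }
  # fewer than two valid samples: empty series
  g4 <- make_gaze(0.1, 1, 1)
  expect_equal(nrow(compute_velocity(g4)), 0)
})

test_that("velocity is never computed across a blink gap", {
  t <- seq(0, 1, by = 0.005)
  g <- make_gaze(t, 100 * t, 0) # fast drift
  g <- remove_blinks(g, data.frame(start = 0.4, end = 0.6))
  v <- compute_velocity(g)
  # no velocity sample straddles the invalid span
  expect_false(any(v$t_mid > 0.4 & v$t_mid < 0.6))
  # dot_next is NA at the run boundary before the gap
  last_before <- max(which(v$t_mid < 0.4))
  expect_true(is.na(v$dot_next[last_before]))
})

test_that("a single clean saccade is detected with correct metrics", {
  # 1 s fixation, 4-degree rightward saccade over 50 ms, 1 s fixation
  t <- seq(0, 2.05, by = 0.005)
  az <- numeric(length(t))
  sacc <- t >= 1 & t < 1.05
  tau <- (t[sacc] - 1) / 0.05
  az[sacc] <- 4 * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  az[t >= 1.05] <- 4
  set.seed(5)
  g <- make_gaze(t, az + rnorm(length(t), 0, 0.05),
                 rnorm(length(t), 0, 0.05))
  s <- detect_saccades(g)
  expect_equal(nrow(s), 1)
  expect_lt(abs(s$amplitude_deg - 4), 0.2)
  expect_true(s$direction_deg > 45 && s$direction_deg < 135) # rightward
  expect_lt(abs(s$onset_s - 1), 0.02)
})

test_that("still gaze with tiny noise yields no saccades", {
  set.seed(8)
  t <- seq(0, 2, by = 0.005)
  g <- make_gaze(t, rnorm(length(t), 0, 0.05), rnorm(length(t), 0, 0.05))
  expect_equal(nrow(detect_saccades(g)), 0)
})

test_that("perfectly still gaze degenerates with a warning, zero events", {
  g <- make_gaze(seq(0, 1, by = 0.005), 2, 2)
  expect_warning(s <- detect_saccades(g), "median")
  expect_equal(nrow(s), 0)
})

test_that("amplitude floor discards small candidates", {
  t <- seq(0, 2.05, by = 0.005)
  mk <- function(amp) {
    az <- numeric(length(t))
    sacc <- t >= 1 & t < 1.05
    tau <- (t[sacc] - 1) / 0.05
    az[sacc] <- amp * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
    az[t >= 1.05] <- amp
    set.seed(1)
    make_gaze(t, az + rnorm(length(t), 0, 0.03),
              rnorm(length(t), 0, 0.03))
  }
  expect_equal(nrow(detect_saccades(mk(2.9))), 0)
  expect_equal(nrow(detect_saccades(mk(3.4))), 1)
})

test_that("refractory rule keeps the faster of two close saccades", {
  ev <- data.frame(onset_s = c(1.00, 1.13), offset_s = c(1.05, 1.18),
                   amplitude_deg = c(5, 4), direction_deg = c(0, 90),
                   peak_speed = c(300, 150))
  kept <- stairgaze:::prune_refractory(ev, 0.100)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$peak_speed, 300)
  # under the amplitude reading of "slower", same outcome here
  kept2 <- stairgaze:::prune_refractory(ev, 0.100, "amplitude")
  expect_equal(kept2$amplitude_deg, 5)
})

test_that("refractory pruning reaches a fixed point with all gaps legal", {
  set.seed(14)
  for (rep in 1:20) {
    n <- sample(2:12, 1)
    onset <- sort(runif(n, 0, 3))
    ev <- data.frame(onset_s = onset, offset_s = onset + 0.03,
                     amplitude_deg = runif(n, 3, 10),
                     direction_deg = runif(n, 0, 360),
                     peak_speed = runif(n, 100, 500))
    kept <- stairgaze:::prune_refractory(ev, 0.100)
    if (nrow(kept) > 1) {
      gaps <- kept$onset_s[-1] - kept$offset_s[-nrow(kept)]
      expect_true(all(gaps >= 0.100))
    }
    expect_identical(stairgaze:::prune_refractory(kept, 0.100), kept)
  }
})

test_that("detection is invariant to uniform scaling of gaze angles", {
  w <- generate_walk(noiseless_params(seed = 17))
  g <- w$recording$gaze
  s1 <- suppressWarnings(detect_saccades(g))
  g2 <- g
  g2$az <- g$az * 1.5
  g2$el <- g$el * 1.5
  s2 <- suppressWarnings(detect_saccades(g2))
  expect_equal(s2$onset_s, s1$onset_s)
  expect_equal(s2$offset_s, s1$offset_s)
  expect_equal(s2$amplitude_deg, 1.5 * s1$amplitude_deg, tolerance = 1e-9)
  expect_equal(attr(s2, "m_session"), 1.5^2 * attr(s1, "m_session"),
               tolerance = 1e-9)
})

test_that("detector equals the naive reference on random traces", {
  set.seed(101)
  for (rep in 1:25) {
    g <- random_trace(n = sample(300:1200, 1), n_jumps = sample(0:4, 1))
    a <- suppressWarnings(detect_saccades(g))
    b <- suppressWarnings(naive_detect_saccades(g))
    expect_equal(nrow(a), nrow(b))
    if (nrow(a) > 0) {
      expect_equal(a$onset_s, b$onset_s)
      expect_equal(a$offset_s, b$offset_s)
      expect_equal(a$amplitude_deg, b$amplitude_deg, tolerance = 1e-12)
      expect_equal(a$direction_deg, b$direction_deg, tolerance = 1e-12)
    }
  }
})

test_that("saccade direction convention: up 0, right 90, down-left 225", {
  expect_equal(saccade_direction(0, 2), 0)
  expect_equal(saccade_direction(2, 0), 90)
  expect_equal(saccade_direction(0, -2), 180)
  expect_equal(saccade_direction(-2, 0), 270)
  expect_equal(saccade_direction(-1, -1), 225)
  expect_error(saccade_direction(0, 0), "zero displacement")
})

test_that("direction binning is half-open and conserves counts", {
  h <- bin_directions(c(0, 8.999, 9.0))
  expect_equal(nrow(h), 40)
  expect_equal(h$count[1], 2)
  expect_equal(h$count[2], 1)
  expect_error(bin_directions(10, bin_width_deg = 7), "divide 360")
  set.seed(11)
  d <- runif(1000, 0, 360)
  h2 <- bin_directions(d)
  expect_equal(sum(h2$count), 1000)
  brute <- integer(40)
  for (x in d) brute[floor(x / 9) + 1L] <- brute[floor(x / 9) + 1L] + 1L
  expect_equal(h2$count, brute)
  # amplitude stratification mirrors the per-class subsets
  amps <- runif(1000, 2, 12)
  h3 <- bin_directions(d, amplitudes_deg = amps, amp_min_deg = c(3, 5, 7))
  expect_equal(sum(h3$count_ge_3), sum(amps >= 3))
  expect_true(all(h3$count_ge_7 <= h3$count_ge_5))
})

test_that("mean amplitude averages across the two staircases", {
  expect_equal(mean_saccade_amplitude(list(4, 6)), 5)
  expect_equal(mean_saccade_amplitude(list(numeric(), c(6, 8))), 7)
  expect_equal(mean_saccade_amplitude(list(c(5, 5), c(5, 5, 5))), 5)
  expect_true(is.na(mean_saccade_amplitude(list(numeric(), numeric()))))
})
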