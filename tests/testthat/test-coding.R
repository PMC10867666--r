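test_that("runs of two or more frames become events, shorter ones vanish", {
  f <- frames_from_labels(c("s1_step04", "s1_step04", "s1_step04",
                            "elsewhere", "elsewhere",
                            "s1_step05", "s1_step05"))
  ev <- label_fixations(f)
  expect_equal(ev$label, c("s1_step04", "elsewhere", "s1_step05"))
  expect_equal(ev$n_frames, c(3L, 2L, 2L))
  expect_equal(ev$step, c(4L, NA, 5L))
  # no run reaches two frames
  f2 <- frames_from_labels(c("s1_step04", "s1_step05", "s1_step04",
                             "s1_step05"))
  expect_equal(nrow(label_fixations(f2)), 0)
})

test_that("a one-frame intrusion is discarded and its flanks merge", {
  f <- frames_from_labels(c("s1_step05", "s1_step05", "s1_step04",
                            "s1_step05", "s1_step05"))
  ev <- label_fixations(f)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$step, 5L)
  expect_equal(ev$n_frames, 4L)
  # brute-force run-length check of the same stream
  r <- rle(f$label)
  kept <- r$values[r$lengths >= 2]
  expect_equal(unique(kept), "s1_step05")
  # strict mode treats the intrusion as a break instead
  ev2 <- label_fixations(f, strict_breaks = TRUE)
  expect_equal(nrow(ev2), 2)
  expect_equal(ev2$step, c(5L, 5L))
})

test_that("none frames never form events and separate their neighbours", {
  f <- frames_from_labels(c(rep("s1_step03", 3), rep("none", 3),
                            rep("s1_step03", 2)))
  ev <- label_fixations(f)
  expect_equal(nrow(ev), 2) # the none run keeps the two step-3 runs apart
  expect_true(all(ev$label == "s1_step03"))
})

test_that("coding is idempotent on its own reconstruction", {
  set.seed(6)
  labs <- sample(c("s1_step01", "s1_step02", "elsewhere"), 60, TRUE)
  ev <- label_fixations(frames_from_labels(labs))
  # rebuild a label stream from the events and recode it
  rebuilt <- unlist(lapply(seq_len(nrow(ev)), function(i) {
    rep(ev$label[i], ev$n_frames[i])
  }))
  ev2 <- label_fixations(frames_from_labels(rebuilt))
  expect_equal(ev2$label, ev$label)
  expect_equal(ev2$n_frames, ev$n_frames)
})

test_that("events never overlap and each frame feeds at most one event", {
  set.seed(7)
  labs <- sample(c("s1_step01", "s1_step02", "s2_step01", "elsewhere",
                   "none"), 120, TRUE)
  ev <- label_fixations(frames_from_labels(labs))
  if (nrow(ev) > 1) {
    expect_true(all(ev$start_s[-1] > ev$last_frame_s[-nrow(ev)]))
  }
  expect_lte(sum(ev$n_frames), 120)
})

test_that("unknown labels are rejected with their position", {
  f <- frames_from_labels(c("s1_step01", "s1_step01", "garbage", "garbage"))
  expect_error(label_fixations(f), "garbage")
})

test_that("window restriction keeps, trims and drops correctly", {
  ev <- label_fixations(frames_from_labels(c(
    rep("elsewhere", 3),              # leading elsewhere -> trimmed
    rep("s1_step01", 3),
    rep("elsewhere", 2),
    rep("s1_step02", 3),
    rep("s2_step01", 3),              # other staircase -> filtered
    rep("elsewhere", 2)               # trailing elsewhere -> trimmed
  )))
  sq <- restrict_to_staircase(ev, c(0, 10), staircase = 1)
  expect_equal(sq$kind, c("step", "elsewhere", "step"))
  expect_equal(sq$step, c(1L, NA, 2L))
  # empty when no step fixation falls in the window
  sq2 <- restrict_to_staircase(ev, c(100, 110), staircase = 1)
  expect_equal(nrow(sq2), 0)
})

test_that("boundary events need two frames inside the window", {
  # step event with frames at 0, 1/30, 2/30: window starting at 1/30 keeps
  # it (2 frames inside); window starting just after drops it
  ev <- label_fixations(frames_from_labels(rep("s1_step01", 3)))
  expect_equal(nrow(restrict_to_staircase(ev, c(1 / 30, 1), 1)), 1)
  expect_equal(nrow(restrict_to_staircase(ev, c(2 / 30 - 1e-6, 1), 1)),
               0) # only the last frame inside -> dropped
})

test_that("coded sequences equal the generator's truth on noise-free walks", {
  w <- generate_walk(noiseless_params(seed = 5))
  rec <- w$recording
  ev <- label_fixations(rec$frames)
  for (i in 1:2) {
    fp <- w$truth$true_foot_placements
    fp <- fp[fp$staircase == i, ]
    sq <- restrict_to_staircase(ev, analysis_window(min(fp$t), max(fp$t)), i)
    tr <- true_sequence(w$truth, i)
    expect_equal(paste(sq$kind, sq$step), paste(tr$kind, tr$step))
  }
})

test_that("a fixation ending 3 s before the first step is excluded", {
  # step-1 fixation far before the window, another inside it
  labs <- c(rep("s1_step01", 3), rep("none", 88), rep("s1_step01", 3),
            rep("s1_step02", 3))
  f <- frames_from_labels(labs)
  # first placement at t = 5 s -> window [3, 6]; early fixation ends ~0.1 s
  sq <- restrict_to_staircase(label_fixations(f), c(3, 6), 1)
  expect_equal(nrow(sq), 2)
  expect_gt(min(sq$start_s), 2.9)
})
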