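test_that("body box derivation matches the hand-computed geometry", {
  b <- body_box_from_head(head_box(100, 50, 40, 50), c(120, 350), 8)
  expect_equal(b$bx, -80)
  expect_equal(b$by, 50)
  expect_equal(b$bw, 400)
  expect_equal(b$bh, 400)
  expect_equal(b$theta, 0)

  b2 <- body_box_from_head(head_box(100, 50, 40, 50), c(175, 350), 8)
  expect_equal(b2$theta, atan(55 / 275), tolerance = 1e-12)
})

test_that("body box invariants: square of 8 head heights, head centred", {
  set.seed(5)
  for (i in 1:20) {
    hb <- head_box(runif(1, 0, 1000), runif(1, 0, 500),
                   runif(1, 10, 80), runif(1, 10, 80))
    hip <- c(hb$fx + runif(1, -100, 100), hb$fy + runif(1, 100, 400))
    b <- body_box_from_head(hb, hip, 8)
    expect_equal(b$bw, 8 * hb$fh)
    expect_identical(b$bw, b$bh)
    expect_equal(b$bx + b$bw / 2, hb$fx + hb$fw / 2)
    expect_gt(b$theta, -pi); expect_lte(b$theta, pi)
  }
})

test_that("a horizontal body yields |theta| near pi/2, not an error", {
  hb <- head_box(100, 100, 40, 40)
  # hips level with the head centre, displaced sideways: fallen flat
  b <- body_box_from_head(hb, c(400, 120), 8)
  expect_equal(abs(b$theta), pi / 2)
  # hip approaching the head centre from below stays at angle zero
  b2 <- body_box_from_head(hb, c(120, 120 + 1e-9), 8)
  expect_equal(b2$theta, 0)
  expect_error(body_box_from_head(hb, c(120, 120)), "geometry error")
})

test_that("torso centroid weights by confidence and thresholds dropouts", {
  cl <- toy_clip(ls = c(10, 20), rs = c(30, 20), lh = c(12, 60),
                 rh = c(28, 60))
  expect_equal(unname(torso_centroid(cl, 1)), c(20, 40))
  ids <- unname(pose_landmarks[c("left_shoulder", "right_shoulder",
                                 "left_hip", "right_hip")]) + 1
  cl$conf[1, ids[1]] <- 0  # drop the left shoulder
  expect_equal(unname(torso_centroid(cl, 1)),
               c(mean(c(30, 12, 28)), mean(c(20, 60, 60))))
  cl$conf[2, ids] <- 0.2
  expect_null(torso_centroid(cl, 2, conf_threshold = 0.5))
})

test_that("offset vector is the centroid displacement", {
  cl <- toy_clip(n = 3)
  expect_equal(unname(offset_vector(cl, 1, 2)), c(0, 0))
  cl$x[2, ] <- cl$x[2, ] + 5
  cl$y[2, ] <- cl$y[2, ] - 3
  expect_equal(unname(offset_vector(cl, 1, 2)), c(5, -3))
  ids <- unname(pose_landmarks[c("left_shoulder", "right_shoulder",
                                 "left_hip", "right_hip")]) + 1
  cl$conf[3, ids] <- 0
  expect_null(offset_vector(cl, 2, 3))
})

test_that("box updates translate and compose additively", {
  b <- body_box_from_head(head_box(100, 50, 40, 50), c(120, 350))
  b1 <- update_box(b, c(5, -3))
  expect_equal(c(b1$bx, b1$by), c(-75, 47))
  expect_equal(c(b1$bw, b1$bh, b1$theta), c(b$bw, b$bh, b$theta))
  expect_equal(update_box(b, c(0, 0)), b)
  ab <- update_box(update_box(b, c(2, 7)), c(-9, 4))
  expect_equal(ab, update_box(b, c(-7, 11)))
})

test_that("re-detection triggers on dropouts, low confidence and jumps", {
  cl <- toy_clip(n = 4)
  b <- body_box_from_head(head_box(10, 5, 20, 25), c(20, 150))
  cfg <- tracker_config()
  expect_false(needs_redetection(cl, 1, b, cfg, c(1, 1)))
  lowc <- toy_clip(n = 2, conf = 0.1)
  expect_true(needs_redetection(lowc, 1, b, cfg))
  expect_true(needs_redetection(cl, 2, b, cfg, c(150, 0)))  # jump > 0.5*bw=100
  cfg2 <- tracker_config(redetect_every = 2)
  expect_true(needs_redetection(cl, 3, b, cfg2))  # frame_index 2 due
})

test_that("a translating subject needs one detector call in 50 frames", {
  p <- motion_params(seed = 21, noise_std = 0)
  cl <- simulate_clip("walking", 50, p)
  tr <- track_clip(cl, head_source_from_track(cl$head_track))
  expect_identical(nrow(tr), 50L)
  expect_identical(sum(tr$redetected), 1L)
  expect_true(tr$redetected[1])
})

test_that("the tracked box keeps the torso centred during rigid translation", {
  # rigid translation: same jitter-free skeleton shifted 4 px/frame
  p <- motion_params(seed = 3, noise_std = 0)
  cl <- simulate_clip("standing", 40, p)
  shift <- 4 * (seq_len(40) - 1)
  cl$x <- sweep(cl$x, 1, shift, `+`)
  cl$head_track$fx <- cl$head_track$fx + shift
  tr <- track_clip(cl, head_source_from_track(cl$head_track))
  rel <- vapply(seq_len(40), function(i)
    torso_centroid(cl, i)[1] - tr$bx[i], 0)
  expect_lt(max(abs(rel - rel[1])), 1e-6)
  rely <- vapply(seq_len(40), function(i)
    torso_centroid(cl, i)[2] - tr$by[i], 0)
  expect_lt(max(abs(rely - rely[1])), 1e-6)
})

test_that("a static subject keeps an identical box", {
  p <- motion_params(seed = 8, noise_std = 0)
  cl <- simulate_clip("standing", 20, p)
  tr <- track_clip(cl, head_source_from_track(cl$head_track))
  expect_equal(diff(range(tr$bx)), 0)
  expect_equal(diff(range(tr$by)), 0)
  expect_identical(sum(tr$redetected), 1L)
})

test_that("confidence loss mid-clip forces a re-detection there", {
  p <- motion_params(seed = 9, noise_std = 0)
  cl <- simulate_clip("standing", 40, p)
  ids <- unname(pose_landmarks[c("left_shoulder", "right_shoulder",
                                 "left_hip", "right_hip")]) + 1
  cl$conf[25, ids] <- 0
  tr <- track_clip(cl, head_source_from_track(cl$head_track))
  expect_true(tr$redetected[25])
})

test_that("per-frame re-detection agrees with coasting on rigid motion", {
  p <- motion_params(seed = 13, noise_std = 0)
  cl <- simulate_clip("standing", 30, p)
  shift <- 5 * (seq_len(30) - 1)           # rigid uniform translation
  cl$x <- sweep(cl$x, 1, shift, `+`)
  cl$head_track$fx <- cl$head_track$fx + shift
  coast <- track_clip(cl, head_source_from_track(cl$head_track))
  naive <- track_clip(cl, head_source_from_track(cl$head_track),
                      tracker_config(redetect_every = 1))
  expect_true(all(naive$redetected))
  expect_lt(max(abs(coast$bx - naive$bx)), 1)
  expect_lt(max(abs(coast$by - naive$by)), 1)
})

test_that("detector failure on frame 0 aborts; mid-clip failure coasts", {
  p <- motion_params(seed = 14, noise_std = 0)
  cl <- simulate_clip("standing", 10, p)
  expect_error(track_clip(cl, function(i) stop("no head")),
               "tracking error")
  ids <- unname(pose_landmarks[c("left_shoulder", "right_shoulder",
                                 "left_hip", "right_hip")]) + 1
  cl$conf[5, ids] <- 0  # triggers a re-detection attempt at frame 5
  flaky <- function(i) {
    if (i == 5) stop("detector offline")
    head_source_from_track(cl$head_track)(i)
  }
  tr <- track_clip(cl, flaky)
  expect_false(tr$redetected[5])
  expect_false(any(is.na(tr$bx)))
})
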