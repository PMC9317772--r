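# torso-axis angle from downward vertical at one frame, from raw coordinates
axis_angle <- function(cl, i) {
  ids <- unname(pose_landmarks[c("left_shoulder", "right_shoulder",
                                 "left_hip", "right_hip")]) + 1
  sx <- mean(cl$x[i, ids[1:2]]); sy <- mean(cl$y[i, ids[1:2]])
  hx <- mean(cl$x[i, ids[3:4]]); hy <- mean(cl$y[i, ids[3:4]])
  atan2(hx - sx, hy - sy)
}

test_that("falling ends near horizontal; standing stays upright", {
  p <- motion_params(seed = 71)
  fall <- simulate_clip("falling", 60, p)
  expect_gt(abs(axis_angle(fall, 60)) * 180 / pi, 60)
  stand <- simulate_clip("standing", 60, p)
  expect_lt(abs(axis_angle(stand, 60)) * 180 / pi, 10)
})

test_that("generation is deterministic per seed and varies across seeds", {
  a <- simulate_clip("walking", 40, motion_params(seed = 5))
  b <- simulate_clip("walking", 40, motion_params(seed = 5))
  expect_identical(a$x, b$x); expect_identical(a$conf, b$conf)
  expect_identical(a$head_track, b$head_track)
  c <- simulate_clip("walking", 40, motion_params(seed = 6))
  expect_false(identical(a$x, c$x))
})

test_that("noise-free standing is exactly static", {
  p <- motion_params(seed = 1, noise_std = 0)
  cl <- simulate_clip("standing", 20, p)
  expect_equal(diff(range(cl$x[, 1])), 0)
  for (j in 1:33) expect_identical(cl$x[1, j], cl$x[20, j])
})

test_that("the corpus is balanced with distinct deterministic clips", {
  clips <- generate_dataset(3, 50, motion_params(seed = 72),
                            include_transitions = FALSE)
  expect_length(clips, 12)
  prefixes <- sub("_[0-9]+$", "", vapply(clips, function(cl) cl$clip_id, ""))
  expect_equal(unname(table(prefixes)[activity_levels]), rep(3L, 4),
               ignore_attr = TRUE)
  ids <- vapply(clips, function(cl) cl$clip_id, "")
  expect_length(unique(ids), 12)
  for (i in 2:12)
    expect_false(identical(clips[[1]]$x, clips[[i]]$x))
  again <- generate_dataset(3, 50, motion_params(seed = 72),
                            include_transitions = FALSE)
  expect_identical(clips[[7]]$x, again[[7]]$x)
})

test_that("generated clips serialize and read back intact", {
  clips <- generate_dataset(1, 30, motion_params(seed = 73))
  path <- withr::local_tempfile(fileext = ".csv")
  write_keypoint_records(clips, path, "csv")
  back <- read_keypoint_records(path, "csv")
  expect_length(back, length(clips))
  ids <- vapply(back, function(cl) cl$clip_id, "")
  for (cl in clips) expect_clip_equal(cl, back[[match(cl$clip_id, ids)]])
})

test_that("coordinates stay inside the image at default parameters", {
  for (act in activity_levels) {
    cl <- simulate_clip(act, 90, motion_params(seed = 74, occlusion_rate = 0))
    expect_true(all(cl$x >= 0 & cl$x <= cl$image_size[1]))
    expect_true(all(cl$y >= 0 & cl$y <= cl$image_size[2]))
  }
  expect_error(simulate_clip("jumping", 50), "invalid activity")
})

test_that("the head track satisfies the Vitruvian ratio within 15%", {
  p <- motion_params(seed = 75)
  for (act in c("standing", "walking")) {
    cl <- simulate_clip(act, 40, p)
    ht <- cl$head_track
    b <- body_box_from_head(head_box(ht$fx[1], ht$fy[1], ht$fw[1], ht$fh[1]),
                            hip_midpoint(cl, 1), ratio = 8)
    expect_lt(abs(b$bw - p$body_height_px) / p$body_height_px, 0.15)
    # the derived box covers the whole standing body
    expect_lt(abs(b$theta) * 180 / pi, 8)
  }
})

test_that("outlier injection hits the contracted number of slots", {
  cl <- simulate_clip("standing", 50, motion_params(seed = 76))
  inj <- inject_outliers(cl, rate = 0.05, magnitude_px = 300, seed = 3)
  expect_equal(sum(inj$mask), round(0.05 * 8 * 50))
  expect_identical(dim(inj$mask), c(50L, 8L))
  # rate 0 is the identity
  inj0 <- inject_outliers(cl, rate = 0)
  expect_identical(inj0$clip$x, cl$x)
  expect_false(any(inj0$mask))
  # corrupted slots moved by exactly the magnitude
  tf0 <- torso_features(cl); tf1 <- torso_features(inj$clip)
  expect_true(all(abs(tf1[inj$mask] - tf0[inj$mask]) == 300))
  expect_true(all(tf1[!inj$mask] == tf0[!inj$mask]))
})

test_that("falling windows separate from standing by mean hip drop rate", {
  # scope: windows containing the complete descent; at the labeling
  # boundary a single barely-started descent frame cannot dominate the
  # jitter noise of the other 29 frames
  hipv <- function(w) {
    hy <- rowMeans(w$features[, c(6, 8)])  # LHy, RHy normalized
    mean(diff(hy))
  }
  fall_v <- unlist(lapply(1:3, function(i) {
    p <- motion_params(seed = 77 + i)
    cl <- clean_clip(simulate_clip("falling", 60, p))
    onset <- 60 - p$fall_duration - 10
    w <- build_windows(cl, W = 30)
    keep <- vapply(w, function(x)
      x$start_frame + 29 >= onset + p$fall_duration, TRUE)
    vapply(w[keep], hipv, 0)
  }))
  stand_v <- unlist(lapply(1:3, function(i) {
    cl <- clean_clip(simulate_clip("standing", 60,
                                   motion_params(seed = 87 + i)))
    vapply(build_windows(cl, W = 30), hipv, 0)
  }))
  # linearly separable: every falling window drops faster than any standing
  expect_gt(min(fall_v), max(stand_v))
})
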