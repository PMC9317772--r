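# shared fixture builders (all data generated in code)

# a clip with hand-placed torso keypoints; every other landmark parked at
# a fixed offset so projection invariance can be checked
toy_clip <- function(n = 5, ls = c(10, 20), rs = c(30, 20), lh = c(12, 60),
                     rh = c(28, 60), conf = 1, image_size = c(200, 100)) {
  x <- matrix(50, n, 33)
  y <- matrix(40, n, 33)
  cf <- matrix(conf, n, 33)
  ids <- unname(pose_landmarks[c("left_shoulder", "right_shoulder",
                                 "left_hip", "right_hip")]) + 1
  for (i in seq_len(n)) {
    x[i, ids] <- c(ls[1], rs[1], lh[1], rh[1])
    y[i, ids] <- c(ls[2], rs[2], lh[2], rh[2])
  }
  skeleton_clip("toy", x, y, cf, image_size = image_size)
}

# clip with fully random finite coordinates, for round-trip properties
random_clip <- function(id = "rand", n = 4, seed = 1) {
  set.seed(seed)
  x <- matrix(runif(n * 33, 0, 1920), n, 33)
  y <- matrix(runif(n * 33, 0, 1080), n, 33)
  conf <- matrix(runif(n * 33), n, 33)
  miss <- matrix(runif(n * 33) < 0.05, n, 33)
  x[miss] <- NA; y[miss] <- NA; conf[miss] <- 0
  skeleton_clip(id, x, y, conf, missing = miss,
                label = sample(c(activity_levels, NA), n, replace = TRUE),
                image_size = c(1920, 1080))
}

# strict equality of two clips on every stored field
expect_clip_equal <- function(a, b) {
  expect_identical(a$clip_id, b$clip_id)
  expect_identical(a$frame_index, b$frame_index)
  expect_identical(a$missing, b$missing)
  expect_identical(a$label, b$label)
  expect_equal(a$image_size, b$image_size)
  expect_identical(unname(a$x[!a$missing]), unname(b$x[!b$missing]))
  expect_identical(unname(a$y[!a$missing]), unname(b$y[!b$missing]))
  expect_identical(unname(a$conf[!a$missing]), unname(b$conf[!b$missing]))
}

head_source_from_track <- function(ht) {
  function(i) head_box(ht$fx[i], ht$fy[i], ht$fw[i], ht$fh[i])
}
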