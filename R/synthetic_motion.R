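#' Synthetic motion generator parameters
#'
#' Controls the 2-D kinematic templates used to emulate labeled skeleton
#' clips for the four activities. The templates are statistical, not
#' physical: what matters downstream is the vertical drop rate, torso
#' orientation and periodicity the classifier consumes.
#'
#' @param fps Frames per second (default 30).
#' @param image_size `(width, height)` px.
#' @param body_height_px Standing body height in px.
#' @param noise_std Gaussian keypoint jitter, px.
#' @param fall_duration Frames a fall takes from onset to lying.
#' @param walk_amplitude Limb-swing amplitude during walking, px.
#' @param walk_speed Horizontal walking speed, px/frame.
#' @param sit_drop Hip descent when sitting down, px.
#' @param occlusion_rate Per-keypoint-frame probability of a dropout
#'   (missing keypoint, confidence 0).
#' @param seed Integer seed.
#' @return An object of class `motion_params`.
#' @export
motion_params <- function(fps = 30, image_size = c(1920, 1080),
                          body_height_px = 600, noise_std = 2,
                          fall_duration = 15, walk_amplitude = 20,
                          walk_speed = 4, sit_drop = 200,
                          occlusion_rate = 0, seed = 1L) {
  stopifnot(fps > 0, all(image_size > 0), body_height_px > 0,
            noise_std >= 0, fall_duration > 0, walk_amplitude >= 0,
            walk_speed >= 0, sit_drop >= 0,
            occlusion_rate >= 0, occlusion_rate <= 1)
  structure(list(fps = fps, image_size = image_size,
                 body_height_px = body_height_px, noise_std = noise_std,
                 fall_duration = fall_duration,
                 walk_amplitude = walk_amplitude, walk_speed = walk_speed,
                 sit_drop = sit_drop, occlusion_rate = occlusion_rate,
                 seed = as.integer(seed)),
            class = "motion_params")
}

# canonical upright pose: per-landmark (x offset, y) in units of body height,
# y measured downward from the top of the head
base_pose <- function() {
  m <- matrix(c(
    0.000, 0.090,                              # nose
    0.020, 0.070,  0.030, 0.070,  0.040, 0.070,  # left eye inner/centre/outer
    -0.020, 0.070, -0.030, 0.070, -0.040, 0.070, # right eye
    0.050, 0.080, -0.050, 0.080,               # ears
    0.020, 0.110, -0.020, 0.110,               # mouth corners
    0.110, 0.220, -0.110, 0.220,               # shoulders
    0.130, 0.360, -0.130, 0.360,               # elbows
    0.140, 0.500, -0.140, 0.500,               # wrists
    0.150, 0.550, -0.150, 0.550,               # pinkies
    0.145, 0.555, -0.145, 0.555,               # index fingers
    0.135, 0.545, -0.135, 0.545,               # thumbs
    0.080, 0.520, -0.080, 0.520,               # hips
    0.085, 0.740, -0.085, 0.740,               # knees
    0.090, 0.950, -0.090, 0.950,               # ankles
    0.095, 0.970, -0.095, 0.970,               # heels
    0.110, 0.990, -0.110, 0.990                # foot tips
  ), ncol = 2, byrow = TRUE)
  colnames(m) <- c("x", "y")
  m
}

smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

# indices (1-based) of landmark groups
head_rows <- 1:11
upper_rows <- 1:25   # head + arms + torso down to the hips
knee_rows <- 26:27
swing_rows <- list(left = c(14, 16, 26, 28), right = c(15, 17, 27, 29))

# build a clip from a script of activity segments.
# segments: list of list(activity=, n=, onset=) where onset (frames into the
# segment) delays the sitting descent / fall; pre-onset frames are labeled
# "standing" since the subject is still upright and static.
build_motion <- function(segments, p, clip_id = "clip", x0 = 700,
                         rng_seed = p$seed) {
  set.seed(rng_seed)
  P0 <- base_pose()
  H <- p$body_height_px
  # floor margin: the fall rotation swings the far-side foot up to ~1.06 H
  # below the crown, so leave headroom beneath the standing footprint
  y_top <- p$image_size[2] - 1.12 * H
  n_total <- sum(vapply(segments, function(s) s$n, 0))
  x <- y <- conf <- matrix(NA_real_, n_total, 33L)
  miss <- matrix(FALSE, n_total, 33L)
  label <- character(n_total)
  x_shift <- 0
  walk_phase <- 0
  t_global <- 0L
  for (seg in segments) {
    act <- seg$activity
    onset <- seg$onset %||% 1L
    for (ts in seq_len(seg$n)) {
      t_global <- t_global + 1L
      pts <- cbind(P0[, 1] * H, P0[, 2] * H)
      lab <- act
      if (act == "walking") {
        # gait starts from rest: speed and swing ramp up over ~0.5 s, so
        # motion-onset windows occur in training with the right label
        r <- smoothstep(ts / (p$fps / 2))
        if (r <= 0.05) lab <- "standing"
        x_shift <- x_shift + r * p$walk_speed
        walk_phase <- walk_phase + r * 2 * pi * 1.6 / p$fps
        amp <- r * p$walk_amplitude
        sw <- amp * c(0.4, 0.8, 0.5, 1.0)   # elbow, wrist, knee, ankle
        pts[swing_rows$left, 1] <- pts[swing_rows$left, 1] +
          sw * sin(walk_phase)
        pts[swing_rows$right, 1] <- pts[swing_rows$right, 1] +
          sw * sin(walk_phase + pi)
        pts[12:13, 1] <- pts[12:13, 1] + 0.15 * amp * sin(walk_phase)
        pts[, 2] <- pts[, 2] + 0.1 * amp * sin(2 * walk_phase)
      } else if (act == "sitting") {
        s <- smoothstep((ts - onset) / p$fps)
        # frames where the descent is not yet observable (below the noise
        # floor) are labeled standing: the label tracks the visible state
        if (s <= 0.05) lab <- "standing"
        pts[upper_rows, 2] <- pts[upper_rows, 2] + s * p$sit_drop
        pts[knee_rows, 2] <- pts[knee_rows, 2] + 0.35 * s * p$sit_drop
        pts[knee_rows, 1] <- pts[knee_rows, 1] + 0.06 * H * s
      } else if (act == "falling") {
        s <- smoothstep((ts - onset) / p$fall_duration)
        if (s <= 0.05) lab <- "standing"
        phi <- s * (85 * pi / 180)
        pivot <- c(mean(pts[28:29, 1]), mean(pts[28:29, 2]))
        dx <- pts[, 1] - pivot[1]
        dy <- pts[, 2] - pivot[2]
        pts[, 1] <- pivot[1] + cos(phi) * dx - sin(phi) * dy
        pts[, 2] <- pivot[2] + sin(phi) * dx + cos(phi) * dy
      }
      pts[, 1] <- pts[, 1] + x0 + x_shift
      pts[, 2] <- pts[, 2] + y_top
      x[t_global, ] <- pts[, 1] + rnorm(33, 0, p$noise_std)
      y[t_global, ] <- pts[, 2] + rnorm(33, 0, p$noise_std)
      conf[t_global, ] <- 1
      label[t_global] <- lab
    }
  }
  if (p$occlusion_rate > 0) {
    drop <- matrix(runif(n_total * 33) < p$occlusion_rate, n_total, 33L)
    miss[drop] <- TRUE
    x[drop] <- NA_real_; y[drop] <- NA_real_; conf[drop] <- 0
  }
  clip <- skeleton_clip(clip_id, x, y, conf, missing = miss, label = label,
                        image_size = p$image_size, source = "synthetic")
  # head box from the (noise-free) head landmark cluster: height = H/8 so
  # the Vitruvian body box bw = 8*fh recovers the body height
  clip$head_track <- head_track_from_clip(clip, p)
  clip
}

# axis-aligned head box per frame, fitted to the head landmark cluster
head_track_from_clip <- function(clip, p) {
  fh <- p$body_height_px / 8
  fw <- 0.8 * fh
  n <- n_frames(clip)
  cx <- cy <- numeric(n)
  for (i in seq_len(n)) {
    ok <- !clip$missing[i, head_rows]
    if (!any(ok)) { cx[i] <- NA; cy[i] <- NA; next }
    cx[i] <- mean(clip$x[i, head_rows][ok])
    # head landmarks sit ~0.085*H below the crown; place the box so its
    # vertical centre matches the anatomical head centre
    cy[i] <- mean(clip$y[i, head_rows][ok]) - 0.085 * p$body_height_px +
      fh / 2
  }
  data.frame(frame_index = clip$frame_index,
             fx = cx - fw / 2, fy = cy - fh / 2, fw = fw, fh = fh)
}

#' Simulate one labeled activity clip
#'
#' Kinematic templates per activity: standing is a stationary skeleton with
#' Gaussian jitter; walking translates horizontally with sinusoidal limb
#' and shoulder sway; sitting descends the hips by `sit_drop` over about a
#' second with an upright torso; falling rotates the body about the feet
#' toward horizontal over `fall_duration` frames (torso angle from vertical
#' reaching 85 degrees) with a rapid drop of all torso landmarks. A fall is
#' scripted to complete shortly before the clip ends; frames before the
#' sitting/falling onset are labeled `standing`. Each clip carries a
#' consistent per-frame head-box track in `$head_track`. Deterministic for
#' a given seed.
#'
#' @param activity One of [activity_levels].
#' @param n_frames Clip length; for falling clips must be at least
#'   `fall_duration + 15`.
#' @param p A [motion_params].
#' @param clip_id Clip identifier.
#' @param x0 Horizontal start position of the body centre, px.
#' @return A `skeleton_clip` with per-frame labels and a `head_track`
#'   data.frame (`frame_index, fx, fy, fw, fh`).
#' @export
simulate_clip <- function(activity, n_frames = 90L, p = motion_params(),
                          clip_id = paste0(activity, "_1"), x0 = 700) {
  if (!activity %in% activity_levels)
    stop("invalid activity: ", activity)
  segs <- switch(activity,
    standing = list(list(activity = "standing", n = n_frames)),
    walking = list(list(activity = "walking", n = n_frames)),
    sitting = list(list(activity = "sitting", n = n_frames, onset = 6L)),
    falling = {
      if (n_frames < p$fall_duration + 15L)
        stop("falling clips need at least fall_duration + 15 frames")
      # the fall completes ~10 frames before the clip ends, so every
      # window ending after onset still overlaps the descent
      list(list(activity = "falling", n = n_frames,
                onset = as.integer(n_frames - p$fall_duration - 10L)))
    })
  build_motion(segs, p, clip_id = clip_id, x0 = x0, rng_seed = p$seed)
}

#' Simulate a stand-walk-fall transition clip
#'
#' Concatenates activity segments with continuous position, for streaming
#' annotation tests: the subject stands, walks, then falls at the start of
#' the falling segment.
#'
#' @param phases Named integer vector of segment lengths in frames, names
#'   drawn from [activity_levels].
#' @param p A [motion_params].
#' @param clip_id Clip identifier.
#' @param x0 Horizontal start position, px.
#' @return A `skeleton_clip` with `$head_track`.
#' @export
simulate_transition_clip <- function(phases = c(standing = 40, walking = 50,
                                                falling = 25),
                                     p = motion_params(),
                                     clip_id = "transition_1", x0 = 500) {
  segs <- lapply(seq_along(phases), function(i)
    list(activity = names(phases)[i], n = as.integer(phases[i]), onset = 1L))
  build_motion(segs, p, clip_id = clip_id, x0 = x0, rng_seed = p$seed)
}

#' Generate a labeled corpus
#'
#' `n_clips_per_class` clips of each of the four activities, plus (by
#' default) the same number of mixed-activity sequence clips
#' (stand-walk-fall and stand-sit, alternating) that emulate the
#' continuous videos such corpora are cut from — so activity transitions
#' occur in training with per-frame labels. Per-clip seeds, start
#' positions and body heights are derived deterministically from the
#' master seed.
#'
#' @param n_clips_per_class Clips per activity.
#' @param n_frames Frames per clip.
#' @param p A [motion_params]; `p$seed` is the master seed.
#' @param include_transitions Also generate mixed-activity sequence clips.
#' @return List of `skeleton_clip`.
#' @export
generate_dataset <- function(n_clips_per_class = 10L, n_frames = 90L,
                             p = motion_params(),
                             include_transitions = TRUE) {
  if (n_clips_per_class < 1L) stop("need at least one clip per class")
  set.seed(p$seed)
  n_tr <- if (include_transitions) n_clips_per_class else 0L
  total <- 4L * n_clips_per_class + n_tr
  seeds <- sample.int(.Machine$integer.max - 1L, total)
  x0s <- runif(total, 450, 900)
  hts <- runif(total, 0.9, 1.1) * p$body_height_px
  leads <- sample(20:35, total, replace = TRUE)
  clips <- vector("list", total)
  k <- 0L
  for (act in activity_levels) {
    for (i in seq_len(n_clips_per_class)) {
      k <- k + 1L
      pk <- p
      pk$seed <- seeds[k]
      pk$body_height_px <- hts[k]
      clips[[k]] <- simulate_clip(act, n_frames, pk,
                                  clip_id = sprintf("%s_%03d", act, i),
                                  x0 = x0s[k])
    }
  }
  for (i in seq_len(n_tr)) {
    k <- k + 1L
    pk <- p
    pk$seed <- seeds[k]
    pk$body_height_px <- hts[k]
    lead <- leads[k]
    phases <- if (i %% 2L == 1L) {
      # lying tails of varied length, so windows of a subject already down
      # occur in training and keep the falling label
      fall_len <- as.integer(p$fall_duration + sample(5:35, 1))
      c(standing = lead, walking = max(n_frames - lead - fall_len, 20L),
        falling = fall_len)
    } else {
      c(standing = lead, sitting = max(n_frames - lead, 40L))
    }
    clips[[k]] <- simulate_transition_clip(
      phases, pk, clip_id = sprintf("sequence_%03d", i), x0 = x0s[k])
  }
  clips
}

#' Inject coordinate spikes with a ground-truth mask
#'
#' Replaces a `rate` fraction of the torso coordinate slots (8 series x
#' n_frames) with spikes of `+/- magnitude_px`, returning the corrupted
#' clip and the truth mask so cleaning recovery can be scored.
#'
#' @param clip A `skeleton_clip`.
#' @param rate Fraction of torso coordinate slots to corrupt, in \[0, 1).
#' @param magnitude_px Spike magnitude in px.
#' @param seed Integer seed.
#' @return List with `clip` (corrupted) and `mask` (`n_frames x 8` logical,
#'   columns in the torso feature order).
#' @export
inject_outliers <- function(clip, rate, magnitude_px = 500, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  n <- n_frames(clip)
  mask <- matrix(FALSE, n, 8L)
  if (rate > 0) {
    set.seed(seed)
    n_hit <- round(rate * 8L * n)
    hit <- sample.int(8L * n, n_hit)
    mask[hit] <- TRUE
    signs <- sample(c(-1, 1), n_hit, replace = TRUE)
    ids <- torso_ids()
    for (h in seq_along(hit)) {
      row <- (hit[h] - 1L) %% n + 1L
      col <- (hit[h] - 1L) %/% n + 1L
      lm <- ids[ceiling(col / 2)]
      axis <- if (col %% 2L == 1L) "x" else "y"
      clip[[axis]][row, lm] <- clip[[axis]][row, lm] +
        signs[h] * magnitude_px
    }
  }
  list(clip = clip, mask = mask)
}

#' Delayed-cue sequences for long-dependence experiments
#'
#' Generates fixed-length 8-channel feature sequences whose class is
#' determined solely by a brief cue at the start of the sequence: class k
#' offsets channel pair (2k-1, 2k) during the first `cue_len` frames, after
#' which every class follows the same stationary noise process. With
#' `W = 120` and `cue_len = 15` the decisive information lies more than
#' 100 frames before the window end, so only a model that can carry state
#' across long gaps can classify them — the setting in which an LSTM
#' separates from a plain recurrent network.
#'
#' @param n_per_class Sequences per class.
#' @param W Sequence length in frames.
#' @param cue_len Cue duration in frames.
#' @param cue_strength Offset added to the cued channel pair.
#' @param noise_std Standard deviation of the per-frame noise.
#' @param seed Integer seed.
#' @return List with `x` (`W x 8 x n` array) and `y` (factor over
#'   [activity_levels], one class per cue pattern).
#' @export
simulate_delayed_cue <- function(n_per_class = 60L, W = 120L, cue_len = 15L,
                                 cue_strength = 0.3, noise_std = 0.02,
                                 seed = 1L) {
  stopifnot(W > cue_len)
  set.seed(seed)
  n <- 4L * n_per_class
  x <- array(NA_real_, c(W, 8L, n))
  y <- factor(rep(activity_levels, each = n_per_class),
              levels = activity_levels)
  tt <- seq_len(W)
  for (s in seq_len(n)) {
    # zero-mean (standardized) channels: a constant per-sequence offset
    # would integrate into the cell state over the long gap and saturate
    # it, turning a memory task into a drift task
    seq8 <- matrix(rnorm(W * 8L, 0, noise_std), W, 8L)
    # information-free sinusoidal distractors on every channel: without
    # them the post-cue input is near-silent and even a plain recurrent
    # network can hold the cue in a fixed-point attractor
    for (j in 1:8)
      seq8[, j] <- seq8[, j] + runif(1, 0.1, 0.3) *
        sin(2 * pi * runif(1, 0.02, 0.2) * tt + runif(1, 0, 2 * pi))
    k <- as.integer(y[s])
    seq8[seq_len(cue_len), c(2 * k - 1, 2 * k)] <-
      seq8[seq_len(cue_len), c(2 * k - 1, 2 * k)] + cue_strength
    x[, , s] <- seq8
  }
  ord <- sample.int(n)
  list(x = x[, , ord, drop = FALSE], y = y[ord])
}
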