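#' Normalize a torso feature vector to image-relative units
#'
#' Divides x-coordinates by image width and y-coordinates by image height,
#' mapping in-frame points into \[0, 1\] so the classifier sees
#' resolution-independent inputs.
#'
#' @param features Length-8 vector or `n x 8` matrix in the fixed torso
#'   order `(LSx, LSy, RSx, RSy, LHx, LHy, RHx, RHy)`.
#' @param image_size Numeric `(width, height)` in px, both positive.
#' @return Same shape as `features`, unitless.
#' @export
normalize_frame <- function(features, image_size) {
  if (any(image_size <= 0)) stop("image dimensions must be positive")
  scale <- rep(c(1 / image_size[1], 1 / image_size[2]), 4)
  if (is.matrix(features)) sweep(features, 2, scale, `*`)
  else features * scale
}

#' Cut a clip into fixed-length labeled feature windows
#'
#' Slides a window of `W` frames at the given stride over the clip's
#' normalized torso features. Each window is labeled from its last frame
#' by default (a fall alarm should reflect the window's end state);
#' majority vote over the window is available instead. A clip shorter than
#' `W` yields an empty list, not an error.
#'
#' @param clip A `skeleton_clip` (cleaned: torso features must be finite).
#' @param W Window length in frames (default 30, about 1 s at 30 fps).
#' @param stride Hop between consecutive windows in frames.
#' @param labeling `"last"` or `"majority"`.
#' @return List of `motion_window` objects, each with a `W x 8` feature
#'   matrix, `label`, `clip_id` and `start_frame` (1-based row in the clip).
#' @export
build_windows <- function(clip, W = 30L, stride = 1L,
                          labeling = c("last", "majority")) {
  labeling <- match.arg(labeling)
  n <- n_frames(clip)
  if (n < W) return(list())
  feat <- normalize_frame(torso_features(clip), clip$image_size)
  if (anyNA(feat))
    stop("window features must be finite; clean the clip first")
  starts <- seq.int(1L, n - W + 1L, by = stride)
  lapply(starts, function(s) {
    rows <- s:(s + W - 1L)
    lab <- if (labeling == "last") clip$label[rows[W]]
    else names(which.max(table(factor(clip$label[rows],
                                      levels = activity_levels))))
    structure(list(features = feat[rows, , drop = FALSE],
                   label = lab, clip_id = clip$clip_id,
                   start_frame = as.integer(s)),
              class = "motion_window")
  })
}

#' Stack motion windows into a training array
#'
#' @param windows List of `motion_window`.
#' @return List with `x` (array `W x 8 x n`) and `y` (factor of labels with
#'   levels [activity_levels]).
#' @export
windows_to_array <- function(windows) {
  if (!length(windows)) stop("no windows supplied")
  W <- nrow(windows[[1]]$features)
  x <- array(NA_real_, c(W, 8L, length(windows)))
  for (i in seq_along(windows)) x[, , i] <- windows[[i]]$features
  y <- factor(vapply(windows, function(w) w$label, ""),
              levels = activity_levels)
  list(x = x, y = y,
       clip_id = vapply(windows, function(w) w$clip_id, ""))
}
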