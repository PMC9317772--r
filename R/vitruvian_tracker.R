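#' Head bounding box
#'
#' Axis-aligned head detection in pixel coordinates: `(fx, fy)` is the
#' top-left corner, `(fw, fh)` width and height.
#'
#' @param fx,fy Left and top edge in px.
#' @param fw,fh Width and height in px; both must be positive.
#' @return An object of class `head_box`.
#' @export
head_box <- function(fx, fy, fw, fh) {
  if (fw <= 0 || fh <= 0) stop("head box width and height must be positive")
  structure(list(fx = fx, fy = fy, fw = fw, fh = fh), class = "head_box")
}

#' Tracker configuration
#'
#' @param ratio Head-height to body-height ratio. The classical Vitruvian
#'   canon puts the head at roughly 1/7.5 of standing height; the default 8
#'   rounds this up to accommodate body-type variation.
#' @param conf_threshold Torso keypoints below this confidence are excluded
#'   from the tracking centroid; mean torso confidence below it triggers
#'   re-detection.
#' @param max_jump_frac A frame-to-frame centroid jump larger than this
#'   fraction of the box width triggers re-detection.
#' @param redetect_every Force a head re-detection every this many frames;
#'   0 disables periodic re-detection.
#' @return An object of class `tracker_config`.
#' @export
tracker_config <- function(ratio = 8, conf_threshold = 0.5,
                           max_jump_frac = 0.5, redetect_every = 0L) {
  if (ratio <= 0) stop("ratio must be positive")
  if (max_jump_frac <= 0) stop("max_jump_frac must be positive")
  structure(list(ratio = ratio, conf_threshold = conf_threshold,
                 max_jump_frac = max_jump_frac,
                 redetect_every = as.integer(redetect_every)),
            class = "tracker_config")
}

#' Derive the body bounding box from a head box and hip midpoint
#'
#' Vitruvian proportion geometry: the body occupies a square of side
#' `ratio * fh` whose top edge is the head-box top and whose horizontal
#' centre is the head-box centre,
#' \deqn{b_x = f_x + 0.5 f_w - (r/2) f_h,\quad b_y = f_y,\quad
#'       b_w = b_h = r\, f_h,}
#' with rotation angle
#' \deqn{\theta = \arctan\frac{h_x - (f_x + 0.5 f_w)}{h_y - (f_y + 0.5 f_h)}}
#' measured from the downward vertical of the head-centre-to-hip axis
#' (positive when the hips are displaced toward +x). The two-argument
#' arctangent is used so that a horizontal (fallen) body yields
#' \eqn{|\theta| \to \pi/2} instead of a division error.
#'
#' @param head A [head_box] (or numeric `c(fx, fy, fw, fh)`).
#' @param hip Numeric `(hx, hy)` hip midpoint in px.
#' @param ratio Head-to-body ratio (default 8).
#' @return An object of class `body_box`: `bx, by, bw, bh, theta` with
#'   `bw == bh` and `theta` in radians.
#' @export
body_box_from_head <- function(head, hip, ratio = 8) {
  if (!inherits(head, "head_box")) head <- do.call(head_box, as.list(head))
  if (any(!is.finite(unlist(hip)))) stop("hip midpoint must be finite")
  cx <- head$fx + 0.5 * head$fw
  cy <- head$fy + 0.5 * head$fh
  dx <- hip[[1]] - cx
  dy <- hip[[2]] - cy
  if (dx == 0 && dy == 0)
    stop("geometry error: hip midpoint coincides with head centre")
  structure(list(bx = cx - (ratio / 2) * head$fh,
                 by = head$fy,
                 bw = ratio * head$fh,
                 bh = ratio * head$fh,
                 theta = atan2(dx, dy)),
            class = "body_box")
}

#' @export
print.body_box <- function(x, ...) {
  cat(sprintf("<body_box> (%.1f, %.1f) %gx%g px, theta=%.3f rad\n",
              x$bx, x$by, x$bw, x$bh, x$theta))
  invisible(x)
}

#' Confidence-weighted torso centroid of a frame
#'
#' Reference point for the offset vector: the confidence-weighted mean of
#' the four torso keypoints (shoulders and hips) whose confidence is at
#' least `conf_threshold`. Returns `NULL` ("missing") when fewer than two
#' qualify.
#'
#' @param clip A `skeleton_clip`.
#' @param frame 1-based frame row.
#' @param conf_threshold Minimum keypoint confidence.
#' @return Numeric `(x, y)` or `NULL`.
#' @export
torso_centroid <- function(clip, frame, conf_threshold = 0.5) {
  ids <- torso_ids()
  w <- clip$conf[frame, ids]
  keep <- !clip$missing[frame, ids] & w >= conf_threshold
  if (sum(keep) < 2L) return(NULL)
  w <- w[keep]
  c(x = sum(clip$x[frame, ids][keep] * w) / sum(w),
    y = sum(clip$y[frame, ids][keep] * w) / sum(w))
}

#' Frame-to-frame offset vector
#'
#' Displacement of the torso centroid between two frames, used to translate
#' the body box without re-running the head detector. `NULL` when either
#' centroid is missing.
#'
#' @param clip A `skeleton_clip`.
#' @param prev,cur 1-based frame rows.
#' @param cfg A [tracker_config].
#' @return Numeric `(dx, dy)` or `NULL`.
#' @export
offset_vector <- function(clip, prev, cur, cfg = tracker_config()) {
  a <- torso_centroid(clip, prev, cfg$conf_threshold)
  b <- torso_centroid(clip, cur, cfg$conf_threshold)
  if (is.null(a) || is.null(b)) return(NULL)
  c(dx = unname(b[1] - a[1]), dy = unname(b[2] - a[2]))
}

#' Translate a body box by an offset vector
#'
#' Shifts the box so the tracked subject stays centred; size and rotation
#' are unchanged (the angle is refreshed separately from the torso axis
#' when keypoints allow, see [track_clip()]).
#'
#' @param box A `body_box`.
#' @param offset Numeric `(dx, dy)`.
#' @return The translated `body_box`.
#' @export
update_box <- function(box, offset) {
  if (any(!is.finite(unlist(offset)))) stop("offset must be finite")
  box$bx <- box$bx + offset[[1]]
  box$by <- box$by + offset[[2]]
  box
}

#' Should the head detector be re-run for this frame?
#'
#' True when tracking has degraded: the torso centroid is missing, mean
#' torso confidence falls below `conf_threshold`, the centroid jumped more
#' than `max_jump_frac * bw` in one frame, or a periodic re-detection is
#' due (`redetect_every`).
#'
#' @param clip A `skeleton_clip`.
#' @param frame 1-based frame row.
#' @param box Current `body_box`.
#' @param cfg A [tracker_config].
#' @param last_offset Most recent offset vector, or `NULL`.
#' @return Logical scalar.
#' @export
needs_redetection <- function(clip, frame, box, cfg = tracker_config(),
                              last_offset = NULL) {
  if (is.null(torso_centroid(clip, frame, cfg$conf_threshold))) return(TRUE)
  ids <- torso_ids()
  w <- clip$conf[frame, ids]
  w[clip$missing[frame, ids]] <- 0
  if (mean(w) < cfg$conf_threshold) return(TRUE)
  if (!is.null(last_offset) &&
      sqrt(sum(unlist(last_offset)^2)) > cfg$max_jump_frac * box$bw)
    return(TRUE)
  if (cfg$redetect_every > 0L &&
      clip$frame_index[frame] %% cfg$redetect_every == 0L)
    return(TRUE)
  FALSE
}

# rotation angle of the shoulder-centre -> hip-centre axis from downward
# vertical; used to refresh theta while coasting (no head box available)
torso_axis_angle <- function(clip, frame) {
  ids <- torso_ids()
  miss <- clip$missing[frame, ids]
  if (any(miss)) return(NA_real_)
  sx <- mean(clip$x[frame, ids[1:2]]); sy <- mean(clip$y[frame, ids[1:2]])
  hx <- mean(clip$x[frame, ids[3:4]]); hy <- mean(clip$y[frame, ids[3:4]])
  if (hx == sx && hy == sy) return(NA_real_)
  atan2(hx - sx, hy - sy)
}

#' Track the body box across a clip
#'
#' Frame 0: the head detector (`head_source`) is invoked and the body box
#' derived with [body_box_from_head()]. Subsequent frames: the box is
#' translated by the torso-centroid offset vector, so the detector is not
#' re-run while tracking is healthy; [needs_redetection()] decides when to
#' re-invoke it. While coasting, the rotation angle is refreshed from the
#' shoulder-centre-to-hip-centre axis. If the detector fails mid-clip the
#' box coasts on the last offset and re-detection is retried next frame.
#'
#' @param clip A `skeleton_clip`.
#' @param head_source Function `(frame_row) -> head_box` (or anything
#'   [body_box_from_head()] accepts); may throw to signal detector failure.
#' @param cfg A [tracker_config].
#' @return A `data.frame` with one row per frame: `frame_index`, box
#'   geometry (`bx, by, bw, bh, theta`) and a `redetected` flag, so callers
#'   can count detector activations.
#' @export
track_clip <- function(clip, head_source, cfg = tracker_config()) {
  n <- n_frames(clip)
  if (n < 1L) stop("tracking error: empty clip")
  redetect <- function(i, prev_theta = NULL) {
    hb <- head_source(i)
    if (!inherits(hb, "head_box")) hb <- do.call(head_box, as.list(hb))
    hip <- tryCatch(hip_midpoint(clip, i), error = function(e) NULL)
    if (!is.null(hip)) return(body_box_from_head(hb, hip, cfg$ratio))
    # hips unavailable: re-derive the geometry from the head alone and
    # carry the last known rotation angle
    structure(list(bx = hb$fx + 0.5 * hb$fw - (cfg$ratio / 2) * hb$fh,
                   by = hb$fy, bw = cfg$ratio * hb$fh,
                   bh = cfg$ratio * hb$fh,
                   theta = prev_theta %||% 0),
              class = "body_box")
  }
  box <- tryCatch(redetect(1L), error = function(e)
    stop("tracking error: head detection failed on first frame: ",
         conditionMessage(e)))
  out <- data.frame(frame_index = clip$frame_index,
                    bx = NA_real_, by = NA_real_, bw = NA_real_,
                    bh = NA_real_, theta = NA_real_, redetected = FALSE)
  put <- function(i, box, flag) {
    out[i, 2:6] <<- c(box$bx, box$by, box$bw, box$bh, box$theta)
    out$redetected[i] <<- flag
  }
  put(1L, box, TRUE)
  last_offset <- c(0, 0)
  for (i in 2:max(n, 2L)) {
    if (n < 2L) break
    off <- offset_vector(clip, i - 1L, i, cfg)
    coast_off <- if (is.null(off)) last_offset else off
    if (needs_redetection(clip, i, box, cfg, off)) {
      newbox <- tryCatch(redetect(i, box$theta), error = function(e) NULL)
      if (!is.null(newbox)) {
        box <- newbox
        put(i, box, TRUE)
        last_offset <- c(0, 0)
        next
      }
      # detector failed: defer re-detection, coast on last offset
      off <- NULL
      coast_off <- last_offset
    }
    box <- update_box(box, coast_off)
    ang <- torso_axis_angle(clip, i)
    if (!is.na(ang)) box$theta <- ang
    put(i, box, FALSE)
    if (!is.null(off)) last_offset <- off
  }
  out
}
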