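#' @importFrom stats quantile runif rnorm approx sd
#' @importFrom utils head tail
NULL

#' The four activity classes
#'
#' Class labels recognised by the classifier, in fixed index order. The
#' order defines the class index used for tie-breaking in [lstm_predict()]
#' and the row/column order of confusion matrices.
#'
#' @format Character vector of length 4.
#' @export
activity_levels <- c("walking", "standing", "sitting", "falling")

#' Two-letter display codes for the activity classes
#'
#' `WK` walking, `SD` standing, `ST` sitting, `FL` falling — the codes used
#' by [annotate_stream()] for per-frame overlay labels.
#'
#' @format Named character vector mapping class name to code.
#' @export
activity_codes <- c(walking = "WK", standing = "SD", sitting = "ST", falling = "FL")

#' 33-landmark pose topology
#'
#' Named 0-based landmark indices of the 33-point full-body pose topology
#' used throughout the package. Only the head region (indices 0--10),
#' shoulders (11, 12) and hips (23, 24) are semantically required by the
#' pipeline; the rest are carried through untouched.
#'
#' @format Named integer vector of length 33; values are 0-based landmark ids.
#' @export
pose_landmarks <- c(
  nose = 0L,
  left_eye_inner = 1L, left_eye = 2L, left_eye_outer = 3L,
  right_eye_inner = 4L, right_eye = 5L, right_eye_outer = 6L,
  left_ear = 7L, right_ear = 8L,
  mouth_left = 9L, mouth_right = 10L,
  left_shoulder = 11L, right_shoulder = 12L,
  left_elbow = 13L, right_elbow = 14L,
  left_wrist = 15L, right_wrist = 16L,
  left_pinky = 17L, right_pinky = 18L,
  left_index = 19L, right_index = 20L,
  left_thumb = 21L, right_thumb = 22L,
  left_hip = 23L, right_hip = 24L,
  left_knee = 25L, right_knee = 26L,
  left_ankle = 27L, right_ankle = 28L,
  left_heel = 29L, right_heel = 30L,
  left_foot_index = 31L, right_foot_index = 32L
)

# 1-based column indices of the four torso landmarks, fixed feature order:
# (LSx, LSy, RSx, RSy, LHx, LHy, RHx, RHy)
torso_ids <- function() {
  unname(pose_landmarks[c("left_shoulder", "right_shoulder",
                          "left_hip", "right_hip")]) + 1L
}

#' Construct a skeleton clip
#'
#' A clip holds the per-frame 33-landmark keypoint record of a single
#' subject: pixel coordinates (origin top-left, x rightward, y downward),
#' per-keypoint confidences in \[0, 1\], an explicit per-keypoint missing
#' flag, per-frame activity labels, and the image size. Missing keypoints
#' are flagged, never encoded as sentinel coordinates, so downstream
#' cleaning can distinguish "outlier removed" from "never observed".
#'
#' @param clip_id Character scalar identifying the clip.
#' @param x,y Numeric `n_frames x 33` matrices of pixel coordinates.
#' @param conf Numeric `n_frames x 33` matrix of confidences in \[0, 1\].
#' @param missing Logical `n_frames x 33` matrix; defaults to non-finite
#'   coordinates.
#' @param frame_index Integer vector of frame indices, strictly increasing;
#'   defaults to `0:(n_frames - 1)`.
#' @param label Character vector of per-frame activity labels (one of
#'   [activity_levels]) or `NA`; recycled if scalar.
#' @param image_size Numeric length-2 `(width, height)` in pixels.
#' @param source Provenance tag, one of `"self_made"`, `"urfall"`, `"fdd"`,
#'   `"synthetic"`.
#' @return An object of class `skeleton_clip`.
#' @export
skeleton_clip <- function(clip_id, x, y, conf, missing = NULL,
                          frame_index = NULL, label = NA_character_,
                          image_size = c(1920, 1080), source = "synthetic") {
  x <- as.matrix(x); y <- as.matrix(y); conf <- as.matrix(conf)
  n <- nrow(x)
  if (n < 1L) stop("clip must contain at least one frame")
  if (ncol(x) != 33L || ncol(y) != 33L || ncol(conf) != 33L)
    stop("schema error: a frame must carry exactly 33 keypoints, got ",
         ncol(x))
  if (is.null(missing)) missing <- !(is.finite(x) & is.finite(y))
  missing <- as.matrix(missing)
  if (is.null(frame_index)) frame_index <- seq_len(n) - 1L
  frame_index <- as.integer(frame_index)
  if (any(frame_index < 0L)) stop("frame_index must be non-negative")
  if (n > 1L && any(diff(frame_index) <= 0L))
    stop("frame_index must be strictly increasing within a clip")
  label <- rep_len(as.character(label), n)
  bad <- !is.na(label) & !(label %in% activity_levels)
  if (any(bad))
    stop("unknown activity label: ", paste(unique(label[bad]), collapse = ", "))
  cr <- conf[!missing]
  if (length(cr) && (any(!is.finite(cr)) || any(cr < 0) || any(cr > 1)))
    stop("confidence must lie in [0, 1]")
  if (any(!is.finite(x[!missing])) || any(!is.finite(y[!missing])))
    stop("non-missing coordinates must be finite")
  if (length(image_size) != 2L || any(image_size <= 0))
    stop("image_size must be positive (width, height)")
  source <- match.arg(source, c("self_made", "urfall", "fdd", "synthetic"))
  structure(list(clip_id = as.character(clip_id), x = x, y = y, conf = conf,
                 missing = missing, frame_index = frame_index, label = label,
                 image_size = as.numeric(image_size), source = source),
            class = "skeleton_clip")
}

#' @export
print.skeleton_clip <- function(x, ...) {
  cat(sprintf("<skeleton_clip '%s'> %d frames, %dx%d px, source=%s\n",
              x$clip_id, n_frames(x), x$image_size[1], x$image_size[2],
              x$source))
  labs <- unique(x$label[!is.na(x$label)])
  if (length(labs)) cat("  labels:", paste(labs, collapse = ", "), "\n")
  invisible(x)
}

#' Number of frames in a clip
#' @param clip A `skeleton_clip`.
#' @return Integer frame count.
#' @export
n_frames <- function(clip) nrow(clip$x)

#' Hip midpoint of a frame
#'
#' Component-wise mean of the left-hip and right-hip keypoints — the body
#' reference point `(hx, hy)` used to derive the body box rotation angle.
#'
#' @param clip A `skeleton_clip`.
#' @param frame 1-based frame row; if `NULL`, returns an `n x 2` matrix for
#'   the whole clip with `NA` rows where either hip is unavailable.
#' @return Numeric `(hx, hy)` or an `n x 2` matrix.
#' @export
hip_midpoint <- function(clip, frame = NULL) {
  lh <- unname(pose_landmarks["left_hip"]) + 1L
  rh <- unname(pose_landmarks["right_hip"]) + 1L
  ok <- !clip$missing[, lh] & !clip$missing[, rh] &
    clip$conf[, lh] > 0 & clip$conf[, rh] > 0
  hx <- (clip$x[, lh] + clip$x[, rh]) / 2
  hy <- (clip$y[, lh] + clip$y[, rh]) / 2
  if (is.null(frame)) {
    hx[!ok] <- NA_real_; hy[!ok] <- NA_real_
    return(cbind(hx = hx, hy = hy))
  }
  if (!ok[frame])
    stop("missing landmark: both hips must be present with confidence > 0")
  c(hx = hx[frame], hy = hy[frame])
}

#' Torso feature vector of a frame
#'
#' Projects a frame onto the four low-freedom torso landmarks in the fixed
#' order `(LSx, LSy, RSx, RSy, LHx, LHy, RHx, RHy)` — the 8-dimensional
#' per-frame feature consumed by the sequence classifier. The ordering is
#' fixed by landmark id, not by storage order in the input file.
#'
#' @param clip A `skeleton_clip`.
#' @param frame 1-based frame row; if `NULL`, returns an `n x 8` matrix
#'   with `NA` entries for missing torso keypoints.
#' @return Numeric length-8 vector, or an `n x 8` matrix.
#' @export
torso_features <- function(clip, frame = NULL) {
  ids <- torso_ids()
  xs <- clip$x[, ids, drop = FALSE]
  ys <- clip$y[, ids, drop = FALSE]
  miss <- clip$missing[, ids, drop = FALSE]
  xs[miss] <- NA_real_; ys[miss] <- NA_real_
  feat <- cbind(xs[, 1], ys[, 1], xs[, 2], ys[, 2],
                xs[, 3], ys[, 3], xs[, 4], ys[, 4])
  colnames(feat) <- c("LSx", "LSy", "RSx", "RSy", "LHx", "LHy", "RHx", "RHy")
  if (is.null(frame)) return(feat)
  v <- feat[frame, ]
  if (anyNA(v))
    stop("missing landmark: all four torso keypoints must be present")
  v
}

# ---- I/O ------------------------------------------------------------------

# full-precision decimal encoding so CSV round-trips bit-exactly
fmt_num <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))

#' Write keypoint records
#'
#' Serialises clips to the package's long CSV schema (one row per keypoint:
#' `clip_id, frame_index, landmark_id, x, y, confidence, label, image_w,
#' image_h`) or to JSON-lines (one frame object per line with a 33-element
#' keypoint array). Missing keypoints are written with empty coordinate
#' fields (CSV) or `null` (JSONL). Numeric values are written with 17
#' significant digits so finite values round-trip bit-exactly.
#'
#' @param clips A `skeleton_clip` or list of them.
#' @param path Output file path.
#' @param dialect `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_keypoint_records <- function(clips, path, dialect = c("csv", "jsonl")) {
  dialect <- match.arg(dialect)
  if (inherits(clips, "skeleton_clip")) clips <- list(clips)
  if (dialect == "csv") {
    tabs <- lapply(clips, function(cl) {
      n <- n_frames(cl)
      data.table::data.table(
        clip_id = rep(cl$clip_id, n * 33L),
        frame_index = rep(cl$frame_index, each = 33L),
        landmark_id = rep(0:32, times = n),
        x = fmt_num(as.vector(ifelse(t(cl$missing), NA_real_, t(cl$x)))),
        y = fmt_num(as.vector(ifelse(t(cl$missing), NA_real_, t(cl$y)))),
        confidence = fmt_num(as.vector(t(cl$conf))),
        label = rep(ifelse(is.na(cl$label), "", cl$label), each = 33L),
        image_w = rep(fmt_num(cl$image_size[1]), n * 33L),
        image_h = rep(fmt_num(cl$image_size[2]), n * 33L))
    })
    data.table::fwrite(data.table::rbindlist(tabs), path, quote = FALSE)
  } else {
    con <- file(path, open = "wt")
    on.exit(close(con))
    jstr <- function(s) as.character(jsonlite::toJSON(s, auto_unbox = TRUE))
    for (cl in clips) {
      for (i in seq_len(n_frames(cl))) {
        # numbers written at 17 significant digits by hand: generic JSON
        # serialisers truncate to 15 and break the bit-exact round trip
        kps <- vapply(1:33, function(j) {
          if (cl$missing[i, j]) "null"
          else sprintf("[%.17g,%.17g,%.17g]",
                       cl$x[i, j], cl$y[i, j], cl$conf[i, j])
        }, "")
        writeLines(sprintf(
          '{"clip_id":%s,"frame_index":%d,"image_w":%.17g,"image_h":%.17g,"label":%s,"source":%s,"keypoints":[%s]}',
          jstr(cl$clip_id), cl$frame_index[i],
          cl$image_size[1], cl$image_size[2],
          if (is.na(cl$label[i])) "null" else jstr(cl$label[i]),
          jstr(cl$source), paste(kps, collapse = ",")), con)
      }
    }
  }
  invisible(path)
}

#' Read keypoint records
#'
#' Parses the CSV or JSON-lines schema written by [write_keypoint_records()]
#' into a list of [skeleton_clip] objects, grouped by `clip_id` and ordered
#' by `frame_index`. An empty file yields an empty list. A frame that does
#' not carry exactly 33 keypoints is a schema error; a malformed row is a
#' parse error naming the offending line.
#'
#' @param path Input file path.
#' @param dialect `"csv"` or `"jsonl"`.
#' @param source Provenance tag attached to the clips (CSV carries none).
#' @return List of `skeleton_clip`.
#' @export
read_keypoint_records <- function(path, dialect = c("csv", "jsonl"),
                                  source = "synthetic") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "csv") {
    # base strtod parsing: correctly rounded, so 17-digit decimals
    # round-trip bit-exactly (fast float parsers can be several ulp off)
    dt <- tryCatch(
      utils::read.csv(path, colClasses = c(
        clip_id = "character", frame_index = "integer",
        landmark_id = "integer", x = "numeric", y = "numeric",
        confidence = "numeric", label = "character",
        image_w = "numeric", image_h = "numeric")),
      error = function(e)
        stop("parse error in ", path, ": ", conditionMessage(e),
             call. = FALSE))
    data.table::setDT(dt)
    if (nrow(dt) == 0L) return(list())
    req <- c("clip_id", "frame_index", "landmark_id", "x", "y",
             "confidence", "label", "image_w", "image_h")
    if (!all(req %in% names(dt)))
      stop("parse error: missing columns ",
           paste(setdiff(req, names(dt)), collapse = ", "))
    bad <- which(!is.finite(dt$confidence) | is.na(dt$landmark_id) |
                   is.na(dt$frame_index))
    if (length(bad))
      stop("parse error at data line ", bad[1],
           ": non-numeric confidence or index")
    clips <- lapply(split(dt, by = "clip_id", sorted = TRUE), clip_from_long)
    return(unname(clips))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(list())
  frames <- lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e)
                      stop("parse error at line ", i, ": ",
                           conditionMessage(e), call. = FALSE))
    if (length(obj$keypoints) != 33L)
      stop("schema error at line ", i, ": frame has ",
           length(obj$keypoints), " keypoints, expected 33")
    obj
  })
  ids <- vapply(frames, function(f) as.character(f$clip_id), "")
  out <- lapply(unique(ids), function(id) {
    fs <- frames[ids == id]
    fs <- fs[order(vapply(fs, function(f) as.integer(f$frame_index), 0L))]
    n <- length(fs)
    x <- y <- conf <- matrix(NA_real_, n, 33L)
    miss <- matrix(TRUE, n, 33L)
    for (i in seq_len(n)) {
      for (j in 1:33) {
        kp <- fs[[i]]$keypoints[[j]]
        if (!is.null(kp)) {
          x[i, j] <- kp[[1]]; y[i, j] <- kp[[2]]; conf[i, j] <- kp[[3]]
          miss[i, j] <- FALSE
        }
      }
    }
    conf[miss] <- 0
    lab <- vapply(fs, function(f)
      if (is.null(f$label)) NA_character_ else as.character(f$label), "")
    src <- if (!is.null(fs[[1]]$source)) fs[[1]]$source else source
    skeleton_clip(id, x, y, conf, missing = miss,
                  frame_index = vapply(fs, function(f)
                    as.integer(f$frame_index), 0L),
                  label = lab,
                  image_size = c(fs[[1]]$image_w, fs[[1]]$image_h),
                  source = src)
  })
  out
}

# assemble one skeleton_clip from long-format rows of a single clip_id
clip_from_long <- function(d) {
  data.table::setorderv(d, c("frame_index", "landmark_id"))
  frames <- unique(d$frame_index)
  cnt <- tabulate(match(d$frame_index, frames))
  if (any(cnt != 33L)) {
    off <- frames[cnt != 33L][1]
    stop("schema error: clip '", d$clip_id[1], "' frame ", off, " has ",
         cnt[match(off, frames)], " keypoints, expected 33")
  }
  n <- length(frames)
  x <- matrix(d$x, n, 33L, byrow = TRUE)
  y <- matrix(d$y, n, 33L, byrow = TRUE)
  conf <- matrix(d$confidence, n, 33L, byrow = TRUE)
  miss <- is.na(x) | is.na(y)
  lab <- d$label[seq(1L, nrow(d), by = 33L)]
  lab[!nzchar(lab) | is.na(lab)] <- NA_character_
  skeleton_clip(d$clip_id[1], x, y, conf, missing = miss,
                frame_index = frames, label = lab,
                image_size = c(d$image_w[1], d$image_h[1]))
}
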