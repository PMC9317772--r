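#' Lower and upper quartiles of a series
#'
#' Linear-interpolation sample quantiles at p = 0.25 and 0.75 (the
#' convention of `stats::quantile(type = 7)`), the quartiles on which the
#' boxplot fences are built.
#'
#' @param values Numeric vector with at least 4 finite values.
#' @return Named numeric `(Q1, Q3)`.
#' @export
series_quartiles <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 4L)
    stop("insufficient data: need at least 4 finite values, got ", length(v))
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
  c(Q1 = q[1], Q3 = q[2])
}

#' Flag boxplot-fence outliers in a series
#'
#' Tukey's rule: values outside `[Q1 - k*IQR, Q3 + k*IQR]` are flagged.
#' Missing (`NA`) values are never flagged as outliers — they are absences,
#' not observations. A constant series has IQR 0 and a zero-width fence
#' that still contains the constant, so nothing is flagged.
#'
#' @param values Numeric vector (may contain `NA` for missing).
#' @param k Fence multiplier; 1.5 is Tukey's default.
#' @return A list of class `series_mask`: `values`, logical `outlier`,
#'   and the fences used.
#' @export
fence_outliers <- function(values, k = 1.5) {
  q <- series_quartiles(values)
  iqr <- q[["Q3"]] - q[["Q1"]]
  lo <- q[["Q1"]] - k * iqr
  hi <- q[["Q3"]] + k * iqr
  out <- !is.na(values) & (values < lo | values > hi)
  structure(list(values = values, outlier = out, lower = lo, upper = hi),
            class = "series_mask")
}

#' Repair flagged and missing positions by linear interpolation
#'
#' Positions that are flagged as outliers or missing are replaced by linear
#' interpolation between the nearest clean neighbours; gaps at the series
#' boundary are filled by nearest-value extension.
#'
#' @param series A `series_mask` from [fence_outliers()], or a numeric
#'   vector (then `flagged` marks the positions to repair).
#' @param flagged Logical vector, used when `series` is a plain vector.
#' @return Numeric vector with all positions finite.
#' @export
interpolate_gaps <- function(series, flagged = NULL) {
  if (inherits(series, "series_mask")) {
    values <- series$values
    flagged <- series$outlier
  } else values <- series
  bad <- flagged | is.na(values)
  if (all(bad)) stop("unrecoverable series: every value flagged or missing")
  if (!any(bad)) return(values)
  idx <- seq_along(values)
  stats::approx(idx[!bad], values[!bad], xout = idx, method = "linear",
                rule = 2)$y
}

# flag outliers with fences computed over sliding windows centred on each
# position (clamped at the boundaries); window NULL = whole series
windowed_outliers <- function(values, k, window = NULL) {
  n <- length(values)
  if (is.null(window) || window >= n) return(fence_outliers(values, k)$outlier)
  if (window < 4L) stop("cleaning window must cover at least 4 frames")
  half <- window %/% 2L
  out <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1L, min(i - half, n - window + 1L))
    seg <- values[lo:(lo + window - 1L)]
    if (sum(is.finite(seg)) < 4L) next
    f <- fence_outliers(seg, k)
    out[i] <- !is.na(values[i]) &&
      (values[i] < f$lower || values[i] > f$upper)
  }
  out
}

#' Boxplot-clean the torso trajectories of a clip
#'
#' Applies fence flagging plus gap interpolation independently to each of
#' the eight torso coordinate series (shoulder and hip x/y) — the series
#' consumed downstream — repairing both fence outliers and missing
#' keypoints (e.g. dropouts while the head detector restarts). Other
#' landmarks pass through untouched. Repaired torso keypoints are marked
#' present with confidence carried over (missing ones get confidence 0
#' replaced by 1 after repair, since the value is now an estimate the
#' pipeline commits to).
#'
#' @param clip A `skeleton_clip` of at least 4 frames.
#' @param k Fence multiplier (default 1.5).
#' @param window Sliding-window length in frames for fence estimation;
#'   `NULL` (default) uses the whole clip.
#' @return The cleaned `skeleton_clip`.
#' @export
clean_clip <- function(clip, k = 1.5, window = NULL) {
  n <- n_frames(clip)
  if (n < 4L) stop("insufficient data: cleaning needs at least 4 frames")
  ids <- torso_ids()
  for (j in ids) {
    for (axis in c("x", "y")) {
      v <- clip[[axis]][, j]
      v[clip$missing[, j]] <- NA_real_
      flag <- windowed_outliers(v, k, window)
      clip[[axis]][, j] <- interpolate_gaps(v, flag)
    }
    repaired <- clip$missing[, j]
    clip$conf[repaired, j] <- 1
    clip$missing[, j] <- FALSE
  }
  clip
}
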