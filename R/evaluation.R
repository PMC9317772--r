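#' Published corpus composition
#'
#' Frame-group counts of the labeled keypoint corpus the method was
#' developed on: a self-recorded set plus re-processed clips from the
#' URFall and FDD public fall datasets. Used for dataset bookkeeping
#' (total count and nominal 7:2:1 partition sizes).
#'
#' @format Named integer vector of frame-group counts per source.
#' @export
reference_corpus_counts <- c(self_made = 3770L, urfall = 2995L, fdd = 4527L)

#' 4-class confusion matrix
#'
#' Rows are true classes, columns predicted, in [activity_levels] order
#' (or the supplied `classes`).
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @param classes Class set.
#' @return Integer matrix `length(classes) x length(classes)` summing to
#'   `length(y_true)`.
#' @export
confusion_matrix <- function(y_true, y_pred, classes = activity_levels) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  bad <- setdiff(unique(c(y_true, y_pred)), classes)
  if (length(bad)) stop("unknown label: ", paste(bad, collapse = ", "))
  tab <- table(factor(y_true, levels = classes),
               factor(y_pred, levels = classes))
  m <- matrix(as.integer(tab), length(classes), length(classes),
              dimnames = list(true = classes, predicted = classes))
  m
}

#' Collapse a confusion matrix against a positive class
#'
#' Reduces the multi-class matrix to binary fall-alarm counts: `TP` the
#' positive diagonal cell, `FN` the rest of the positive row, `FP` the
#' rest of the positive column, `TN` everything else.
#'
#' @param cm Square confusion matrix with dimnames.
#' @param positive Positive class (default `"falling"`).
#' @return List of class `confusion_counts`: `TP`, `TN`, `FP`, `FN`.
#' @export
collapse_binary <- function(cm, positive = "falling") {
  if (!positive %in% rownames(cm)) stop("unknown class: ", positive)
  tp <- cm[positive, positive]
  fn <- sum(cm[positive, ]) - tp
  fp <- sum(cm[, positive]) - tp
  tn <- sum(cm) - tp - fn - fp
  structure(list(TP = as.integer(tp), TN = as.integer(tn),
                 FP = as.integer(fp), FN = as.integer(fn)),
            class = "confusion_counts")
}

#' Accuracy, sensitivity and specificity (percent)
#'
#' \deqn{Accuracy = \frac{TP+TN}{TP+TN+FP+FN} \times 100\%}
#' \deqn{Sensitivity = \frac{TP}{TP+FN} \times 100\%,\quad
#'       Specificity = \frac{TN}{TN+FP} \times 100\%}
#' Sensitivity is the fall-alarm recall; specificity the non-fall
#' rejection rate. A zero denominator yields `NA` for that metric (an
#' undefined-metric flag, not an error).
#'
#' @param counts A `confusion_counts`.
#' @return Named numeric `(accuracy, sensitivity, specificity)` in percent.
#' @export
classification_metrics <- function(counts) {
  with(counts, c(
    accuracy = if (TP + TN + FP + FN > 0)
      (TP + TN) / (TP + TN + FP + FN) * 100 else NA_real_,
    sensitivity = if (TP + FN > 0) TP / (TP + FN) * 100 else NA_real_,
    specificity = if (TN + FP > 0) TN / (TN + FP) * 100 else NA_real_))
}

#' Nominal 7:2:1 partition sizes
#'
#' Floors of the ratio shares; their sum can fall short of `n` by at most
#' `length(ratios) - 1` items, which [split_dataset()] appends to the test
#' partition.
#'
#' @param n Number of items.
#' @param ratios Partition ratios summing to 1.
#' @return Named integer `(train, validation, test)`.
#' @export
split_sizes <- function(n, ratios = c(0.7, 0.2, 0.1)) {
  if (abs(sum(ratios) - 1) > 1e-9) stop("ratios must sum to 1")
  c(train = as.integer(floor(ratios[1] * n)),
    validation = as.integer(floor(ratios[2] * n)),
    test = as.integer(floor(ratios[3] * n)))
}

#' Split a dataset 7:2:1 into train / validation / test
#'
#' Seeded shuffle, then nominal partition sizes `floor(0.7 n)`,
#' `floor(0.2 n)`, `floor(0.1 n)` with the (at most 2) leftover items
#' appended to the test partition. With `unit = "clip"` whole clips are
#' assigned to one partition, preventing overlapping windows from leaking
#' labels across the split.
#'
#' @param items Vector or list of items to split (e.g. motion windows).
#' @param ratios Partition ratios (default `c(0.7, 0.2, 0.1)`).
#' @param seed Integer seed for the shuffle.
#' @param unit `"item"` (each element independent, the frame-group
#'   convention) or `"clip"` (group by `clip_id`).
#' @param clip_ids Character vector parallel to `items`, required for
#'   `unit = "clip"`; defaults to each element's `clip_id` field.
#' @return List of class `dataset_split` with `train`, `validation`,
#'   `test` — integer index vectors into `items` — plus the sizes.
#' @export
split_dataset <- function(items, ratios = c(0.7, 0.2, 0.1), seed = 1L,
                          unit = c("item", "clip"), clip_ids = NULL) {
  unit <- match.arg(unit)
  n <- length(items)
  if (n < 10L) stop("need at least 10 items to split 7:2:1, got ", n)
  if (abs(sum(ratios) - 1) > 1e-9) stop("ratios must sum to 1")
  set.seed(seed)
  if (unit == "item") {
    ord <- sample.int(n)
    sz <- split_sizes(n, ratios)
    train <- ord[seq_len(sz[1])]
    validation <- ord[sz[1] + seq_len(sz[2])]
    test <- ord[(sz[1] + sz[2] + 1L):n]
  } else {
    if (is.null(clip_ids))
      clip_ids <- vapply(items, function(w) w$clip_id, "")
    ids <- unique(clip_ids)
    ord <- sample(ids)
    szc <- split_sizes(length(ids), ratios)
    tr_ids <- ord[seq_len(szc[1])]
    va_ids <- ord[szc[1] + seq_len(szc[2])]
    train <- which(clip_ids %in% tr_ids)
    validation <- which(clip_ids %in% va_ids)
    test <- which(!(clip_ids %in% c(tr_ids, va_ids)))
  }
  structure(list(train = train, validation = validation, test = test,
                 sizes = c(train = length(train),
                           validation = length(validation),
                           test = length(test))),
            class = "dataset_split")
}

#' Full evaluation report for a set of predictions
#'
#' Confusion matrix, per-class precision/recall, and the three headline
#' metrics after collapsing against the falling class.
#'
#' @param y_true,y_pred Label vectors.
#' @param classes Class set.
#' @return List of class `evaluation_report`: `confusion`, `per_class`
#'   (data.frame), `counts`, `metrics`.
#' @export
evaluation_report <- function(y_true, y_pred, classes = activity_levels) {
  cm <- confusion_matrix(y_true, y_pred, classes)
  per_class <- data.frame(
    class = classes,
    n = rowSums(cm),
    precision = diag(cm) / pmax(colSums(cm), 1) * 100,
    recall = diag(cm) / pmax(rowSums(cm), 1) * 100,
    row.names = NULL)
  counts <- collapse_binary(cm, "falling")
  structure(list(confusion = cm, per_class = per_class, counts = counts,
                 metrics = classification_metrics(counts)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Confusion matrix (rows = true, cols = predicted):\n")
  print(x$confusion)
  cat("\nPer-class precision/recall (%):\n")
  print(x$per_class, digits = 4)
  cat(sprintf("\nFall detection: accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%\n",
              x$metrics["accuracy"], x$metrics["sensitivity"],
              x$metrics["specificity"]))
  invisible(x)
}
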