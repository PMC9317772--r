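#' Default pipeline configuration
#'
#' A single declarative configuration drives the whole pipeline:
#' data source, tracker, cleaning, windowing, split and training settings.
#' Unknown keys in a user configuration are rejected.
#'
#' @return Nested list of class `pipeline_config`.
#' @export
default_pipeline_config <- function() {
  structure(list(
    seed = 1L,
    data = list(source = "synthetic", path = NULL, dialect = "csv",
                n_clips_per_class = 10L, n_frames = 90L),
    motion = list(fps = 30, body_height_px = 600, noise_std = 2,
                  fall_duration = 15, walk_amplitude = 20, walk_speed = 4,
                  sit_drop = 200, occlusion_rate = 0),
    tracker = list(ratio = 8, conf_threshold = 0.5, max_jump_frac = 0.5,
                   redetect_every = 0L),
    cleaning = list(k = 1.5, window = NULL),
    windows = list(W = 30L, stride = 1L, labeling = "last"),
    split = list(ratios = c(0.7, 0.2, 0.1), unit = "item"),
    training = list(epochs = 200L, lr = 3e-3, batch = 32L, hidden = 64L,
                    fc = 32L, bias = TRUE, cell = "lstm")
  ), class = "pipeline_config")
}

merge_config <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(defaults))
      stop("config error: unknown key '", full, "'")
    if (is.list(defaults[[nm]]) && !is.null(user[[nm]]))
      defaults[[nm]] <- merge_config(defaults[[nm]], as.list(user[[nm]]),
                                     full)
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

#' Read a pipeline configuration file
#'
#' YAML file with any subset of the keys of [default_pipeline_config()];
#' missing keys keep their defaults, unknown keys raise a config error.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config error: file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- merge_config(unclass(default_pipeline_config()),
                      if (is.null(user)) list() else user)
  class(cfg) <- "pipeline_config"
  cfg
}

stage <- function(name, expr, quiet) {
  if (!quiet) message(sprintf("[%s] ...", name))
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  if (!quiet)
    message(sprintf("[%s] done (%.1fs)", name,
                    proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full fall-detection pipeline
#'
#' Executes track -> clean -> window -> split -> train -> evaluate on
#' either generated synthetic clips or keypoint records read from file.
#' The tracking stage exercises the Vitruvian tracker on every clip that
#' carries a head-box track and reports how often the head detector was
#' activated. Evaluation reports the confusion matrix, per-class
#' precision/recall and the accuracy/sensitivity/specificity headline
#' metrics on both the held-out test split and the full window set. Fully
#' deterministic for a fixed configuration.
#'
#' @param config A `pipeline_config` (see [default_pipeline_config()]).
#' @param quiet Suppress per-stage progress messages.
#' @return List of class `pipeline_result`: `report_test`, `report_full`,
#'   `params`, `history`, `split_sizes`, `tracking`, `config`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), quiet = FALSE) {
  cfg <- merge_config(unclass(default_pipeline_config()), unclass(config))
  clips <- stage("data", {
    if (cfg$data$source == "synthetic") {
      mp <- do.call(motion_params, c(cfg$motion, list(seed = cfg$seed)))
      generate_dataset(cfg$data$n_clips_per_class, cfg$data$n_frames, mp)
    } else {
      if (is.null(cfg$data$path) || !file.exists(cfg$data$path))
        stop("config error: data path missing or not found: ",
             cfg$data$path)
      read_keypoint_records(cfg$data$path, cfg$data$dialect)
    }
  }, quiet)
  tracking <- stage("track", {
    tcfg <- do.call(tracker_config, cfg$tracker)
    rows <- lapply(clips, function(cl) {
      if (is.null(cl$head_track)) return(NULL)
      ht <- cl$head_track
      tr <- track_clip(cl, function(i)
        head_box(ht$fx[i], ht$fy[i], ht$fw[i], ht$fh[i]), tcfg)
      data.frame(clip_id = cl$clip_id, frames = nrow(tr),
                 detector_calls = sum(tr$redetected),
                 final_theta = tr$theta[nrow(tr)])
    })
    do.call(rbind, rows)
  }, quiet)
  clips <- stage("clean", lapply(clips, clean_clip, k = cfg$cleaning$k,
                                 window = cfg$cleaning$window), quiet)
  windows <- stage("window", {
    w <- unlist(lapply(clips, build_windows, W = cfg$windows$W,
                       stride = cfg$windows$stride,
                       labeling = cfg$windows$labeling),
                recursive = FALSE)
    if (!length(w)) stop("no windows produced; clips shorter than W?")
    w
  }, quiet)
  sp <- stage("split", split_dataset(windows, ratios = cfg$split$ratios,
                                     seed = cfg$seed, unit = cfg$split$unit),
              quiet)
  fit <- stage("train", {
    tr <- cfg$training
    lstm_train(windows[sp$train], epochs = tr$epochs, lr = tr$lr,
               batch = tr$batch, seed = cfg$seed, hidden = tr$hidden,
               fc = tr$fc, bias = tr$bias, cell = tr$cell,
               validation = windows[sp$validation])
  }, quiet)
  result <- stage("evaluate", {
    pred <- function(idx) {
      ds <- windows_to_array(windows[idx])
      n <- dim(ds$x)[3]
      out <- character(n)
      for (s in seq.int(1L, n, by = 256L)) {
        id <- s:min(s + 255L, n)
        h <- core_forward(fit$params, ds$x[, , id, drop = FALSE])$h
        probs <- head_forward(fit$params, h)$probs
        out[id] <- fit$params$classes[apply(probs, 2, which.max)]
      }
      list(true = as.character(ds$y), pred = out)
    }
    te <- pred(sp$test)
    fu <- pred(seq_along(windows))
    list(test = evaluation_report(te$true, te$pred),
         full = evaluation_report(fu$true, fu$pred))
  }, quiet)
  structure(list(report_test = result$test, report_full = result$full,
                 params = fit$params, history = fit$history,
                 split_sizes = sp$sizes, tracking = tracking,
                 config = cfg),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("== fall-detection pipeline result ==\n")
  cat(sprintf("windows: %d train / %d validation / %d test\n",
              x$split_sizes["train"], x$split_sizes["validation"],
              x$split_sizes["test"]))
  if (!is.null(x$tracking))
    cat(sprintf("tracking: %d clips, %.2f detector calls/clip (of %d frames)\n",
                nrow(x$tracking), mean(x$tracking$detector_calls),
                x$tracking$frames[1]))
  cat("\n-- held-out test split --\n")
  print(x$report_test)
  cat("\n-- full window set --\n")
  print(x$report_full)
  invisible(x)
}

#' Per-frame streaming annotation
#'
#' Slides the classifier along the clip and assigns each frame the
#' two-letter activity code (`SD` standing, `WK` walking, `ST` sitting,
#' `FL` falling) of the window ending at that frame; the first `W - 1`
#' frames take the first window's label.
#'
#' @param clip A `skeleton_clip` of at least `W` frames (cleaned, or
#'   cleanable: it is boxplot-cleaned internally when any torso keypoint
#'   is missing).
#' @param params Trained `lstm_params` (or a checkpoint path).
#' @param W Window length used at training time.
#' @return Character vector of per-frame codes, length `n_frames(clip)`.
#' @export
annotate_stream <- function(clip, params, W = 30L) {
  if (is.character(params)) params <- load_checkpoint(params)
  n <- n_frames(clip)
  if (n < W) stop("clip shorter than the classifier window (", W, " frames)")
  if (any(clip$missing[, torso_ids()])) clip <- clean_clip(clip)
  feat <- normalize_frame(torso_features(clip), clip$image_size)
  X <- array(NA_real_, c(W, 8L, n - W + 1L))
  for (s in seq_len(n - W + 1L)) X[, , s] <- feat[s:(s + W - 1L), ]
  h <- core_forward(params, X)$h
  probs <- head_forward(params, h)$probs
  lab <- params$classes[apply(probs, 2, which.max)]
  codes <- unname(activity_codes[lab])
  c(rep(codes[1], W - 1L), codes)
}
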