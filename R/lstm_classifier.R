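#' Initialise LSTM classifier parameters
#'
#' The cell follows the explicit gate formulation
#' \deqn{f_t = \sigma(U_f h_{t-1} + W_f x_t),\quad k_t = c_{t-1} \odot f_t}
#' \deqn{i_t = \sigma(U_i h_{t-1} + W_i x_t),\quad
#'       g_t = \tanh(U_g h_{t-1} + W_g x_t),\quad j_t = g_t \odot i_t}
#' \deqn{c_t = j_t + k_t,\quad o_t = \sigma(U_o h_{t-1} + W_o x_t),\quad
#'       h_t = \tanh(c_t) \odot o_t}
#' with recurrent matrices `U*` (`hidden x hidden`) and input matrices `W*`
#' (`hidden x n_in`). The reference cell is bias-free, matching the gate
#' equations exactly; the trainable configuration adds gate biases behind
#' the `bias` flag (default on) for optimisation stability, with the forget
#' bias initialised at +1 so early training retains long-range state.
#' The classifier head is fully connected -> ReLU -> fully connected ->
#' softmax over the four classes. Weights are drawn from
#' `uniform(-1/sqrt(hidden), 1/sqrt(hidden))`.
#'
#' A plain recurrent baseline (`cell = "rnn"`,
#' \eqn{h_t = \tanh(U h_{t-1} + W x_t + b)}) shares the head and trainer,
#' for long-dependence comparisons.
#'
#' @param hidden Hidden state size (default 64).
#' @param n_in Input feature dimension (8 torso coordinates).
#' @param n_classes Number of classes (4).
#' @param fc Width of the intermediate fully connected layer.
#' @param bias Add trainable gate biases (default `TRUE`). `FALSE` gives
#'   the bias-free reference cell.
#' @param cell `"lstm"` or `"rnn"`.
#' @param forget_bias Initial forget-gate bias (used only when
#'   `bias = TRUE` and `cell = "lstm"`).
#' @param seed Integer seed for the draw; `NULL` leaves the RNG state alone.
#' @param classes Class labels, defining the class-index order.
#' @return An object of class `lstm_params`.
#' @export
lstm_init_params <- function(hidden = 64L, n_in = 8L, n_classes = 4L,
                             fc = 32L, bias = TRUE, cell = c("lstm", "rnn"),
                             forget_bias = 1, seed = NULL,
                             classes = activity_levels) {
  cell <- match.arg(cell)
  if (!is.null(seed)) set.seed(seed)
  r <- 1 / sqrt(hidden)
  mat <- function(nr, nc) matrix(runif(nr * nc, -r, r), nr, nc)
  p <- list(hidden = as.integer(hidden), n_in = as.integer(n_in),
            n_classes = as.integer(n_classes), fc = as.integer(fc),
            bias = bias, cell = cell, classes = classes)
  if (cell == "lstm") {
    for (g in c("f", "i", "g", "o")) {
      p[[paste0("U", g)]] <- mat(hidden, hidden)
      p[[paste0("W", g)]] <- mat(hidden, n_in)
    }
    if (bias) {
      p$bf <- rep(forget_bias, hidden)
      p$bi <- numeric(hidden); p$bg <- numeric(hidden)
      p$bo <- numeric(hidden)
    }
  } else {
    p$U <- mat(hidden, hidden)
    p$W <- mat(hidden, n_in)
    if (bias) p$b <- numeric(hidden)
  }
  p$head_W1 <- mat(fc, hidden); p$head_b1 <- numeric(fc)
  p$head_W2 <- mat(n_classes, fc); p$head_b2 <- numeric(n_classes)
  class(p) <- "lstm_params"
  p
}

sigmoid <- function(z) 1 / (1 + exp(-z))

as_col <- function(x, n) if (is.matrix(x)) x else matrix(x, n, 1L)

#' One LSTM cell step
#'
#' Applies the gate equations to one input (or a batch: columns are batch
#' elements) and the previous state, returning the new state. See
#' [lstm_init_params()] for the formulation. With the bias flag off this is
#' the bias-free reference cell used by the oracle tests.
#'
#' @param params An `lstm_params` with `cell = "lstm"`.
#' @param x_t Input vector of length `n_in`, or `n_in x B` matrix.
#' @param state List with `h` and `c` (vectors of length `hidden`, or
#'   `hidden x B` matrices). `NULL` gives the zero state.
#' @param keep_gates Also return the gate activations (for inspection and
#'   backpropagation).
#' @return List with `h`, `c` (same shape as supplied) and optionally
#'   `f`, `i`, `g`, `o`.
#' @export
lstm_step <- function(params, x_t, state = NULL, keep_gates = FALSE) {
  H <- params$hidden
  vec_in <- !is.matrix(x_t)
  x <- as_col(x_t, params$n_in)
  if (nrow(x) != params$n_in) stop("shape error: x_t must have length n_in")
  B <- ncol(x)
  if (is.null(state)) state <- list(h = matrix(0, H, B), c = matrix(0, H, B))
  h <- as_col(state$h, H); c0 <- as_col(state$c, H)
  if (nrow(h) != H || nrow(c0) != H)
    stop("shape error: state must have hidden rows")
  bz <- function(nm) if (params$bias) params[[nm]] else 0
  f <- sigmoid(params$Uf %*% h + params$Wf %*% x + bz("bf"))
  k <- c0 * f
  i <- sigmoid(params$Ui %*% h + params$Wi %*% x + bz("bi"))
  g <- tanh(params$Ug %*% h + params$Wg %*% x + bz("bg"))
  j <- g * i
  cc <- j + k
  o <- sigmoid(params$Uo %*% h + params$Wo %*% x + bz("bo"))
  hh <- tanh(cc) * o
  res <- if (vec_in) list(h = drop(hh), c = drop(cc))
  else list(h = hh, c = cc)
  if (keep_gates) { res$f <- f; res$i <- i; res$g <- g; res$o <- o }
  res
}

rnn_step <- function(params, x_t, state = NULL) {
  H <- params$hidden
  x <- as_col(x_t, params$n_in)
  B <- ncol(x)
  if (is.null(state)) state <- list(h = matrix(0, H, B))
  b <- if (params$bias) params$b else 0
  list(h = tanh(params$U %*% as_col(state$h, H) + params$W %*% x + b))
}

# run the recurrent core over a batch; X is W x n_in x B.
# returns final h plus per-step caches needed by backprop.
core_forward <- function(params, X, keep = FALSE) {
  dm <- dim(X)
  W <- dm[1]; B <- dm[3]; H <- params$hidden
  h <- matrix(0, H, B); c <- matrix(0, H, B)
  cache <- if (keep) vector("list", W) else NULL
  for (t in seq_len(W)) {
    x_t <- matrix(X[t, , ], params$n_in, B)
    if (params$cell == "lstm") {
      s <- lstm_step(params, x_t, list(h = h, c = c), keep_gates = keep)
      if (keep) cache[[t]] <- list(x = x_t, h_prev = h, c_prev = c,
                                   f = s$f, i = s$i, g = s$g, o = s$o,
                                   c = s$c, h = s$h)
      h <- s$h; c <- s$c
    } else {
      s <- rnn_step(params, x_t, list(h = h))
      if (keep) cache[[t]] <- list(x = x_t, h_prev = h, h = s$h)
      h <- s$h
    }
  }
  list(h = h, cache = cache)
}

head_forward <- function(params, h) {
  z1 <- params$head_W1 %*% h + params$head_b1
  a1 <- pmax(z1, 0)
  z2 <- params$head_W2 %*% a1 + params$head_b2
  z2 <- sweep(z2, 2, apply(z2, 2, max))
  e <- exp(z2)
  probs <- sweep(e, 2, colSums(e), `/`)
  list(z1 = z1, a1 = a1, probs = probs)
}

#' Forward pass: window of features to class probabilities
#'
#' Runs the recurrent cell over the window from the zero initial state,
#' then the fully connected -> ReLU -> fully connected -> softmax head.
#' Output is a proper probability vector: positive components summing to 1.
#'
#' @param params An `lstm_params`.
#' @param window A `motion_window`, or a `W x n_in` feature matrix.
#' @return Named probability vector over `params$classes`.
#' @export
lstm_forward <- function(params, window) {
  feat <- if (inherits(window, "motion_window")) window$features else window
  feat <- as.matrix(feat)
  if (nrow(feat) < 1L) stop("shape error: window must have at least 1 frame")
  if (ncol(feat) != params$n_in)
    stop("shape error: window features must have n_in columns")
  X <- array(feat, c(nrow(feat), ncol(feat), 1L))
  h <- core_forward(params, X)$h
  p <- drop(head_forward(params, h)$probs)
  names(p) <- params$classes
  p
}

#' Predict the activity class of a window
#'
#' Argmax of [lstm_forward()]; ties are broken toward the lowest class
#' index in `params$classes`.
#'
#' @param params Trained `lstm_params`.
#' @param window A `motion_window` or feature matrix.
#' @return List with `label` (character) and `probability` (its softmax
#'   probability).
#' @export
lstm_predict <- function(params, window) {
  p <- lstm_forward(params, window)
  k <- which.max(p)
  list(label = params$classes[k], probability = unname(p[k]))
}

# one-hot C x B matrix from a factor aligned to params$classes
one_hot <- function(y, classes) {
  Y <- matrix(0, length(classes), length(y))
  Y[cbind(match(as.character(y), classes), seq_along(y))] <- 1
  Y
}

#' Loss and analytic gradients on a batch
#'
#' Mean cross-entropy of the classifier over a batch of windows, with
#' gradients for every trainable parameter computed by backpropagation
#' through time. Exposed so gradient correctness can be verified against
#' finite differences.
#'
#' @param params An `lstm_params`.
#' @param X Array `W x n_in x B` of features.
#' @param y Labels (factor or character, in `params$classes`).
#' @return List with `loss`, `probs` (`C x B`) and `grads` (named list
#'   matching the parameter matrices).
#' @export
sequence_loss_grads <- function(params, X, y) {
  B <- dim(X)[3]
  Y <- one_hot(y, params$classes)
  fw <- core_forward(params, X, keep = TRUE)
  hd <- head_forward(params, fw$h)
  probs <- hd$probs
  loss <- -mean(log(pmax(colSums(probs * Y), 1e-300)))
  g <- list()
  dz2 <- (probs - Y) / B
  g$head_W2 <- dz2 %*% t(hd$a1)
  g$head_b2 <- rowSums(dz2)
  da1 <- t(params$head_W2) %*% dz2
  dz1 <- da1 * (hd$z1 > 0)
  g$head_W1 <- dz1 %*% t(fw$h)
  g$head_b1 <- rowSums(dz1)
  dh <- t(params$head_W1) %*% dz1
  H <- params$hidden
  Wlen <- dim(X)[1]
  if (params$cell == "lstm") {
    for (nm in c("Uf", "Wf", "Ui", "Wi", "Ug", "Wg", "Uo", "Wo"))
      g[[nm]] <- array(0, dim(params[[nm]]))
    if (params$bias) for (nm in c("bf", "bi", "bg", "bo"))
      g[[nm]] <- numeric(H)
    dc <- matrix(0, H, B)
    for (t in rev(seq_len(Wlen))) {
      cc <- fw$cache[[t]]
      tc <- tanh(cc$c)
      do_ <- dh * tc
      dc <- dc + dh * cc$o * (1 - tc^2)
      df <- dc * cc$c_prev
      di <- dc * cc$g
      dg <- dc * cc$i
      dpre_f <- df * cc$f * (1 - cc$f)
      dpre_i <- di * cc$i * (1 - cc$i)
      dpre_g <- dg * (1 - cc$g^2)
      dpre_o <- do_ * cc$o * (1 - cc$o)
      g$Uf <- g$Uf + dpre_f %*% t(cc$h_prev)
      g$Ui <- g$Ui + dpre_i %*% t(cc$h_prev)
      g$Ug <- g$Ug + dpre_g %*% t(cc$h_prev)
      g$Uo <- g$Uo + dpre_o %*% t(cc$h_prev)
      g$Wf <- g$Wf + dpre_f %*% t(cc$x)
      g$Wi <- g$Wi + dpre_i %*% t(cc$x)
      g$Wg <- g$Wg + dpre_g %*% t(cc$x)
      g$Wo <- g$Wo + dpre_o %*% t(cc$x)
      if (params$bias) {
        g$bf <- g$bf + rowSums(dpre_f)
        g$bi <- g$bi + rowSums(dpre_i)
        g$bg <- g$bg + rowSums(dpre_g)
        g$bo <- g$bo + rowSums(dpre_o)
      }
      dh <- t(params$Uf) %*% dpre_f + t(params$Ui) %*% dpre_i +
        t(params$Ug) %*% dpre_g + t(params$Uo) %*% dpre_o
      dc <- dc * cc$f
    }
  } else {
    g$U <- array(0, dim(params$U)); g$W <- array(0, dim(params$W))
    if (params$bias) g$b <- numeric(H)
    for (t in rev(seq_len(Wlen))) {
      cc <- fw$cache[[t]]
      dpre <- dh * (1 - cc$h^2)
      g$U <- g$U + dpre %*% t(cc$h_prev)
      g$W <- g$W + dpre %*% t(cc$x)
      if (params$bias) g$b <- g$b + rowSums(dpre)
      dh <- t(params$U) %*% dpre
    }
  }
  list(loss = loss, probs = probs, grads = g)
}

trainable_names <- function(params) {
  nms <- c("head_W1", "head_b1", "head_W2", "head_b2")
  if (params$cell == "lstm") {
    nms <- c(nms, "Uf", "Wf", "Ui", "Wi", "Ug", "Wg", "Uo", "Wo")
    if (params$bias) nms <- c(nms, "bf", "bi", "bg", "bo")
  } else {
    nms <- c(nms, "U", "W")
    if (params$bias) nms <- c(nms, "b")
  }
  nms
}

eval_dataset <- function(params, X, y, batch = 256L) {
  n <- dim(X)[3]
  Y <- one_hot(y, params$classes)
  loss <- 0; correct <- 0
  for (s in seq.int(1L, n, by = batch)) {
    idx <- s:min(s + batch - 1L, n)
    Xb <- X[, , idx, drop = FALSE]
    h <- core_forward(params, Xb)$h
    probs <- head_forward(params, h)$probs
    loss <- loss - sum(log(pmax(colSums(probs * Y[, idx, drop = FALSE]),
                                1e-300)))
    correct <- correct + sum(apply(probs, 2, which.max) ==
                               match(as.character(y[idx]), params$classes))
  }
  c(loss = loss / n, acc = correct / n)
}

#' Train the sequence classifier with Adam
#'
#' Minimises mean cross-entropy over labeled motion windows by
#' backpropagation through time and the Adam optimiser
#' (beta1 = 0.9, beta2 = 0.999, eps = 1e-8). Fully deterministic for a
#' given seed: the parameter draw, batch shuffling and every update are
#' reproducible bit for bit.
#'
#' @param windows List of `motion_window`, or a list with `x`
#'   (`W x n_in x B` array) and `y` (labels) as from [windows_to_array()].
#' @param epochs Training epochs.
#' @param lr Learning rate.
#' @param batch Minibatch size.
#' @param seed Integer seed.
#' @param hidden,fc,bias,cell,forget_bias Passed to [lstm_init_params()].
#' @param validation Optional held-out set in the same form, evaluated each
#'   epoch into the history.
#' @param classes Class label order.
#' @param verbose Print per-epoch progress.
#' @return List with `params` (trained `lstm_params`) and `history`
#'   (data.frame: epoch, train_loss, train_acc, val_loss, val_acc).
#' @export
lstm_train <- function(windows, epochs = 200L, lr = 3e-3, batch = 32L,
                       seed = 1L, hidden = 64L, fc = 32L, bias = TRUE,
                       cell = c("lstm", "rnn"), forget_bias = 1,
                       validation = NULL, classes = activity_levels,
                       verbose = FALSE) {
  cell <- match.arg(cell)
  ds <- if (is.list(windows) && !is.null(windows$x)) windows
  else windows_to_array(windows)
  n <- dim(ds$x)[3]
  if (n < 1L) stop("degenerate dataset: no training windows")
  if (length(unique(as.character(ds$y))) < 2L)
    stop("degenerate dataset: at least 2 classes required")
  val <- if (!is.null(validation)) {
    if (is.list(validation) && !is.null(validation$x)) validation
    else windows_to_array(validation)
  }
  set.seed(seed)
  params <- lstm_init_params(hidden = hidden, n_in = dim(ds$x)[2],
                             n_classes = length(classes), fc = fc,
                             bias = bias, cell = cell,
                             forget_bias = forget_bias, classes = classes)
  nms <- trainable_names(params)
  m <- v <- lapply(params[nms], function(p) p * 0)
  names(m) <- names(v) <- nms
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     train_acc = numeric(), val_loss = numeric(),
                     val_acc = numeric())
  yi <- match(as.character(ds$y), classes)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0
    for (s in seq.int(1L, n, by = batch)) {
      idx <- ord[s:min(s + batch - 1L, n)]
      Xb <- ds$x[, , idx, drop = FALSE]
      res <- sequence_loss_grads(params, Xb, ds$y[idx])
      ep_loss <- ep_loss + res$loss * length(idx)
      ep_correct <- ep_correct +
        sum(apply(res$probs, 2, which.max) == yi[idx])
      if (lr > 0) {
        step <- step + 1L
        for (nm in nms) {
          gr <- res$grads[[nm]]
          m[[nm]] <- b1 * m[[nm]] + (1 - b1) * gr
          v[[nm]] <- b2 * v[[nm]] + (1 - b2) * gr^2
          mhat <- m[[nm]] / (1 - b1^step)
          vhat <- v[[nm]] / (1 - b2^step)
          params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        }
      }
    }
    row <- data.frame(epoch = ep, train_loss = ep_loss / n,
                      train_acc = ep_correct / n,
                      val_loss = NA_real_, val_acc = NA_real_)
    if (!is.null(val)) {
      ev <- eval_dataset(params, val$x, val$y)
      row$val_loss <- ev[["loss"]]; row$val_acc <- ev[["acc"]]
    }
    hist <- rbind(hist, row)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  acc %.3f%s", ep, row$train_loss,
                      row$train_acc,
                      if (!is.null(val))
                        sprintf("  val_acc %.3f", row$val_acc) else ""))
  }
  list(params = params, history = hist)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load a model checkpoint
#'
#' The checkpoint holds every weight matrix, the dimensions, the
#' class-label order and the configuration flags, and round-trips
#' bit-exactly.
#'
#' @param params An `lstm_params`.
#' @param path File path (RDS container).
#' @return `save_checkpoint`: `path` invisibly. `load_checkpoint`: the
#'   restored `lstm_params`.
#' @export
save_checkpoint <- function(params, path) {
  stopifnot(inherits(params, "lstm_params"))
  saveRDS(params, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  p <- readRDS(path)
  if (!inherits(p, "lstm_params")) stop("not a model checkpoint: ", path)
  p
}
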