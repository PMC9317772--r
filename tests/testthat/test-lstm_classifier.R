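# bias-free scalar parameter sets for hand-checkable cell arithmetic
scalar_params <- function(val = 1) {
  p <- lstm_init_params(hidden = 1, n_in = 1, n_classes = 2, fc = 1,
                        bias = FALSE, seed = 1)
  for (nm in c("Uf", "Wf", "Ui", "Wi", "Ug", "Wg", "Uo", "Wo"))
    p[[nm]] <- matrix(val, 1, 1)
  p
}

zero_params <- function(hidden = 3, n_in = 8, fc = 4) {
  p <- lstm_init_params(hidden = hidden, n_in = n_in, fc = fc,
                        bias = FALSE, seed = 1)
  for (nm in c("Uf", "Wf", "Ui", "Wi", "Ug", "Wg", "Uo", "Wo",
               "head_W1", "head_W2"))
    p[[nm]] <- p[[nm]] * 0
  p
}

test_that("the cell reproduces the scalar hand computation of the gates", {
  p <- scalar_params(1)
  s <- lstm_step(p, 1, list(h = 0, c = 0))
  sig1 <- stats::plogis(1)  # independent sigmoid
  expect_equal(s$c, sig1 * tanh(1), tolerance = 1e-12)
  expect_equal(s$h, tanh(sig1 * tanh(1)) * sig1, tolerance = 1e-12)
  expect_equal(round(s$c, 4), 0.5568)
  expect_equal(round(s$h, 4), 0.3696)
})

test_that("zero weights give zero state; only the forget path scales c", {
  p <- zero_params()
  s <- lstm_step(p, runif(8), list(h = rep(0, 3), c = rep(0, 3)))
  expect_equal(s$h, rep(0, 3))
  expect_equal(s$c, rep(0, 3))
  c0 <- c(2, -1, 0.5)
  s2 <- lstm_step(p, runif(8), list(h = rep(0, 3), c = c0))
  expect_equal(s2$c, 0.5 * c0)               # f = sigmoid(0) = 0.5
  expect_equal(s2$h, 0.5 * tanh(0.5 * c0))   # o = 0.5
})

test_that("gate activations stay in range on random inputs", {
  set.seed(77)
  p <- lstm_init_params(hidden = 6, n_in = 8, seed = 77)
  st <- NULL
  for (t in 1:20) {
    st <- lstm_step(p, rnorm(8, sd = 3), st, keep_gates = TRUE)
    expect_true(all(st$f > 0 & st$f < 1))
    expect_true(all(st$i > 0 & st$i < 1))
    expect_true(all(st$o > 0 & st$o < 1))
    expect_true(all(abs(st$g) < 1))
    expect_true(all(abs(st$h) < 1))
    st <- list(h = st$h, c = st$c)
  }
})

test_that("forward yields a probability vector; zero weights give uniform", {
  p0 <- zero_params()
  expect_equal(unname(lstm_forward(p0, matrix(rnorm(80), 10, 8))),
               rep(0.25, 4))
  set.seed(5)
  p <- lstm_init_params(hidden = 5, n_in = 8, seed = 5)
  pr <- lstm_forward(p, matrix(rnorm(240), 30, 8))
  expect_equal(sum(pr), 1, tolerance = 1e-9)
  expect_true(all(pr > 0))
})

test_that("a single-step window equals cell + head applied manually", {
  set.seed(6)
  p <- lstm_init_params(hidden = 4, n_in = 8, fc = 3, seed = 6)
  x <- rnorm(8)
  via_forward <- lstm_forward(p, matrix(x, 1, 8))
  s <- lstm_step(p, x)
  z1 <- p$head_W1 %*% s$h + p$head_b1
  z2 <- p$head_W2 %*% pmax(z1, 0) + p$head_b2
  manual <- exp(z2 - max(z2)) / sum(exp(z2 - max(z2)))
  expect_equal(unname(via_forward), as.vector(manual), tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  for (spec in list(list(cell = "lstm", bias = TRUE),
                    list(cell = "lstm", bias = FALSE),
                    list(cell = "rnn", bias = TRUE))) {
    set.seed(99)
    p <- lstm_init_params(hidden = 3, n_in = 4, fc = 4, seed = 99,
                          bias = spec$bias, cell = spec$cell)
    X <- array(rnorm(5 * 4 * 3), c(5, 4, 3))
    y <- c("walking", "falling", "sitting")
    an <- sequence_loss_grads(p, X, y)
    eps <- 1e-5
    nms <- fallsense:::trainable_names(p)
    for (nm in nms) {
      num <- p[[nm]] * 0
      for (k in seq_along(p[[nm]])) {
        pp <- p; pp[[nm]][k] <- pp[[nm]][k] + eps
        pm <- p; pm[[nm]][k] <- pm[[nm]][k] - eps
        num[k] <- (sequence_loss_grads(pp, X, y)$loss -
                     sequence_loss_grads(pm, X, y)$loss) / (2 * eps)
      }
      denom <- max(abs(num), abs(an$grads[[nm]]), 1e-8)
      expect_lt(max(abs(num - an$grads[[nm]])) / denom, 1e-4)
    }
  }
})

test_that("training separates trivially separable windows within 30 epochs", {
  set.seed(123)
  mk <- function(kind, i) {
    base <- runif(8, 0.3, 0.6)
    f <- matrix(rep(base, each = 30), 30, 8)
    if (kind == "falling") {
      drop <- seq(0, 0.4, length.out = 30)
      f[, c(2, 4, 6, 8)] <- f[, c(2, 4, 6, 8)] + drop
    }
    f <- f + matrix(rnorm(240, 0, 0.005), 30, 8)
    structure(list(features = f, label = kind, clip_id = paste0(kind, i),
                   start_frame = 1L), class = "motion_window")
  }
  w <- c(lapply(1:100, function(i) mk("standing", i)),
         lapply(1:100, function(i) mk("falling", i)))
  fit <- lstm_train(w, epochs = 30, lr = 1e-2, batch = 32, seed = 2,
                    hidden = 16, fc = 8)
  expect_equal(max(fit$history$train_acc), 1.0)
})

test_that("training is bitwise deterministic and inert at lr = 0", {
  set.seed(11)
  w <- build_windows(clean_clip(simulate_clip("falling", 60,
                                              motion_params(seed = 11))),
                     W = 30)
  a <- lstm_train(w, epochs = 3, batch = 16, seed = 7, hidden = 8, fc = 4)
  b <- lstm_train(w, epochs = 3, batch = 16, seed = 7, hidden = 8, fc = 4)
  expect_identical(a$history, b$history)
  expect_identical(a$params, b$params)
  frozen <- lstm_train(w, epochs = 3, lr = 0, batch = 16, seed = 7,
                       hidden = 8, fc = 4)
  # constant up to float summation order across epoch shuffles
  expect_lt(diff(range(frozen$history$train_loss)), 1e-10)
})

test_that("degenerate datasets are rejected", {
  w <- build_windows(clean_clip(simulate_clip("standing", 40,
                                              motion_params(seed = 12))),
                     W = 30)
  expect_error(lstm_train(w, epochs = 1), "degenerate dataset")
  expect_error(lstm_train(list(), epochs = 1), "no windows")
})

test_that("prediction takes the argmax with ties to the lowest class index", {
  p0 <- zero_params()
  pred <- lstm_predict(p0, matrix(rnorm(80), 10, 8))
  expect_identical(pred$label, "walking")  # uniform tie -> first class
  expect_equal(pred$probability, 0.25)
  set.seed(8)
  p <- lstm_init_params(hidden = 5, n_in = 8, seed = 8)
  win <- matrix(rnorm(160), 20, 8)
  pr <- lstm_forward(p, win)
  pred2 <- lstm_predict(p, win)
  expect_identical(pred2$label, names(pr)[which.max(pr)])
  expect_equal(pred2$probability, max(pr))
})

test_that("checkpoints round-trip bit-exactly", {
  set.seed(9)
  p <- lstm_init_params(hidden = 6, seed = 9)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(p, path)
  expect_identical(load_checkpoint(path), p)
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(1), bad)
  expect_error(load_checkpoint(bad), "not a model checkpoint")
})
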