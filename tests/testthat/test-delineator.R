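# Convolutional feature extraction and BiLSTM labeling: brute-force
# oracles, symmetry properties, gradient correctness, compiled-vs-reference
# kernel agreement, and the derived-boundary post-processing.

test_that("conv_features matches a sliding-window oracle on small instances", {
  # oracle: explicit loops over position, kernel tap and channel, with
  # zero padding at the sequence edges
  oracle_conv <- function(W, b, A, relu = TRUE) {
    Tn <- nrow(A); cin <- ncol(A)
    k <- dim(W)[1]; cout <- dim(W)[3]
    half <- (k - 1) / 2
    out <- matrix(0, Tn, cout)
    for (t in seq_len(Tn)) for (o in seq_len(cout)) {
      acc <- b[o]
      for (kk in seq_len(k)) {
        src <- t + kk - 1 - half
        if (src >= 1 && src <= Tn)
          for (cc in seq_len(cin)) acc <- acc + W[kk, cc, o] * A[src, cc]
      }
      out[t, o] <- if (relu) max(acc, 0) else acc
    }
    out
  }
  withr::with_seed(21, {
    for (rep in 1:10) {
      Tn <- sample(4:10, 1)
      spec1 <- delineator_spec(conv_stages = list(c(2, 3, 1)),
                               recurrent_hidden = 2L, sequence_length = Tn)
      w <- tiny_weights(spec1, seed = rep)
      w[["c1.b"]] <- stats::rnorm(2) * 0.1  # keep pre-activations off the kink
      x <- stats::rnorm(Tn)
      got <- conv_features(w, x, spec1)
      want <- oracle_conv(w[["c1.W"]], w[["c1.b"]], matrix(x, Tn, 1))
      expect_equal(got, want, tolerance = 1e-10)
    }
  })
})

test_that("degenerate conv kernels behave as the arithmetic dictates", {
  Tn <- 12L
  spec1 <- delineator_spec(conv_stages = list(c(1, 3, 1)),
                           recurrent_hidden = 2L, sequence_length = Tn)
  w <- tiny_weights(spec1)
  # all-zero weights annihilate any input
  w[["c1.W"]][] <- 0; w[["c1.b"]][] <- 0
  expect_true(all(conv_features(w, stats::rnorm(Tn), spec1) == 0))
  # delta kernel (0, 1, 0) passes a nonnegative input through unchanged
  w[["c1.W"]][, 1, 1] <- c(0, 1, 0)
  x <- abs(stats::rnorm(Tn))
  expect_equal(drop(conv_features(w, x, spec1)), x, tolerance = 1e-12)
  # four default stages with stride 1 preserve the 370-sample length
  spec <- delineator_spec()
  w4 <- tiny_weights(spec)
  fm <- conv_features(w4, stats::rnorm(370), spec)
  expect_equal(dim(fm), c(370L, 64L))
})

test_that("zero output weights give uniform class probabilities", {
  spec <- tiny_spec(Tn = 6L)
  w <- tiny_weights(spec)
  w[["o.W"]][] <- 0; w[["o.b"]][] <- 0
  res <- bilstm_labels(matrix(stats::rnorm(18), 6, 3), w)
  expect_true(all(abs(res$probabilities - 0.2) < 1e-12))
  # argmax ties break to the lowest class index (canonical order)
  expect_true(all(res$labels == "P"))
})

test_that("probability rows sum to one for random weights", {
  withr::with_seed(9, {
    spec <- tiny_spec(Tn = 10L, hidden = 4L)
    w <- tiny_weights(spec)
    res <- bilstm_labels(matrix(stats::rnorm(30), 10, 3), w)
    expect_equal(rowSums(res$probabilities), rep(1, 10), tolerance = 1e-6)
    expect_true(all(res$labels ==
                      colnames(res$probabilities)[max.col(res$probabilities,
                                                          "first")]))
  })
})

test_that("reversing the input swaps the forward and backward streams", {
  withr::with_seed(14, {
    Tn <- 6L; C <- 2L; H <- 3L
    Wx <- matrix(stats::rnorm(C * 4 * H), C, 4 * H)
    Wh <- matrix(stats::rnorm(H * 4 * H) * 0.3, H, 4 * H)
    b <- stats::rnorm(4 * H)
    X <- array(stats::rnorm(Tn * C), c(Tn, 1, C))
    Xrev <- X[Tn:1, , , drop = FALSE]
    fwd <- ecgwave:::lstm_forward(Wx, Wh, b, X, +1)
    bwd_rev <- ecgwave:::lstm_forward(Wx, Wh, b, Xrev, -1)
    # forward pass over x equals backward pass over reversed x, reversed
    expect_equal(fwd$Hs[, , 1:Tn], bwd_rev$Hs[, , Tn:1], tolerance = 1e-12)
  })
})

test_that("compiled LSTM kernels agree with the plain-R reference", {
  withr::with_seed(6, {
    Tn <- 12L; B <- 3L; C <- 4L; H <- 5L
    Wx <- matrix(stats::rnorm(C * 4 * H), C, 4 * H)
    Wh <- matrix(stats::rnorm(H * 4 * H) * 0.2, H, 4 * H)
    b <- stats::rnorm(4 * H)
    X <- array(stats::rnorm(Tn * B * C), c(Tn, B, C))
    dH <- array(stats::rnorm(B * H * Tn), c(B, H, Tn))
    for (dir in c(1, -1)) {
      f_cpp <- ecgwave:::lstm_forward(Wx, Wh, b, X, dir)
      f_ref <- ecgwave:::lstm_forward_ref(Wx, Wh, b, X, dir)
      expect_equal(f_cpp$Hs, f_ref$Hs, tolerance = 1e-14)
      g_cpp <- ecgwave:::lstm_backward(Wx, Wh, b, X, f_cpp, dH)
      g_ref <- ecgwave:::lstm_backward_ref(Wx, Wh, b, X, f_ref, dH)
      for (nm in c("dWx", "dWh", "db", "dX"))
        expect_equal(g_cpp[[nm]], g_ref[[nm]], tolerance = 1e-12)
    }
  })
})

test_that("end-to-end analytic gradients match finite differences", {
  spec <- tiny_spec(Tn = 8L)
  w <- tiny_weights(spec, seed = 5)
  # nonzero biases keep ReLU pre-activations off the nondifferentiable kink
  w[["c1.b"]] <- c(0.11, -0.07)
  w[["c2.b"]] <- c(0.05, 0.13, -0.09)
  withr::with_seed(5, {
    B <- 2L
    X <- matrix(stats::runif(B * 8), B, 8)
    lab <- matrix(sample(1:5, 8 * B, TRUE), 8, B)
    Y <- ecgwave:::onehot(lab, 5L)
    fwd <- ecgwave:::delin_forward(spec, w, X)
    gr <- ecgwave:::delin_backward(spec, w, fwd, Y)
    lossfn <- function(w)
      ecgwave:::delin_loss(ecgwave:::delin_forward(spec, w, X)$P, Y)
    eps <- 1e-6
    for (nm in names(w)) {
      idx <- seq_len(min(10, length(w[[nm]])))
      for (i in idx) {
        wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
        wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
        num <- (lossfn(wp) - lossfn(wm)) / (2 * eps)
        expect_equal(gr[[nm]][i], num, tolerance = 1e-4)
      }
    }
  })
})

test_that("training is seed-deterministic and rejects degenerate configs", {
  ds <- generate_dataset(8, seed = 33)
  spec <- tiny_spec(Tn = 370L, stages = list(c(2, 3, 1)), hidden = 2L)
  cfg <- train_config(epochs = 2, batch_size = 4, learning_rate = 5e-3,
                      loss = "categorical_crossentropy", seed = 11)
  m1 <- train_delineator(ds$noisy, cfg, spec)
  m2 <- train_delineator(ds$noisy, cfg, spec)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(m1$weights, m2$weights)
  expect_error(delineator_spec(conv_stages = list(c(8, 3, 2))), "stride")
  expect_error(delineator_spec(conv_stages = list(c(8, 4, 1))), "kernel")
})

test_that("wave boundaries come from contiguous runs with a length floor", {
  lab <- c(rep("ISO", 3), rep("P", 4), rep("ISO", 2), "QRS",
           rep("QRS", 3), rep("ISO", 2), rep("T", 2), rep("PAD", 3))
  x <- seq_along(lab) / 10
  wb <- wave_boundaries(lab, x, min_run = 3L)
  expect_equal(wb$wave, c("P", "QRS"))          # T run of 2 dropped
  expect_equal(wb$onset[wb$wave == "P"], 3L)    # 0-based first index
  expect_equal(wb$offset[wb$wave == "P"], 6L)
  expect_equal(wb$peak[wb$wave == "QRS"], 12L)  # 0-based argmax inside the run
  wb1 <- wave_boundaries(lab, x, min_run = 1L)
  expect_true("T" %in% wb1$wave)
})

test_that("a delineation carries boundaries and R-peak for a labeled frame", {
  # degenerate model whose head always prefers PAD on zero features
  spec <- tiny_spec(Tn = 370L, stages = list(c(2, 3, 1)), hidden = 2L)
  w <- tiny_weights(spec)
  w[["o.W"]][] <- 0
  w[["o.b"]] <- c(-1, -1, -1, -1, 1)
  model <- structure(list(spec = spec, weights = w, loss_history = NA,
                          config = NULL), class = "delineator_model")
  res <- delineate(model, beat_frame(numeric(370), rep("ISO", 370)))
  expect_equal(nrow(res$waves), 0L)
  expect_true(is.na(res$r_peak))
  expect_equal(rowSums(res$probabilities), rep(1, 370), tolerance = 1e-6)
})

test_that("delineator serialisation round-trips predictions exactly", {
  ds <- generate_dataset(4, seed = 27)
  spec <- tiny_spec(Tn = 370L, stages = list(c(2, 3, 1)), hidden = 2L)
  cfg <- train_config(epochs = 1, batch_size = 4, learning_rate = 5e-3,
                      loss = "categorical_crossentropy", seed = 2)
  m <- train_delineator(ds$noisy, cfg, spec)
  path <- withr::local_tempfile(fileext = ".json")
  save_delineator(m, path)
  m2 <- load_delineator(path)
  p1 <- delineate(m, ds$noisy[[1]])
  p2 <- delineate(m2, ds$noisy[[1]])
  expect_equal(p1$probabilities, p2$probabilities, tolerance = 1e-12)
})
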