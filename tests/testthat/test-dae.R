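# Auto-encoder math against dense matrix oracles, SNR definition cases,
# gradient correctness, and training-behaviour contracts.

test_that("encode and decode match element-by-element oracles on small instances", {
  # brute-force oracle: explicit loops, no matrix ops
  oracle_affine <- function(W, x, b) {
    out <- numeric(nrow(W))
    for (i in seq_len(nrow(W))) {
      acc <- b[i]
      for (j in seq_len(ncol(W))) acc <- acc + W[i, j] * x[j]
      out[i] <- acc
    }
    out
  }
  withr::with_seed(31, {
    for (rep in 1:20) {
      h <- sample(1:8, 1); d <- sample(1:8, 1)
      p <- dae_params(h, matrix(stats::rnorm(h * d), h, d), stats::rnorm(h),
                      matrix(stats::rnorm(h * d), d, h), stats::rnorm(d),
                      input_size = d)
      x <- stats::rnorm(d)
      expect_equal(dae_encode(p, x), pmax(oracle_affine(p$W, x, p$b), 0),
                   tolerance = 1e-10)
      y <- dae_encode(p, x)
      expect_equal(dae_decode(p, y),
                   1 / (1 + exp(-oracle_affine(p$W_prime, y, p$b_prime))),
                   tolerance = 1e-10)
    }
  })
})

test_that("degenerate parameter cases behave as the maps dictate", {
  d <- 6L
  p0 <- dae_params(d, matrix(0, d, d), rep(0, d), matrix(0, d, d), rep(0, d),
                   input_size = d)
  x <- stats::rnorm(d)
  expect_equal(dae_encode(p0, x), rep(0, d))           # ReLU(0) = 0
  expect_equal(dae_decode(p0, rep(0, d)), rep(0.5, d)) # sigmoid(0) = 0.5
  pid <- dae_params(d, diag(d), rep(0, d), diag(d), rep(0, d),
                    phi = "identity", phi_prime = "identity", input_size = d)
  expect_equal(dae_encode(pid, x), x)
  # sigmoid decoder output always lies strictly in (0, 1)
  pr <- dae_params(d, diag(d), rep(0, d),
                   matrix(stats::rnorm(d * d, sd = 3), d, d),
                   stats::rnorm(d), input_size = d)
  z <- dae_decode(pr, stats::rnorm(d))
  expect_true(all(z > 0 & z < 1))
  expect_error(dae_encode(p0, stats::rnorm(3)), "length")
})

test_that("reconstruction loss is the batch mean of squared L2 residuals", {
  x <- matrix(stats::rnorm(20), 4, 5)
  expect_equal(reconstruction_loss(x, x), 0)
  z <- x; z[1, 1] <- z[1, 1] - 1  # unit residual in one sample
  expect_equal(reconstruction_loss(x, z), 1 / 4)
  one <- matrix(c(1, rep(0, 9)), 1, 10)
  expect_equal(reconstruction_loss(one, matrix(0, 1, 10)), 1)
  # elementwise-sum oracle on a random batch
  withr::with_seed(8, {
    a <- matrix(stats::rnorm(30), 3, 10)
    b <- matrix(stats::rnorm(30), 3, 10)
    acc <- 0
    for (i in 1:3) for (j in 1:10) acc <- acc + (a[i, j] - b[i, j])^2
    expect_equal(reconstruction_loss(a, b), acc / 3, tolerance = 1e-12)
  })
  expect_error(reconstruction_loss(matrix(0, 0, 5), matrix(0, 0, 5)), "empty")
})

test_that("snr_db implements the power-ratio definition", {
  ref <- c(3, -4, 5, 1)
  # noise power == signal power -> 0 dB
  noise0 <- ref / sqrt(sum(ref^2)) * sqrt(sum(ref^2))  # same power
  expect_equal(snr_db(ref, ref + rev(noise0)), 0, tolerance = 1e-12)
  # noise power == signal power / 10 -> 10 dB
  noise10 <- rev(ref) / sqrt(10)
  expect_equal(snr_db(ref, ref + noise10), 10, tolerance = 1e-12)
  # random vectors against the direct ratio
  withr::with_seed(12, {
    for (rep in 1:50) {
      r <- stats::rnorm(30); e <- r + stats::rnorm(30, sd = 0.3)
      expect_equal(snr_db(r, e), 10 * log10(sum(r^2) / sum((r - e)^2)),
                   tolerance = 1e-12)
    }
  })
  expect_identical(snr_db(ref, ref), Inf)
  expect_error(snr_db(rep(0, 4), ref), "identically zero")
})

test_that("analytic gradients match finite differences on a tiny instance", {
  withr::with_seed(2, {
    p <- ecgwave:::local_seed(2, ecgwave:::init_dae(4L, 6L,
                                                    target_means = stats::runif(6)))
    Xb <- matrix(stats::runif(12), 2, 6)
    Tb <- matrix(stats::runif(12), 2, 6)
    fwd <- ecgwave:::dae_forward(p, Xb)
    g <- ecgwave:::dae_backward(p, Xb, Tb, fwd)
    lf <- function(q) reconstruction_loss(Tb, ecgwave:::dae_forward(q, Xb)$Z)
    eps <- 1e-6
    for (nm in c("W", "b", "W_prime", "b_prime")) {
      for (i in seq_along(p[[nm]])) {
        pp <- p; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- p; pm[[nm]][i] <- pm[[nm]][i] - eps
        num <- (lf(pp) - lf(pm)) / (2 * eps)
        expect_equal(g[[nm]][i], num, tolerance = 1e-5)
      }
    }
  })
})

test_that("training is seed-deterministic, rejects bad configs, loss decreases", {
  ds <- generate_dataset(16, seed = 44)
  cfg <- train_config(epochs = 3, batch_size = 4, learning_rate = 5e-3,
                      seed = 5)
  m1 <- train_dae(ds, cfg, arch = "model2")
  m2 <- train_dae(ds, cfg, arch = "model2")
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(m1$params$W, m2$params$W)
  expect_lt(utils::tail(m1$loss_history, 1), m1$loss_history[1])
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(learning_rate = 0), "learning_rate")
  # architecture sizes per the two layouts
  expect_equal(train_dae(ds, cfg, arch = "model1")$params$hidden_size, 185L)
  expect_equal(m1$params$hidden_size, 370L)
})

test_that("denoise carries labels through, keeps PAD at zero, composes encode/decode", {
  ds <- generate_dataset(8, seed = 15)
  cfg <- train_config(epochs = 2, batch_size = 4, learning_rate = 5e-3,
                      seed = 5)
  m <- train_dae(ds, cfg)
  den <- dae_denoise(m, ds$noisy[[1]])
  expect_length(den$samples, 370)
  expect_identical(den$labels, ds$noisy[[1]]$labels)
  expect_true(all(den$samples[den$labels == "PAD"] == 0))
  # pipeline equals encode -> decode called separately (modulo normalisation)
  x <- ds$noisy[[1]]$samples
  nrm <- ecgwave:::frame_norm(x)
  xin <- (x - nrm["lo"]) / (nrm["hi"] - nrm["lo"])
  z <- dae_decode(m$params, dae_encode(m$params, xin))
  z <- z * (nrm["hi"] - nrm["lo"]) + nrm["lo"]
  z[den$labels == "PAD"] <- 0
  expect_equal(den$samples, unname(z), tolerance = 1e-12)
})

test_that("a trained model serialises and reloads to identical reconstructions", {
  ds <- generate_dataset(8, seed = 16)
  m <- train_dae(ds, train_config(epochs = 2, batch_size = 4,
                                  learning_rate = 5e-3, seed = 1))
  path <- withr::local_tempfile(fileext = ".json")
  save_dae(m, path)
  m2 <- load_dae(path)
  expect_equal(dae_denoise(m2, ds$noisy[[2]])$samples,
               dae_denoise(m, ds$noisy[[2]])$samples, tolerance = 1e-12)
})
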