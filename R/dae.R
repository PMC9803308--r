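#' Denoising auto-encoder parameters
#'
#' One fully-connected encoder/decoder pair over 370-sample beats. The
#' encoder maps an input beat `x` to a hidden representation
#' `y = phi(W x + b)`; the decoder reconstructs `z = phi'(W' y + b')`. Two
#' standard layouts are supported: model 1 compresses to 185 hidden nodes,
#' model 2 keeps 370.
#'
#' @param hidden_size Hidden-layer width (185 for model 1, 370 for model 2).
#' @param W Encoder weights, `hidden_size x 370`.
#' @param b Encoder bias, length `hidden_size`.
#' @param W_prime Decoder weights, `370 x hidden_size`.
#' @param b_prime Decoder bias, length 370.
#' @param phi Encoder activation name (default `"ReLU"`).
#' @param phi_prime Decoder activation name (default `"sigmoid"`).
#' @param input_size Input width (370 beat frames; configurable for small
#'   oracle tests).
#' @return An object of class `dae_params`.
#' @export
dae_params <- function(hidden_size, W, b, W_prime, b_prime,
                       phi = "ReLU", phi_prime = "sigmoid",
                       input_size = frame_length()) {
  activation(phi); activation(phi_prime)
  p <- structure(list(W = W, b = as.numeric(b), W_prime = W_prime,
                      b_prime = as.numeric(b_prime), phi = phi,
                      phi_prime = phi_prime,
                      hidden_size = as.integer(hidden_size),
                      input_size = as.integer(input_size)),
                 class = "dae_params")
  if (!all(dim(p$W) == c(p$hidden_size, p$input_size)))
    stop("dae_params: W must be hidden_size x input_size")
  if (length(p$b) != p$hidden_size)
    stop("dae_params: b must have length hidden_size")
  if (!all(dim(p$W_prime) == c(p$input_size, p$hidden_size)))
    stop("dae_params: W_prime must be input_size x hidden_size")
  if (length(p$b_prime) != p$input_size)
    stop("dae_params: b_prime must have length input_size")
  p
}

# Internal: Glorot-initialised parameters, optional per-output bias from
# target means (standard practice for sigmoid output layers: the output bias
# is set to the logit of the clamped per-position mean target, so training
# starts from the dataset's baseline rather than 0.5 everywhere).
init_dae <- function(hidden_size, input_size = frame_length(),
                     target_means = NULL) {
  W <- glorot(hidden_size, input_size, fan_in = input_size,
              fan_out = hidden_size)
  W_prime <- glorot(input_size, hidden_size, fan_in = hidden_size,
                    fan_out = input_size)
  b_prime <- rep(0, input_size)
  if (!is.null(target_means)) {
    m <- pmin(pmax(target_means, 1e-3), 1 - 1e-3)
    b_prime <- log(m / (1 - m))
  }
  dae_params(hidden_size, W, rep(0, hidden_size), W_prime, b_prime,
             input_size = input_size)
}

#' Encode a beat
#'
#' `y = phi(W x + b)`.
#'
#' @param params A [dae_params()].
#' @param x Numeric vector of length `params$input_size`.
#' @return Hidden representation, length `params$hidden_size`.
#' @export
dae_encode <- function(params, x) {
  if (length(x) != params$input_size)
    stop("dae_encode: x must have length ", params$input_size)
  act <- activation(params$phi)
  pre <- drop(params$W %*% x) + params$b
  act$f(pre)
}

#' Decode a hidden representation
#'
#' `z = phi'(W' y + b')`. With the default sigmoid output every component
#' lies in (0, 1).
#'
#' @param params A [dae_params()].
#' @param y Hidden vector of length `params$hidden_size`.
#' @return Reconstructed beat, length `params$input_size`.
#' @export
dae_decode <- function(params, y) {
  if (length(y) != params$hidden_size)
    stop("dae_decode: y must have length ", params$hidden_size)
  act <- activation(params$phi_prime)
  pre <- drop(params$W_prime %*% y) + params$b_prime
  act$f(pre)
}

#' Mean squared reconstruction loss
#'
#' `(1/N) * sum_i || x_i - z_i ||^2`: the squared L2 residual of each beat,
#' averaged over the batch. Zero iff the batches are identical.
#'
#' @param clean_batch,reconstructed_batch Numeric matrices, beats in rows
#'   (a single vector is treated as one row).
#' @return Non-negative scalar.
#' @export
reconstruction_loss <- function(clean_batch, reconstructed_batch) {
  x <- rbind(clean_batch)
  z <- rbind(reconstructed_batch)
  if (!all(dim(x) == dim(z)))
    stop("reconstruction_loss: shape mismatch")
  if (nrow(x) == 0L) stop("reconstruction_loss: empty batch")
  sum((x - z)^2) / nrow(x)
}

#' Signal-to-noise ratio in decibels
#'
#' `10 * log10( sum(reference^2) / sum((reference - estimate)^2) )`. A
#' perfect estimate returns `Inf` (a distinguished value, not an error).
#'
#' @param reference Clean signal (not identically zero).
#' @param estimate Reconstructed / noisy signal, same length.
#' @return SNR in dB.
#' @export
snr_db <- function(reference, estimate) {
  if (length(reference) != length(estimate))
    stop("snr_db: length mismatch")
  sp <- sum(reference^2)
  if (sp == 0) stop("snr_db: reference is identically zero")
  np <- sum((reference - estimate)^2)
  if (np == 0) return(Inf)
  10 * log10(sp / np)
}

# Internal batched forward pass; X is batch x input (already normalised).
dae_forward <- function(params, X) {
  act1 <- activation(params$phi)
  act2 <- activation(params$phi_prime)
  Hpre <- X %*% t(params$W) + rep(params$b, each = nrow(X))
  H <- act1$f(Hpre)
  Zpre <- H %*% t(params$W_prime) + rep(params$b_prime, each = nrow(X))
  Z <- act2$f(Zpre)
  list(Hpre = Hpre, H = H, Zpre = Zpre, Z = Z)
}

# Internal: gradients of reconstruction_loss wrt params for one batch.
dae_backward <- function(params, X, Tg, fwd) {
  act1 <- activation(params$phi)
  act2 <- activation(params$phi_prime)
  B <- nrow(X)
  dZ <- 2 * (fwd$Z - Tg) / B
  dZpre <- dZ * act2$df(fwd$Zpre, fwd$Z)
  dW_prime <- t(dZpre) %*% fwd$H
  db_prime <- colSums(dZpre)
  dH <- dZpre %*% params$W_prime
  dHpre <- dH * act1$df(fwd$Hpre, fwd$H)
  list(W = t(dHpre) %*% X, b = colSums(dHpre),
       W_prime = dW_prime, b_prime = db_prime)
}

# Internal: per-frame min-max normalisation constants from the noisy input
frame_norm <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi <= lo) hi <- lo + 1
  c(lo = lo, hi = hi)
}

#' Train a denoising auto-encoder
#'
#' Trains on paired (clean, noisy) beat frames: the noisy beat is the input,
#' the clean beat the target, minimising the mean squared reconstruction
#' error with Adam. Each frame is min-max normalised to `[0, 1]` using its
#' noisy input's range (inverted on output), matching the sigmoid decoder.
#' The run is deterministic given `cfg$seed`.
#'
#' @param pairs A `beat_dataset` from [generate_dataset()], or a list with
#'   `clean` and `noisy` lists of [beat_frame()].
#' @param cfg A [train_config()].
#' @param arch `"model1"` (370-185 layout) or `"model2"` (370-370).
#' @param normalize `"minmax"` (default) or `"none"`.
#' @return An object of class `dae_model`: `params`, `loss_history`,
#'   `config`, `arch`, `normalize`.
#' @export
train_dae <- function(pairs, cfg = train_config(), arch = c("model2", "model1"),
                      normalize = c("minmax", "none")) {
  arch <- match.arg(arch)
  normalize <- match.arg(normalize)
  stopifnot(length(pairs$clean) >= 1,
            length(pairs$clean) == length(pairs$noisy))
  hidden <- if (arch == "model1") 185L else 370L
  n <- length(pairs$clean)
  d <- frame_length()
  X <- t(vapply(pairs$noisy, function(f) f$samples, numeric(d)))
  Tg <- t(vapply(pairs$clean, function(f) f$samples, numeric(d)))
  norms <- t(apply(X, 1, frame_norm))
  if (normalize == "minmax") {
    X <- (X - norms[, "lo"]) / (norms[, "hi"] - norms[, "lo"])
    Tg <- (Tg - norms[, "lo"]) / (norms[, "hi"] - norms[, "lo"])
  }
  loss_hist <- numeric(cfg$epochs)
  params <- local_seed(cfg$seed, {
    params <- unclass(init_dae(hidden, d, target_means = colMeans(Tg)))
    opt_names <- c("W", "b", "W_prime", "b_prime")
    state <- adam_init(params[opt_names])
    for (ep in seq_len(cfg$epochs)) {
      lr <- epoch_lr(cfg, ep)
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        Tb <- Tg[idx, , drop = FALSE]
        p <- do.call(dae_params, c(params[opt_names],
                                   list(hidden_size = hidden, input_size = d)))
        fwd <- dae_forward(p, Xb)
        loss <- reconstruction_loss(Tb, fwd$Z)
        if (!is.finite(loss))
          stop("train_dae: loss diverged (non-finite) at epoch ", ep)
        grads <- dae_backward(p, Xb, Tb, fwd)
        upd <- adam_step(state, params[opt_names], grads, lr)
        state <- upd$state
        params[opt_names] <- upd$params
        ep_loss <- ep_loss + loss * length(idx)
      }
      loss_hist[ep] <- ep_loss / n
    }
    params
  })
  structure(list(
    params = do.call(dae_params,
                     c(params[c("W", "b", "W_prime", "b_prime")],
                       list(hidden_size = hidden, input_size = d))),
    loss_history = loss_hist, config = cfg, arch = arch,
    normalize = normalize), class = "dae_model")
}

#' @export
print.dae_model <- function(x, ...) {
  cat(sprintf("<dae_model> %s (hidden %d), %d epochs, final loss %.4g\n",
              x$arch, x$params$hidden_size, length(x$loss_history),
              utils::tail(x$loss_history, 1)))
  invisible(x)
}

#' Denoise a beat frame
#'
#' Runs encode-decode on the frame's samples (with the model's per-frame
#' normalisation applied and inverted); labels and sampling rate are carried
#' through unchanged. Zero-padding samples are exactly zero on input, and
#' the reconstruction's padding tail is re-zeroed so the output remains a
#' valid beat frame.
#'
#' @param model A [train_dae()] result (or a bare [dae_params()]).
#' @param noisy A [beat_frame()] (or a bare numeric vector of length 370).
#' @return Denoised [beat_frame()] (or numeric vector).
#' @export
dae_denoise <- function(model, noisy) {
  params <- if (inherits(model, "dae_model")) model$params else model
  normalize <- if (inherits(model, "dae_model")) model$normalize else "minmax"
  x <- if (inherits(noisy, "beat_frame")) noisy$samples else as.numeric(noisy)
  nrm <- frame_norm(x)
  xin <- if (normalize == "minmax") (x - nrm["lo"]) / (nrm["hi"] - nrm["lo"]) else x
  z <- dae_decode(params, dae_encode(params, xin))
  if (normalize == "minmax") z <- z * (nrm["hi"] - nrm["lo"]) + nrm["lo"]
  if (inherits(noisy, "beat_frame")) {
    out <- noisy
    z[noisy$labels == "PAD"] <- 0
    out$samples <- z
    out
  } else z
}

#' Reconstruction SNR of a model over held-out pairs
#'
#' Denoises each held-out noisy frame and scores it against its clean twin
#' with [snr_db()]. Reported per beat and as the mean.
#'
#' @param model A `dae_model`.
#' @param pairs Held-out `beat_dataset`.
#' @return List with `per_beat` (dB vector) and `mean` (dB).
#' @export
dae_heldout_snr <- function(model, pairs) {
  per <- vapply(seq_along(pairs$clean), function(i) {
    den <- dae_denoise(model, pairs$noisy[[i]])
    snr_db(pairs$clean[[i]]$samples, den$samples)
  }, numeric(1))
  list(per_beat = per, mean = mean(per))
}

#' Descriptive reconstruction accuracy surrogate
#'
#' Fraction of samples reconstructed within `eps` of the clean target, over
#' a paired dataset. Reported descriptively alongside SNR for regression
#' reconstructions (a classification-style "accuracy" has no canonical
#' definition for this task).
#'
#' @param model A `dae_model`.
#' @param pairs Held-out `beat_dataset`.
#' @param eps Absolute tolerance per sample (default 0.05).
#' @return Fraction in `[0, 1]`.
#' @export
dae_sample_accuracy <- function(model, pairs, eps = 0.05) {
  hits <- vapply(seq_along(pairs$clean), function(i) {
    den <- dae_denoise(model, pairs$noisy[[i]])
    mean(abs(den$samples - pairs$clean[[i]]$samples) <= eps)
  }, numeric(1))
  mean(hits)
}

#' Save / load a trained auto-encoder
#'
#' Versioned plain-text serialisation: a JSON header (shapes, activations,
#' normalisation mode) plus flat weight arrays.
#'
#' @param model A `dae_model`.
#' @param path File path.
#' @return `path` invisibly (writer); a `dae_model` (reader).
#' @export
save_dae <- function(model, path) {
  p <- model$params
  obj <- list(format = "ecgwave-dae", version = 1L,
              arch = model$arch, normalize = model$normalize,
              hidden_size = p$hidden_size, input_size = p$input_size,
              phi = p$phi, phi_prime = p$phi_prime,
              W = as.numeric(p$W), b = p$b,
              W_prime = as.numeric(p$W_prime), b_prime = p$b_prime,
              loss_history = model$loss_history)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_dae
#' @export
load_dae <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "ecgwave-dae"))
    stop("load_dae: not an ecgwave DAE file: ", path)
  params <- dae_params(obj$hidden_size,
                       matrix(obj$W, obj$hidden_size, obj$input_size),
                       obj$b,
                       matrix(obj$W_prime, obj$input_size, obj$hidden_size),
                       obj$b_prime, phi = obj$phi, phi_prime = obj$phi_prime,
                       input_size = obj$input_size)
  structure(list(params = params, loss_history = obj$loss_history,
                 config = NULL, arch = obj$arch, normalize = obj$normalize),
            class = "dae_model")
}
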