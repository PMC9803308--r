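# Batched end-to-end forward/backward for the Conv+BiLSTM delineator, plus
# the trainer and the user-facing delineate().

# full forward over a batch; X is B x T matrix of samples
delin_forward <- function(spec, w, X) {
  B <- nrow(X); Tn <- spec$sequence_length
  act <- activation(spec$conv_activation)
  A <- array(t(X), c(Tn, B, spec$in_channels))
  conv_cache <- list()
  for (l in seq_along(spec$conv_stages)) {
    st <- conv_stage_forward(w[[paste0("c", l, ".W")]],
                             w[[paste0("c", l, ".b")]], A, act)
    conv_cache[[l]] <- list(input = A, pre = st$pre)
    A <- st$out
  }
  fw <- lstm_forward(w[["f.Wx"]], w[["f.Wh"]], w[["f.b"]], A, +1)
  bw <- lstm_forward(w[["b.Wx"]], w[["b.Wh"]], w[["b.b"]], A, -1)
  H <- fw$H
  Hcat <- cbind(matrix(aperm(fw$Hs, c(3, 1, 2)), Tn * B, H),
                matrix(aperm(bw$Hs, c(3, 1, 2)), Tn * B, H))
  logits <- Hcat %*% w[["o.W"]] + rep(w[["o.b"]], each = Tn * B)
  P <- softmax_rows(logits)
  list(conv_cache = conv_cache, feat = A, fw = fw, bw = bw,
       Hcat = Hcat, P = P, B = B, Tn = Tn, H = H)
}

# mean categorical cross-entropy; Y is (T*B) x K one-hot
delin_loss <- function(P, Y) {
  -mean(log(pmax(rowSums(P * Y), 1e-12)))
}

delin_backward <- function(spec, w, fwd, Y) {
  B <- fwd$B; Tn <- fwd$Tn; H <- fwd$H
  act <- activation(spec$conv_activation)
  n <- Tn * B
  dlogits <- (fwd$P - Y) / n
  grads <- list()
  grads[["o.W"]] <- t(fwd$Hcat) %*% dlogits
  grads[["o.b"]] <- colSums(dlogits)
  dHcat <- dlogits %*% t(w[["o.W"]])
  dHf <- aperm(array(dHcat[, 1:H], c(Tn, B, H)), c(2, 3, 1))
  dHb <- aperm(array(dHcat[, (H + 1):(2 * H)], c(Tn, B, H)), c(2, 3, 1))
  gf <- lstm_backward(w[["f.Wx"]], w[["f.Wh"]], w[["f.b"]], fwd$feat, fwd$fw, dHf)
  gb <- lstm_backward(w[["b.Wx"]], w[["b.Wh"]], w[["b.b"]], fwd$feat, fwd$bw, dHb)
  grads[["f.Wx"]] <- gf$dWx; grads[["f.Wh"]] <- gf$dWh; grads[["f.b"]] <- gf$db
  grads[["b.Wx"]] <- gb$dWx; grads[["b.Wh"]] <- gb$dWh; grads[["b.b"]] <- gb$db
  dA <- gf$dX + gb$dX
  for (l in rev(seq_along(spec$conv_stages))) {
    cc <- fwd$conv_cache[[l]]
    g <- conv_stage_backward(w[[paste0("c", l, ".W")]], cc$input, cc$pre, dA, act)
    grads[[paste0("c", l, ".W")]] <- g$dW
    grads[[paste0("c", l, ".b")]] <- g$db
    dA <- g$dA
  }
  grads
}

# frames -> (B x T samples matrix, (T*B) x K one-hot labels)
frames_to_xy <- function(frames, n_classes = 5L) {
  Tn <- frame_length()
  X <- t(vapply(frames, function(f) f$samples, numeric(Tn)))
  lab <- vapply(frames, function(f)
    match(f$labels, ecg_classes()), integer(Tn))  # Tn x B
  list(X = X, lab = lab)
}

onehot <- function(lab_mat, n_classes) {
  # lab_mat: Tn x B integer classes -> (Tn*B) x K
  v <- as.integer(lab_mat)
  Y <- matrix(0, length(v), n_classes)
  Y[cbind(seq_along(v), v)] <- 1
  Y
}

#' Train the Conv+BiLSTM delineator
#'
#' Minimises per-sample categorical cross-entropy over labeled beat frames
#' with Adam. Deterministic given `cfg$seed`; training stops with an error
#' naming the epoch if the loss becomes non-finite.
#'
#' @param frames List of labeled [beat_frame()] objects (clean, noisy or
#'   denoised — whatever the deployment input will be).
#' @param cfg A [train_config()] (use `loss = "categorical_crossentropy"`).
#' @param spec A [delineator_spec()].
#' @return An object of class `delineator_model`: `spec`, `weights`,
#'   `loss_history`, `config`.
#' @export
train_delineator <- function(frames,
                             cfg = train_config(epochs = 30, batch_size = 8,
                                                learning_rate = 5e-3,
                                                loss = "categorical_crossentropy"),
                             spec = delineator_spec()) {
  stopifnot(length(frames) >= 1)
  xy <- frames_to_xy(frames, spec$n_classes)
  n <- nrow(xy$X)
  loss_hist <- numeric(cfg$epochs)
  w <- local_seed(cfg$seed, {
    w <- init_delineator(spec)
    state <- adam_init(w)
    for (ep in seq_len(cfg$epochs)) {
      lr <- epoch_lr(cfg, ep)
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        Xb <- xy$X[idx, , drop = FALSE]
        Yb <- onehot(xy$lab[, idx, drop = FALSE], spec$n_classes)
        fwd <- delin_forward(spec, w, Xb)
        loss <- delin_loss(fwd$P, Yb)
        if (!is.finite(loss))
          stop("train_delineator: loss diverged (non-finite) at epoch ", ep)
        grads <- delin_backward(spec, w, fwd, Yb)
        upd <- adam_step(state, w, grads, lr)
        state <- upd$state
        w <- upd$params
        ep_loss <- ep_loss + loss * length(idx)
      }
      loss_hist[ep] <- ep_loss / n
    }
    w
  })
  structure(list(spec = spec, weights = w, loss_history = loss_hist,
                 config = cfg), class = "delineator_model")
}

#' @export
print.delineator_model <- function(x, ...) {
  cat(sprintf("<delineator_model> %d conv stages, BiLSTM hidden %d, %d epochs, final loss %.4g\n",
              length(x$spec$conv_stages), x$spec$recurrent_hidden,
              length(x$loss_history), utils::tail(x$loss_history, 1)))
  invisible(x)
}

#' Delineate one beat frame
#'
#' Produces the full per-sample labeling plus derived wave boundaries:
#' onset/offset (first/last 0-based index) of each contiguous wave run, and
#' the R-peak index (argmax of the samples within the QRS run).
#'
#' @param model A [train_delineator()] result.
#' @param frame A [beat_frame()] (labels, if present, are ignored).
#' @param min_run Contiguous runs shorter than this many samples are
#'   discarded as noise when deriving boundaries (default 3).
#' @return A `delineation_result` with extra fields `waves` (data frame:
#'   `wave`, `onset`, `offset`, `peak`) and `r_peak` (index or `NA`).
#' @export
delineate <- function(model, frame, min_run = 3L) {
  stopifnot(inherits(model, "delineator_model"))
  x <- if (inherits(frame, "beat_frame")) frame$samples else as.numeric(frame)
  fwd <- delin_forward(model$spec, model$weights, matrix(x, 1))
  P <- fwd$P
  colnames(P) <- ecg_classes()[seq_len(ncol(P))]
  labels <- colnames(P)[max.col(P, ties.method = "first")]
  res <- structure(list(probabilities = P, labels = labels),
                   class = "delineation_result")
  res$waves <- wave_boundaries(labels, x, min_run = min_run)
  qrs <- res$waves[res$waves$wave == "QRS", ]
  res$r_peak <- if (nrow(qrs)) qrs$peak[which.max(
    vapply(seq_len(nrow(qrs)),
           function(i) x[qrs$peak[i] + 1L], numeric(1)))] else NA_integer_
  res
}

#' Derive wave boundaries from a per-sample labeling
#'
#' First/last index of each contiguous P / QRS / T run (0-based, inclusive);
#' runs shorter than `min_run` samples are dropped. `peak` is the index of
#' the maximum sample within the run.
#'
#' @param labels Character label vector.
#' @param samples Matching amplitude vector.
#' @param min_run Minimum run length kept.
#' @return Data frame with columns `wave`, `onset`, `offset`, `peak`.
#' @export
wave_boundaries <- function(labels, samples, min_run = 3L) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values %in% c("P", "QRS", "T") & r$lengths >= min_run
  out <- data.frame(wave = r$values[keep],
                    onset = starts[keep] - 1L, offset = ends[keep] - 1L)
  out$peak <- vapply(seq_len(nrow(out)), function(i) {
    seg <- out$onset[i]:out$offset[i]
    seg[which.max(samples[seg + 1L])]
  }, integer(1))
  out
}

#' Per-sample delineation accuracy against ground truth
#'
#' @param model A `delineator_model`.
#' @param frames Labeled held-out frames.
#' @return List: `overall` accuracy, `per_class` named accuracy vector
#'   (recall per true class).
#' @export
delineator_accuracy <- function(model, frames) {
  xy <- frames_to_xy(frames, model$spec$n_classes)
  fwd <- delin_forward(model$spec, model$weights, xy$X)
  pred <- max.col(fwd$P, ties.method = "first")
  truth <- as.integer(xy$lab)
  per <- vapply(seq_len(model$spec$n_classes), function(k) {
    idx <- truth == k
    if (!any(idx)) NA_real_ else mean(pred[idx] == k)
  }, numeric(1))
  names(per) <- ecg_classes()[seq_len(model$spec$n_classes)]
  list(overall = mean(pred == truth), per_class = per)
}

#' Predicted class probabilities for a set of frames
#'
#' @param model A `delineator_model`.
#' @param frames List of [beat_frame()].
#' @return List with `probabilities` ((n_frames*370) x 5 matrix, frames
#'   stacked), `labels` (character vector) and `truth` (character vector of
#'   ground-truth labels).
#' @export
delineator_predictions <- function(model, frames) {
  xy <- frames_to_xy(frames, model$spec$n_classes)
  fwd <- delin_forward(model$spec, model$weights, xy$X)
  P <- fwd$P
  colnames(P) <- ecg_classes()[seq_len(ncol(P))]
  list(probabilities = P,
       labels = colnames(P)[max.col(P, ties.method = "first")],
       truth = ecg_classes()[as.integer(xy$lab)])
}

#' Save / load a trained delineator
#'
#' Versioned plain-text serialisation (JSON header + flat weight arrays).
#'
#' @param model A `delineator_model`.
#' @param path File path.
#' @return `path` invisibly (writer); a `delineator_model` (reader).
#' @export
save_delineator <- function(model, path) {
  w <- model$weights
  obj <- list(format = "ecgwave-delineator", version = 1L,
              spec = unclass(model$spec),
              weight_names = names(w),
              weight_dims = lapply(w, function(p) dim(p) %||% length(p)),
              weights = lapply(w, as.numeric),
              loss_history = model$loss_history)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_delineator
#' @export
load_delineator <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "ecgwave-delineator"))
    stop("load_delineator: not an ecgwave delineator file: ", path)
  sp <- obj$spec
  spec <- delineator_spec(conv_stages = lapply(seq_len(nrow(sp$conv_stages) %||% length(sp$conv_stages)),
                                               function(i) as.numeric(if (is.matrix(sp$conv_stages)) sp$conv_stages[i, ] else sp$conv_stages[[i]])),
                          recurrent_hidden = sp$recurrent_hidden,
                          n_classes = sp$n_classes,
                          sequence_length = sp$sequence_length,
                          conv_activation = sp$conv_activation,
                          in_channels = sp$in_channels)
  w <- lapply(names(obj$weights), function(nm) {
    d <- obj$weight_dims[[nm]]
    v <- obj$weights[[nm]]
    if (length(d) > 1) array(v, unlist(d)) else as.numeric(v)
  })
  names(w) <- names(obj$weights)
  structure(list(spec = spec, weights = w, loss_history = obj$loss_history,
                 config = NULL), class = "delineator_model")
}
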