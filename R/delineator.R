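#' Delineator architecture description
#'
#' Four 1-D convolutional stages (8, 16, 32, 64 filters, kernel 3, stride 1,
#' ReLU, zero-padded so the 370-sample length is preserved) followed by a
#' single bidirectional LSTM layer and a per-position affine + softmax head
#' over the five classes P / QRS / T / ISO / PAD. Stage layout and hidden
#' size are overridable for small oracle tests.
#'
#' @param conv_stages List of `c(filters, kernel, stride)` triples; stride
#'   must be 1.
#' @param recurrent_hidden LSTM hidden size per direction (default 64).
#' @param n_classes Number of output classes (5).
#' @param sequence_length Input length (370).
#' @param conv_activation Activation after each conv stage.
#' @param in_channels Input channel count (1 for a single lead).
#' @return An object of class `delineator_spec`.
#' @export
delineator_spec <- function(conv_stages = list(c(8, 3, 1), c(16, 3, 1),
                                               c(32, 3, 1), c(64, 3, 1)),
                            recurrent_hidden = 64L, n_classes = 5L,
                            sequence_length = frame_length(),
                            conv_activation = "ReLU", in_channels = 1L) {
  for (st in conv_stages) {
    if (length(st) != 3) stop("each conv stage is c(filters, kernel, stride)")
    if (st[3] != 1) stop("delineator_spec: stride must be 1")
    if (st[2] %% 2 != 1) stop("delineator_spec: kernel must be odd")
  }
  activation(conv_activation)
  structure(list(conv_stages = conv_stages,
                 recurrent_hidden = as.integer(recurrent_hidden),
                 n_classes = as.integer(n_classes),
                 sequence_length = as.integer(sequence_length),
                 conv_activation = conv_activation,
                 in_channels = as.integer(in_channels)),
            class = "delineator_spec")
}

# ---- weight initialisation -------------------------------------------------

init_delineator <- function(spec) {
  w <- list()
  cin <- spec$in_channels
  for (l in seq_along(spec$conv_stages)) {
    st <- spec$conv_stages[[l]]
    cout <- st[1]; k <- st[2]
    lim <- sqrt(6 / (k * cin + cout))
    w[[paste0("c", l, ".W")]] <-
      array(stats::runif(k * cin * cout, -lim, lim), dim = c(k, cin, cout))
    w[[paste0("c", l, ".b")]] <- rep(0, cout)
    cin <- cout
  }
  H <- spec$recurrent_hidden
  for (d in c("f", "b")) {
    w[[paste0(d, ".Wx")]] <- glorot(cin, 4 * H, fan_in = cin, fan_out = 4 * H)
    w[[paste0(d, ".Wh")]] <- glorot(H, 4 * H, fan_in = H, fan_out = 4 * H)
    bias <- rep(0, 4 * H)
    bias[(H + 1):(2 * H)] <- 1  # forget-gate bias init
    w[[paste0(d, ".b")]] <- bias
  }
  w[["o.W"]] <- glorot(2 * H, spec$n_classes, fan_in = 2 * H,
                       fan_out = spec$n_classes)
  w[["o.b"]] <- rep(0, spec$n_classes)
  w
}

# ---- convolution -----------------------------------------------------------

# shift array A (T,B,C) along time by s: out[t,,] = A[t+s,,], zero outside
shift_time <- function(A, s) {
  d <- dim(A)
  out <- array(0, d)
  t_out <- seq_len(d[1])
  keep <- t_out + s >= 1 & t_out + s <= d[1]
  out[t_out[keep], , ] <- A[t_out[keep] + s, , , drop = FALSE]
  out
}

# one conv stage forward on A (T,B,Cin) -> list(pre, out) each (T,B,Cout)
conv_stage_forward <- function(W, b, A, act) {
  d <- dim(A); Tn <- d[1]; B <- d[2]; cin <- d[3]
  k <- dim(W)[1]; cout <- dim(W)[3]
  half <- (k - 1) / 2
  Zmat <- matrix(rep(b, each = Tn * B), Tn * B, cout)
  for (kk in seq_len(k)) {
    As <- shift_time(A, kk - 1 - half)
    Zmat <- Zmat + matrix(As, Tn * B, cin) %*% matrix(W[kk, , ], cin, cout)
  }
  pre <- array(Zmat, c(Tn, B, cout))
  list(pre = pre, out = array(act$f(Zmat), c(Tn, B, cout)))
}

conv_stage_backward <- function(W, A, pre, dOut, act) {
  d <- dim(A); Tn <- d[1]; B <- d[2]; cin <- d[3]
  k <- dim(W)[1]; cout <- dim(W)[3]
  half <- (k - 1) / 2
  dZmat <- matrix(dOut, Tn * B, cout) *
    matrix(act$df(pre, act$f(pre)), Tn * B, cout)
  dW <- array(0, dim(W))
  dA <- array(0, d)
  for (kk in seq_len(k)) {
    s <- kk - 1 - half
    As <- shift_time(A, s)
    dW[kk, , ] <- t(matrix(As, Tn * B, cin)) %*% dZmat
    dAs <- array(dZmat %*% t(matrix(W[kk, , ], cin, cout)), c(Tn, B, cin))
    dA <- dA + shift_time(dAs, -s)
  }
  list(dW = dW, db = colSums(dZmat), dA = dA)
}

#' Convolutional feature extraction
#'
#' Applies the spec's convolution stages in order to a single beat's
#' amplitude vector, preserving the sequence length at every stage
#' (zero-padded, "same" convolution), and returns the final feature map.
#'
#' @param weights Delineator weights (from [train_delineator()]'s model via
#'   `model$weights`, or [init_delineator] internals for tests).
#' @param x Numeric vector of length `spec$sequence_length`.
#' @param spec A [delineator_spec()].
#' @return Feature-map matrix, `sequence_length x last_stage_filters`.
#' @export
conv_features <- function(weights, x, spec = delineator_spec()) {
  if (length(x) != spec$sequence_length)
    stop("conv_features: x must have length ", spec$sequence_length)
  act <- activation(spec$conv_activation)
  A <- array(x, c(spec$sequence_length, 1, spec$in_channels))
  for (l in seq_along(spec$conv_stages)) {
    st <- conv_stage_forward(weights[[paste0("c", l, ".W")]],
                             weights[[paste0("c", l, ".b")]], A, act)
    A <- st$out
  }
  matrix(A, spec$sequence_length, dim(A)[3])
}

# ---- bidirectional LSTM ----------------------------------------------------

# forward pass of one direction over Xarr (T,B,C); dir +1 or -1.
# The input projection is one large BLAS product; the sequential recurrence
# runs in compiled code. State layout is (B, *, T).
lstm_forward <- function(Wx, Wh, b, Xarr, dir) {
  d <- dim(Xarr); Tn <- d[1]; B <- d[2]; C <- d[3]
  H <- ncol(Wh) / 4
  Xp_mat <- matrix(Xarr, Tn * B, C) %*% Wx + rep(b, each = Tn * B)
  Xp <- aperm(array(Xp_mat, c(Tn, B, 4 * H)), c(2, 3, 1))  # (B, 4H, T)
  out <- .lstm_forward_cpp(Xp, Wh, as.integer(dir))
  out$ord <- if (dir > 0) seq_len(Tn) else rev(seq_len(Tn))
  out$H <- H
  out
}

# backward through one direction; dH (B,H,T) is gradient into Hs
lstm_backward <- function(Wx, Wh, b, Xarr, cache, dH) {
  d <- dim(Xarr); Tn <- d[1]; B <- d[2]; C <- d[3]
  H <- cache$H
  ord <- cache$ord
  dXp <- .lstm_backward_cpp(cache$Gates, cache$Cs, cache$TC, Wh, dH,
                            as.integer(if (ord[1] == 1L) 1L else -1L))
  dXp_tbh <- aperm(dXp, c(3, 1, 2))                 # (T, B, 4H)
  dXpmat <- matrix(dXp_tbh, Tn * B, 4 * H)
  Hprev <- array(0, c(B, H, Tn))
  Hprev[, , ord[-1]] <- cache$Hs[, , ord[-length(ord)]]
  Hprev_mat <- matrix(aperm(Hprev, c(3, 1, 2)), Tn * B, H)
  list(dWx = crossprod(matrix(Xarr, Tn * B, C), dXpmat),
       dWh = crossprod(Hprev_mat, dXpmat), db = colSums(dXpmat),
       dX = array(dXpmat %*% t(Wx), c(Tn, B, C)))
}

# Plain-R reference implementations of the two kernels above. They are the
# independent oracle the unit tests check the compiled path against, and
# they document the recurrence in full.
lstm_forward_ref <- function(Wx, Wh, b, Xarr, dir) {
  d <- dim(Xarr); Tn <- d[1]; B <- d[2]; C <- d[3]
  H <- ncol(Wh) / 4
  Xp_mat <- matrix(Xarr, Tn * B, C) %*% Wx + rep(b, each = Tn * B)
  Xp <- aperm(array(Xp_mat, c(Tn, B, 4 * H)), c(2, 3, 1))  # (B, 4H, T)
  ord <- if (dir > 0) seq_len(Tn) else rev(seq_len(Tn))
  Gates <- array(0, c(B, 4 * H, Tn))  # post-nonlinearity gate values
  Cs <- TC <- Hs <- array(0, c(B, H, Tn))
  h <- matrix(0, B, H); cs <- matrix(0, B, H)
  i1 <- 1:H; i2 <- (H + 1):(2 * H); i3 <- (2 * H + 1):(3 * H)
  i4 <- (3 * H + 1):(4 * H)
  for (t in ord) {
    G <- Xp[, , t] + h %*% Wh
    if (B == 1L) dim(G) <- c(1L, 4L * H)
    A <- 1 / (1 + exp(-G))          # sigmoid for i, f, o (g overwritten)
    A[, i3] <- tanh(G[, i3])
    cs <- A[, i2] * cs + A[, i1] * A[, i3]
    tc <- tanh(cs)
    h <- A[, i4] * tc
    if (B == 1L) { dim(cs) <- c(1L, H); dim(tc) <- c(1L, H); dim(h) <- c(1L, H) }
    Gates[, , t] <- A; Cs[, , t] <- cs; TC[, , t] <- tc; Hs[, , t] <- h
  }
  list(Gates = Gates, Cs = Cs, TC = TC, Hs = Hs, ord = ord, H = H)
}

lstm_backward_ref <- function(Wx, Wh, b, Xarr, cache, dH) {
  d <- dim(Xarr); Tn <- d[1]; B <- d[2]; C <- d[3]
  H <- cache$H
  ord <- cache$ord
  dXp <- array(0, c(B, 4 * H, Tn))
  dh_rec <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  tWh <- t(Wh)
  i1 <- 1:H; i2 <- (H + 1):(2 * H); i3 <- (2 * H + 1):(3 * H)
  i4 <- (3 * H + 1):(4 * H)
  sl <- function(A, t, w) {
    out <- A[, , t]
    if (B == 1L) dim(out) <- c(1L, w)
    out
  }
  zero <- matrix(0, B, H)
  for (k in rev(seq_along(ord))) {
    t <- ord[k]
    c_prev <- if (k > 1) sl(cache$Cs, ord[k - 1], H) else zero
    A <- sl(cache$Gates, t, 4 * H)
    tc <- sl(cache$TC, t, H)
    dh <- sl(dH, t, H) + dh_rec
    ig <- A[, i1]; fg <- A[, i2]; gg <- A[, i3]; og <- A[, i4]
    dc <- dc_next + dh * og * (1 - tc^2)
    dG <- cbind((dc * gg) * ig * (1 - ig),
                (dc * c_prev) * fg * (1 - fg),
                (dc * ig) * (1 - gg^2),
                (dh * tc) * og * (1 - og))
    dc_next <- dc * fg
    dXp[, , t] <- dG
    dh_rec <- dG %*% tWh
    if (B == 1L) dim(dh_rec) <- c(1L, H)
  }
  # weight gradients in two big products: dWh over shifted hidden states,
  # dWx over the inputs
  dXp_tbh <- aperm(dXp, c(3, 1, 2))                 # (T, B, 4H)
  dXpmat <- matrix(dXp_tbh, Tn * B, 4 * H)
  # h_{prev in traversal order}: shift Hs one step along ord
  Hprev <- array(0, c(B, H, Tn))
  Hprev[, , ord[-1]] <- cache$Hs[, , ord[-length(ord)]]
  Hprev_mat <- matrix(aperm(Hprev, c(3, 1, 2)), Tn * B, H)
  list(dWx = crossprod(matrix(Xarr, Tn * B, C), dXpmat),
       dWh = crossprod(Hprev_mat, dXpmat), db = colSums(dXpmat),
       dX = array(dXpmat %*% t(Wx), c(Tn, B, C)))
}

#' Bidirectional LSTM labeling head
#'
#' Runs the forward (left-to-right) and backward (right-to-left) recurrences
#' over a feature map, concatenates the two hidden streams per position, and
#' projects each position to class probabilities via an affine map and
#' softmax.
#'
#' @param features Feature-map matrix, `T x C`.
#' @param weights Delineator weights (entries `f.*`, `b.*`, `o.*`).
#' @return A `delineation_result`: `probabilities` (`T x 5`, rows sum to 1)
#'   and `labels` (argmax class per position; ties break to the lowest class
#'   index in the canonical order).
#' @export
bilstm_labels <- function(features, weights) {
  Tn <- nrow(features)
  Xarr <- array(features, c(Tn, 1, ncol(features)))
  fw <- lstm_forward(weights[["f.Wx"]], weights[["f.Wh"]], weights[["f.b"]],
                     Xarr, +1)
  bw <- lstm_forward(weights[["b.Wx"]], weights[["b.Wh"]], weights[["b.b"]],
                     Xarr, -1)
  H <- fw$H
  Hcat <- cbind(matrix(aperm(fw$Hs, c(3, 1, 2)), Tn, H),
                matrix(aperm(bw$Hs, c(3, 1, 2)), Tn, H))
  logits <- Hcat %*% weights[["o.W"]] + rep(weights[["o.b"]], each = Tn)
  if (!all(is.finite(logits))) stop("bilstm_labels: non-finite activations")
  P <- softmax_rows(logits)
  colnames(P) <- ecg_classes()[seq_len(ncol(P))]
  structure(list(probabilities = P,
                 labels = colnames(P)[max.col(P, ties.method = "first")]),
            class = "delineation_result")
}

#' @export
print.delineation_result <- function(x, ...) {
  tab <- table(factor(x$labels, levels = ecg_classes()))
  cat("<delineation_result>", nrow(x$probabilities), "positions; labels:",
      paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}
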