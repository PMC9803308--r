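#' Class labels used throughout the package
#'
#' Canonical per-sample class order for a delineated beat: P-wave,
#' QRS-complex, T-wave, isoelectric line, zero-padding. Every labels vector,
#' probability matrix column order and confusion-matrix axis in the package
#' follows this order.
#'
#' @return Character vector of the five class names.
#' @export
ecg_classes <- function() c("P", "QRS", "T", "ISO", "PAD")

#' Fixed beat-frame length in samples
#'
#' Every beat frame holds exactly 370 samples (one beat, from the start of
#' one P-wave to the start of the next, zero-padded if shorter).
#'
#' @return Integer, 370.
#' @export
frame_length <- function() 370L

# support half-width multiplier: a sample belongs to a wave iff within
# +/- 3 widths of its center; the bump itself is truncated there too
.support_k <- 3

#' Beat morphology description
#'
#' Parametric description of a single synthetic beat: three compact-support
#' Gaussian bumps (P, QRS, T) on a flat zero baseline. Positions are 0-based
#' sample offsets within the beat; widths are Gaussian standard deviations in
#' samples. A wave's support is `center +/- 3*width`; supports must not
#' overlap, must lie inside `[0, beat_length)`, and the beat must fit in the
#' 370-sample frame.
#'
#' @param p_amp,qrs_amp,t_amp Peak amplitudes in normalized units (typically
#'   in `[0, 1]` so a sigmoid output layer can represent them).
#' @param p_center,qrs_center,t_center Bump centers, 0-based samples.
#' @param p_width,qrs_width,t_width Bump standard deviations, samples.
#' @param beat_length Beat duration in samples, `1..370`. Samples at and
#'   beyond `beat_length` are zero-padding.
#' @param fs Sampling rate in Hz (default 250).
#' @return An object of class `beat_morphology`.
#' @export
beat_morphology <- function(p_amp = 0.15, p_center = 22, p_width = 5,
                            qrs_amp = 0.9, qrs_center = 75, qrs_width = 3,
                            t_amp = 0.35, t_center = 165, t_width = 9,
                            beat_length = 300L, fs = 250) {
  m <- structure(list(
    p_amp = p_amp, p_center = p_center, p_width = p_width,
    qrs_amp = qrs_amp, qrs_center = qrs_center, qrs_width = qrs_width,
    t_amp = t_amp, t_center = t_center, t_width = t_width,
    beat_length = as.integer(beat_length), fs = fs
  ), class = "beat_morphology")
  validate_beat_morphology(m)
  m
}

#' @rdname beat_morphology
#' @param m A `beat_morphology` object.
#' @export
validate_beat_morphology <- function(m) {
  stopifnot(inherits(m, "beat_morphology"))
  num <- unlist(m[c("p_amp", "p_center", "p_width", "qrs_amp", "qrs_center",
                    "qrs_width", "t_amp", "t_center", "t_width")])
  if (!all(is.finite(num)))
    stop("beat_morphology: all parameters must be finite")
  if (m$beat_length < 1L || m$beat_length > frame_length())
    stop("beat_morphology: beat_length must be in [1, ", frame_length(), "]")
  if (!(m$p_width > 0 && m$qrs_width > 0 && m$t_width > 0))
    stop("beat_morphology: widths must be > 0")
  if (!(0 < m$p_center && m$p_center < m$qrs_center &&
        m$qrs_center < m$t_center && m$t_center < m$beat_length))
    stop("beat_morphology: need 0 < p_center < qrs_center < t_center < beat_length")
  sup <- function(c, w) c(c - .support_k * w, c + .support_k * w)
  p <- sup(m$p_center, m$p_width)
  q <- sup(m$qrs_center, m$qrs_width)
  t <- sup(m$t_center, m$t_width)
  if (p[1] < 0 || t[2] >= m$beat_length)
    stop("beat_morphology: wave supports must lie inside [0, beat_length)")
  if (p[2] >= q[1] || q[2] >= t[1])
    stop("beat_morphology: wave supports overlap")
  invisible(m)
}

#' Construct a beat frame
#'
#' A beat frame is one beat in the fixed 370-sample representation: an
#' amplitude vector plus a per-sample class label over
#' P / QRS / T / ISO / PAD. PAD labels occur only as a contiguous suffix and
#' samples are exactly zero wherever the label is PAD.
#'
#' @param samples Numeric vector, length 370.
#' @param labels Character (or factor) vector, length 370, values from
#'   [ecg_classes()].
#' @param fs Sampling rate in Hz.
#' @return An object of class `beat_frame`.
#' @export
beat_frame <- function(samples, labels, fs = 250) {
  fr <- structure(list(samples = as.numeric(samples),
                       labels = as.character(labels), fs = fs),
                  class = "beat_frame")
  validate_beat_frame(fr)
  fr
}

#' @rdname beat_frame
#' @param frame A `beat_frame` object.
#' @export
validate_beat_frame <- function(frame) {
  stopifnot(inherits(frame, "beat_frame"))
  n <- frame_length()
  if (length(frame$samples) != n || length(frame$labels) != n)
    stop("beat_frame: samples and labels must both have length ", n)
  if (!all(frame$labels %in% ecg_classes()))
    stop("beat_frame: unknown label(s): ",
         paste(setdiff(unique(frame$labels), ecg_classes()), collapse = ", "))
  pad <- frame$labels == "PAD"
  if (any(pad)) {
    first_pad <- which(pad)[1]
    if (!all(pad[first_pad:n]))
      stop("beat_frame: PAD labels must form a contiguous suffix")
    if (any(frame$samples[pad] != 0))
      stop("beat_frame: samples must be exactly 0 where label == PAD")
  }
  if (!all(is.finite(frame$samples)))
    stop("beat_frame: samples must be finite")
  invisible(frame)
}

#' Number of non-padding samples of a beat frame
#' @param frame A `beat_frame`.
#' @return Integer beat length (index of the first PAD sample, or 370).
#' @export
beat_length <- function(frame) {
  pad <- which(frame$labels == "PAD")
  if (length(pad) == 0L) frame_length() else pad[1] - 1L
}

#' @export
print.beat_frame <- function(x, ...) {
  tab <- table(factor(x$labels, levels = ecg_classes()))
  cat("<beat_frame> fs =", x$fs, "Hz, beat length", beat_length(x),
      "samples\n  labels:", paste(names(tab), tab, sep = "=", collapse = " "),
      "\n")
  invisible(x)
}

#' @export
print.beat_morphology <- function(x, ...) {
  cat(sprintf(
    "<beat_morphology> fs = %g Hz, beat_length = %d\n  P  : amp %.3f center %g width %g\n  QRS: amp %.3f center %g width %g\n  T  : amp %.3f center %g width %g\n",
    x$fs, x$beat_length, x$p_amp, x$p_center, x$p_width,
    x$qrs_amp, x$qrs_center, x$qrs_width, x$t_amp, x$t_center, x$t_width))
  invisible(x)
}

# Internal: run code with a temporary, restorable RNG state.
# Guarantees that explicit seeds never leak into (or read) global RNG state.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Internal: derive a bounded child seed from (seed, index)
child_seed <- function(seed, i) {
  as.integer((as.double(seed) * 1009 + 97 * as.double(i)) %% 2147483629)
}
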