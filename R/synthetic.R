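#' Generate one labeled synthetic beat
#'
#' Renders a `beat_morphology` into a 370-sample [beat_frame()]. Each wave is
#' a compact-support Gaussian bump
#' `a * max(0, exp(-(i - c)^2 / (2 w^2)) - exp(-4.5))`, which is exactly zero
#' outside `c +/- 3w`, so isoelectric and padding samples are exactly zero.
#' Labels mark each wave's support, ISO elsewhere within the beat, PAD beyond.
#'
#' @param morph A [beat_morphology()].
#' @return A [beat_frame()] with ground-truth labels. The morphology is
#'   attached as attribute `"morphology"`.
#' @export
generate_beat <- function(morph) {
  validate_beat_morphology(morph)
  n <- frame_length()
  i <- seq_len(n) - 1  # 0-based sample index
  bump <- function(a, c, w) {
    g <- exp(-((i - c)^2) / (2 * w^2)) - exp(-.support_k^2 / 2)
    a * pmax(0, g)
  }
  samples <- bump(morph$p_amp, morph$p_center, morph$p_width) +
    bump(morph$qrs_amp, morph$qrs_center, morph$qrs_width) +
    bump(morph$t_amp, morph$t_center, morph$t_width)
  labels <- rep("ISO", n)
  mark <- function(a, c, w, lab) {
    # a flat (zero-amplitude) wave has no support; its samples stay ISO
    if (a > 0) labels[abs(i - c) <= .support_k * w] <<- lab
  }
  mark(morph$p_amp, morph$p_center, morph$p_width, "P")
  mark(morph$qrs_amp, morph$qrs_center, morph$qrs_width, "QRS")
  mark(morph$t_amp, morph$t_center, morph$t_width, "T")
  if (morph$beat_length < n) {
    pad <- (morph$beat_length + 1L):n
    labels[pad] <- "PAD"
    samples[pad] <- 0
  }
  fr <- beat_frame(samples, labels, fs = morph$fs)
  attr(fr, "morphology") <- morph
  fr
}

#' Random beat-morphology sampler
#'
#' Returns a sampler function drawing physiologically plausible morphologies
#' for a 250 Hz single-lead beat. Two presets are provided: `"normal"`
#' (resting sinus rhythm, heart rate about 45-65 BPM so a whole beat fits the
#' 370-sample frame with a padding tail) and `"fast"` (heart rate above
#' 80 BPM, the regime where the T-wave-alternans rule is active). Parameter
#' ranges are sampled uniformly and re-drawn until the morphology validates
#' (non-overlapping wave supports).
#'
#' @param preset `"normal"` or `"fast"`.
#' @param fs Sampling rate in Hz.
#' @return A function `f(n)` returning a list of `n` [beat_morphology()]
#'   objects, using the caller's RNG stream.
#' @export
morph_sampler <- function(preset = c("normal", "fast"), fs = 250) {
  preset <- match.arg(preset)
  rng <- if (preset == "normal") {
    list(p_c = c(18, 26), p_w = c(4, 5.5), p_a = c(0.10, 0.22),
         q_c = c(65, 85), q_w = c(2.5, 4), q_a = c(0.75, 1.0),
         t_c = c(150, 185), t_w = c(7, 10), t_a = c(0.25, 0.5),
         len = c(230, 330))
  } else {
    list(p_c = c(16, 22), p_w = c(3.5, 4.5), p_a = c(0.10, 0.22),
         q_c = c(52, 64), q_w = c(2.5, 3.5), q_a = c(0.75, 1.0),
         t_c = c(110, 128), t_w = c(6, 8), t_a = c(0.25, 0.5),
         len = c(155, 180))
  }
  u <- function(r) stats::runif(1, r[1], r[2])
  function(n) {
    lapply(seq_len(n), function(i) {
      repeat {
        m <- try(beat_morphology(
          p_amp = u(rng$p_a), p_center = u(rng$p_c), p_width = u(rng$p_w),
          qrs_amp = u(rng$q_a), qrs_center = u(rng$q_c), qrs_width = u(rng$q_w),
          t_amp = u(rng$t_a), t_center = u(rng$t_c), t_width = u(rng$t_w),
          beat_length = round(u(rng$len)), fs = fs), silent = TRUE)
        if (!inherits(m, "try-error")) return(m)
      }
    })
  }
}

#' Noise specification
#'
#' @param target_snr_db Target signal-to-noise ratio in decibels (the
#'   training protocol for the denoising auto-encoder uses 35 dB).
#' @param noise_kind One of `"white_gaussian"`, `"baseline_wander"`,
#'   `"powerline"`, `"mixture"`.
#' @param seed Integer seed (`NULL` to use the caller's RNG stream).
#' @param powerline_hz Mains frequency for the powerline component (50 or 60).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(target_snr_db = 35,
                       noise_kind = c("white_gaussian", "baseline_wander",
                                      "powerline", "mixture"),
                       seed = NULL, powerline_hz = 50) {
  noise_kind <- match.arg(noise_kind)
  if (!is.finite(target_snr_db))
    stop("noise_spec: target_snr_db must be finite")
  structure(list(target_snr_db = target_snr_db, noise_kind = noise_kind,
                 seed = seed, powerline_hz = powerline_hz),
            class = "noise_spec")
}

# Internal: raw (unscaled) noise realisation over n samples at fs Hz
raw_noise <- function(n, fs, kind, powerline_hz = 50) {
  t <- (seq_len(n) - 1) / fs
  switch(kind,
    white_gaussian = stats::rnorm(n),
    baseline_wander = {
      f <- stats::runif(1, 0.15, 0.45)  # Hz, respiratory-range drift
      sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
    },
    powerline = sin(2 * pi * powerline_hz * t + stats::runif(1, 0, 2 * pi)),
    mixture = {
      w <- stats::rnorm(n)
      f <- stats::runif(1, 0.15, 0.45)
      bw <- sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
      pl <- sin(2 * pi * powerline_hz * t + stats::runif(1, 0, 2 * pi))
      w / stats::sd(w) + bw / stats::sd(bw) + pl / stats::sd(pl)
    },
    stop("unknown noise kind: ", kind))
}

#' Add noise at an exact signal-to-noise ratio
#'
#' Adds a noise realisation to `clean`, scaled so that
#' `10*log10(sum(clean^2) / sum(noise^2))` equals `spec$target_snr_db`
#' exactly (to floating-point precision). When `pad_from` is given (or
#' `clean` is a [beat_frame()]), the zero-padding suffix is left unmodified
#' and excluded from the power sums.
#'
#' @param clean Numeric vector, or a [beat_frame()] (noise is then added to
#'   its samples and its labels carried through).
#' @param spec A [noise_spec()].
#' @param fs Sampling rate in Hz (taken from the frame if given one).
#' @param pad_from 1-based index of the first padding sample, or `NULL`.
#' @return Same type as `clean`, with noise added.
#' @export
add_noise_at_snr <- function(clean, spec, fs = 250, pad_from = NULL) {
  stopifnot(inherits(spec, "noise_spec"))
  if (inherits(clean, "beat_frame")) {
    bl <- beat_length(clean)
    noisy <- add_noise_at_snr(clean$samples, spec, fs = clean$fs,
                              pad_from = if (bl < frame_length()) bl + 1L else NULL)
    out <- clean
    out$samples <- noisy
    return(out)
  }
  x <- as.numeric(clean)
  n_active <- if (is.null(pad_from)) length(x) else pad_from - 1L
  active <- seq_len(n_active)
  sig_pow <- sum(x[active]^2)
  if (sig_pow == 0)
    stop("add_noise_at_snr: clean signal is identically zero; SNR undefined")
  noise <- local_seed(spec$seed,
    raw_noise(n_active, fs, spec$noise_kind, spec$powerline_hz))
  alpha <- sqrt(sig_pow / (10^(spec$target_snr_db / 10) * sum(noise^2)))
  out <- x
  out[active] <- x[active] + alpha * noise
  out
}

#' Inject T-wave alternans into a beat sequence
#'
#' Raises the T-peak amplitude of every beat whose 0-based index matches
#' `parity` by exactly `delta`, by rescaling the T-labeled samples of those
#' beats; all other samples are untouched. The injected magnitude is recorded
#' as attribute `"alternans_delta"` for closed-loop recovery tests.
#'
#' @param frames List of [beat_frame()] objects (clean or noisy).
#' @param delta Non-negative amplitude increment (same units as the samples).
#' @param parity `"even"` or `"odd"` (0-based beat index).
#' @return List of frames with alternating T-peak amplitudes.
#' @export
inject_alternans <- function(frames, delta, parity = c("even", "odd")) {
  parity <- match.arg(parity)
  if (length(frames) == 0L) stop("inject_alternans: empty frame list")
  if (delta < 0) stop("inject_alternans: delta must be >= 0")
  want <- if (parity == "even") 0L else 1L
  out <- lapply(seq_along(frames), function(k) {
    fr <- frames[[k]]
    if (((k - 1L) %% 2L) != want || delta == 0) return(fr)
    tt <- fr$labels == "T"
    if (!any(tt)) return(fr)
    peak <- max(fr$samples[tt])
    if (peak <= 0) return(fr)
    fr$samples[tt] <- fr$samples[tt] * ((peak + delta) / peak)
    fr
  })
  attr(out, "alternans_delta") <- delta
  attr(out, "alternans_parity") <- parity
  out
}

#' Generate a paired clean/noisy beat dataset
#'
#' Draws `n_beats` morphologies from `sampler`, renders each to a clean
#' frame, and adds noise per `noise` at the requested SNR. Labels of each
#' pair are identical; the whole dataset is reproducible from `seed`.
#'
#' @param n_beats Number of beats (>= 1).
#' @param sampler A sampler from [morph_sampler()] (or any `f(n)` returning
#'   morphologies).
#' @param noise A [noise_spec()]; its `seed` field is ignored in favour of
#'   per-beat seeds derived from `seed`.
#' @param seed Integer seed for the whole dataset.
#' @return List with elements `clean` and `noisy` (lists of [beat_frame()]),
#'   plus the generating `seed` as an attribute.
#' @export
generate_dataset <- function(n_beats, sampler = morph_sampler(),
                             noise = noise_spec(35), seed = 1L) {
  stopifnot(n_beats >= 1)
  morphs <- local_seed(seed, sampler(n_beats))
  clean <- lapply(morphs, generate_beat)
  noisy <- lapply(seq_along(clean), function(i) {
    sp <- noise
    sp$seed <- child_seed(seed, i)
    add_noise_at_snr(clean[[i]], sp)
  })
  structure(list(clean = clean, noisy = noisy), seed = seed,
            class = "beat_dataset")
}

#' @export
print.beat_dataset <- function(x, ...) {
  cat("<beat_dataset>", length(x$clean), "clean/noisy beat pairs\n")
  invisible(x)
}

#' Write / read a beat dataset as CSV
#'
#' Long format, one row per sample: `frame_id, index, clean, noisy, label`
#' (`index` is 0-based). This is the on-disk interchange format shared by the
#' simulator and the command-line interface.
#'
#' @param dataset A dataset from [generate_dataset()].
#' @param path Output CSV path.
#' @param fs Sampling rate recorded on read-back.
#' @return `path`, invisibly (writer); a `beat_dataset` (reader).
#' @export
write_dataset_csv <- function(dataset, path) {
  n <- frame_length()
  rows <- do.call(rbind, lapply(seq_along(dataset$clean), function(i) {
    data.frame(frame_id = i, index = 0:(n - 1),
               clean = dataset$clean[[i]]$samples,
               noisy = dataset$noisy[[i]]$samples,
               label = dataset$clean[[i]]$labels)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path, fs = 250) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  ids <- unique(d$frame_id)
  clean <- list(); noisy <- list()
  for (k in seq_along(ids)) {
    di <- d[d$frame_id == ids[k], ]
    di <- di[order(di$index), ]
    clean[[k]] <- beat_frame(di$clean, di$label, fs = fs)
    noisy[[k]] <- beat_frame_relaxed(di$noisy, di$label, fs = fs)
  }
  structure(list(clean = clean, noisy = noisy), class = "beat_dataset")
}

# Internal: like beat_frame() but tolerates CSV round-trip quantisation of
# noisy samples (PAD samples are snapped back to exact zero).
beat_frame_relaxed <- function(samples, labels, fs = 250) {
  samples[labels == "PAD"] <- 0
  beat_frame(samples, labels, fs = fs)
}

#' Extract the T-peak amplitude series from labeled frames
#'
#' T-peak amplitude of each beat is the maximum sample within its T-wave run.
#' Heart rate, unless supplied, is derived from the mean beat length:
#' `HR = 60 * fs / mean(beat_length)` (consecutive frames abut, so the beat
#' length is the inter-beat interval in samples).
#'
#' @param frames List of [beat_frame()] objects with T labels.
#' @param heart_rate Optional BPM override.
#' @param record_id Identifier carried into the result.
#' @return A [t_peak_series()].
#' @export
t_peaks_from_frames <- function(frames, heart_rate = NULL, record_id = "rec") {
  amps <- vapply(frames, function(fr) {
    tt <- fr$labels == "T"
    if (!any(tt)) NA_real_ else max(fr$samples[tt])
  }, numeric(1))
  if (anyNA(amps))
    warning("t_peaks_from_frames: ", sum(is.na(amps)),
            " frame(s) without a T-wave run dropped")
  keep <- !is.na(amps)
  if (is.null(heart_rate)) {
    fs <- frames[[1]]$fs
    heart_rate <- 60 * fs / mean(vapply(frames, beat_length, numeric(1)))
  }
  t_peak_series(amps[keep], heart_rate = heart_rate, record_id = record_id)
}
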