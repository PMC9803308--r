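#' Annotated ECG record
#'
#' A single-lead signal with wave onset/peak/offset annotations in the
#' vocabulary `P_on, P_peak, P_off, QRS_on, R_peak, QRS_off, T_on, T_peak,
#' T_off`. Annotation indices are 0-based samples into the signal.
#'
#' @param signal Numeric amplitude vector.
#' @param fs Sampling rate in Hz.
#' @param annotations Data frame with columns `sample` (0-based integer) and
#'   `mark`.
#' @param record_id Identifier.
#' @return An object of class `annotated_record`.
#' @export
annotated_record <- function(signal, fs, annotations,
                             record_id = "rec") {
  marks <- c("P_on", "P_peak", "P_off", "QRS_on", "R_peak", "QRS_off",
             "T_on", "T_peak", "T_off")
  stopifnot(is.data.frame(annotations),
            all(c("sample", "mark") %in% names(annotations)))
  bad <- !(annotations$mark %in% marks)
  if (any(bad)) {
    warning("annotated_record: dropping unknown annotation symbol(s): ",
            paste(unique(annotations$mark[bad]), collapse = ", "))
    annotations <- annotations[!bad, ]
  }
  if (any(annotations$sample < 0 | annotations$sample >= length(signal)))
    stop("annotated_record: annotation indices must lie within the signal")
  annotations <- annotations[order(annotations$sample), ]
  structure(list(signal = as.numeric(signal), fs = fs,
                 annotations = annotations, record_id = record_id),
            class = "annotated_record")
}

#' @export
print.annotated_record <- function(x, ...) {
  cat(sprintf("<annotated_record> %s: %d samples @ %g Hz, %d annotations\n",
              x$record_id, length(x$signal), x$fs, nrow(x$annotations)))
  invisible(x)
}

#' Segment an annotated record into beat frames
#'
#' One frame per consecutive pair of P-wave onsets (a beat runs from the
#' start of one P-wave to the start of the next). Beats shorter than 370
#' samples are zero-padded and PAD-labeled; beats longer than 370 samples
#' are truncated at 370 with a warning. Per-sample labels come from the
#' enclosing half-open `[onset, offset)` intervals; a wave with a missing
#' onset or offset mark falls back to ISO with a warning.
#'
#' @param rec An [annotated_record()].
#' @return List of [beat_frame()] objects (empty, with a warning, if the
#'   record has fewer than two `P_on` marks).
#' @export
segment_beats <- function(rec) {
  stopifnot(inherits(rec, "annotated_record"))
  ann <- rec$annotations
  p_on <- ann$sample[ann$mark == "P_on"]
  if (length(p_on) < 2L) {
    warning("segment_beats: fewer than 2 P_on marks; no beats segmented")
    return(list())
  }
  n <- frame_length()
  frames <- vector("list", length(p_on) - 1L)
  for (k in seq_len(length(p_on) - 1L)) {
    s <- p_on[k]; s_next <- p_on[k + 1L]
    L <- s_next - s
    if (L > n) {
      warning("segment_beats: beat ", k, " is ", L,
              " samples; truncated at ", n)
      L <- n
    }
    samples <- numeric(n)
    samples[seq_len(L)] <- rec$signal[(s + 1L):(s + L)]
    labels <- rep("ISO", n)
    in_beat <- ann[ann$sample >= s & ann$sample < s_next, ]
    for (wv in list(c("P_on", "P_off", "P"), c("QRS_on", "QRS_off", "QRS"),
                    c("T_on", "T_off", "T"))) {
      on <- in_beat$sample[in_beat$mark == wv[1]]
      off <- in_beat$sample[in_beat$mark == wv[2]]
      if (length(on) < 1L || length(off) < 1L) {
        if (length(on) + length(off) > 0L)
          warning("segment_beats: beat ", k, ": incomplete ", wv[3],
                  " marks; wave left as ISO")
        next
      }
      on <- on[1]; off <- off[1]
      lo <- on - s + 1L
      hi <- min(off - s, L)
      if (lo <= hi) labels[lo:hi] <- wv[3]
    }
    if (L < n) {
      labels[(L + 1L):n] <- "PAD"
      samples[(L + 1L):n] <- 0
    }
    frames[[k]] <- beat_frame(samples, labels, fs = rec$fs)
  }
  frames
}

#' Band-limited resampling
#'
#' Delay-compensated polyphase FIR resampling from `fs_in` to `fs_out` Hz:
#' the signal is zero-stuffed by the rational upsampling factor, filtered
#' with a linear-phase windowed-sinc low-pass (cutoff at the tighter of the
#' two Nyquist rates), the known group delay removed, and the result
#' decimated. Output length scales by `fs_out / fs_in` (rounded up).
#'
#' @param x Numeric signal.
#' @param fs_in,fs_out Sampling rates in Hz (> 0).
#' @param taps_per_phase Half-length of the prototype filter per polyphase
#'   branch (default 10; larger is sharper but slower).
#' @return Resampled numeric vector.
#' @export
resample_signal <- function(x, fs_in, fs_out, taps_per_phase = 10L) {
  stopifnot(fs_in > 0, fs_out > 0)
  x <- as.numeric(x)
  if (fs_in == fs_out) return(x)
  g <- function(a, b) if (b == 0) a else Recall(b, a %% b)
  # rationalise the ratio (sampling rates here are small integers)
  p0 <- round(fs_out * 1000); q0 <- round(fs_in * 1000)
  d <- g(p0, q0)
  p <- p0 / d; q <- q0 / d
  n <- length(x)
  up <- numeric(n * p)
  up[seq(1, by = p, length.out = n)] <- x
  m <- max(p, q)
  K <- 2L * as.integer(taps_per_phase) * m        # even order -> delay K/2
  h <- p * signal::fir1(K, 1 / m)
  y_full <- stats::convolve(up, rev(h), type = "open")
  n_out <- ceiling(n * p / q)
  idx <- K / 2 + 1 + (seq_len(n_out) - 1) * q
  y_full[idx]
}

#' Min-max normalisation to \[0, 1\] with inversion
#'
#' Per-record amplitude normalisation used before the sigmoid-output
#' auto-encoder; `unnormalize_minmax` inverts it with the stored constants.
#'
#' @param x Numeric vector.
#' @return `normalize_minmax`: list `x` (scaled), `lo`, `hi`.
#' @export
normalize_minmax <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi <= lo) hi <- lo + 1
  list(x = (x - lo) / (hi - lo), lo = lo, hi = hi)
}

#' @rdname normalize_minmax
#' @param scaled Output of `normalize_minmax`.
#' @export
unnormalize_minmax <- function(scaled) {
  scaled$x * (scaled$hi - scaled$lo) + scaled$lo
}

# ---- minimal WFDB-compatible record I/O ------------------------------------

#' Write / read a WFDB-compatible record
#'
#' Minimal single-signal WFDB support: a text header (`<record>.hea`) and a
#' 16-bit little-endian sample file (`<record>.dat`, format 16), with the
#' standard `gain(baseline)/units` field. Annotations travel as a
#' plain-text CSV (`<record>.ann.csv`, columns `sample`, `mark`) rather than
#' the binary annotation format. Amplitudes round-trip within one ADC
#' quantum (`1/gain`).
#'
#' @param rec An [annotated_record()].
#' @param record_path Path prefix (without extension).
#' @param gain ADC units per physical unit (default 2000, i.e. 0.5 uV
#'   resolution on a millivolt-scaled signal).
#' @return `record_path` invisibly (writer); an [annotated_record()]
#'   (reader).
#' @export
write_wfdb <- function(rec, record_path, gain = 2000) {
  stopifnot(inherits(rec, "annotated_record"))
  name <- basename(record_path)
  adc <- as.integer(pmin(pmax(round(rec$signal * gain), -32768), 32767))
  header <- c(
    sprintf("%s 1 %g %d", name, rec$fs, length(adc)),
    sprintf("%s.dat 16 %g(0)/mV 16 0 %d 0 0 ECG", name, gain,
            if (length(adc)) adc[1] else 0))
  writeLines(header, paste0(record_path, ".hea"))
  con <- file(paste0(record_path, ".dat"), "wb")
  writeBin(adc, con, size = 2, endian = "little")
  close(con)
  utils::write.csv(rec$annotations, paste0(record_path, ".ann.csv"),
                   row.names = FALSE)
  invisible(record_path)
}

#' @rdname write_wfdb
#' @export
read_wfdb <- function(record_path) {
  hea <- paste0(record_path, ".hea")
  dat <- paste0(record_path, ".dat")
  if (!file.exists(hea)) stop("read_wfdb: missing header file: ", hea)
  lines <- readLines(hea)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  rl <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(rl) < 3) stop("read_wfdb: malformed record line in ", hea)
  fs <- as.numeric(rl[3])
  nsamp <- if (length(rl) >= 4) as.integer(rl[4]) else NA_integer_
  sl <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  fmt <- sl[2]
  if (!startsWith(fmt, "16"))
    stop("read_wfdb: only format 16 is supported, got format ", fmt)
  gain_field <- if (length(sl) >= 3) sl[3] else "200"
  gm <- regmatches(gain_field,
                   regexec("^([0-9.eE+-]+)(\\(([0-9-]+)\\))?", gain_field))[[1]]
  gain <- as.numeric(gm[2]); if (!is.finite(gain) || gain == 0) gain <- 200
  baseline <- if (nzchar(gm[4] %||% "")) as.numeric(gm[4]) else 0
  if (!file.exists(dat)) stop("read_wfdb: missing signal file: ", dat)
  con <- file(dat, "rb")
  adc <- readBin(con, integer(), n = if (is.na(nsamp)) file.size(dat) / 2 else nsamp,
                 size = 2, endian = "little")
  close(con)
  signal <- (adc - baseline) / gain
  ann_path <- paste0(record_path, ".ann.csv")
  ann <- if (file.exists(ann_path)) {
    utils::read.csv(ann_path, stringsAsFactors = FALSE)
  } else data.frame(sample = integer(), mark = character())
  annotated_record(signal, fs, ann, record_id = basename(record_path))
}

#' Render a beat-frame sequence as one annotated record
#'
#' Concatenates the non-padding parts of consecutive frames into a
#' continuous signal and emits onset/peak/offset annotations from the frame
#' labels — the inverse of [segment_beats()] for synthetic data, used for
#' interoperability round-trips.
#'
#' @param frames List of labeled [beat_frame()] objects.
#' @param record_id Identifier.
#' @return An [annotated_record()].
#' @export
frames_to_record <- function(frames, record_id = "synth") {
  stopifnot(length(frames) >= 1)
  fs <- frames[[1]]$fs
  signal <- numeric(0)
  ann <- list()
  offset <- 0L
  for (fr in frames) {
    L <- beat_length(fr)
    seg <- fr$samples[seq_len(L)]
    wb <- wave_boundaries(fr$labels[seq_len(L)], seg, min_run = 1L)
    for (i in seq_len(nrow(wb))) {
      pre <- c(P = "P", QRS = "QRS", T = "T")[[wb$wave[i]]]
      peak_mark <- if (pre == "QRS") "R_peak" else paste0(pre, "_peak")
      ann[[length(ann) + 1L]] <- data.frame(
        sample = offset + c(wb$onset[i], wb$peak[i], wb$offset[i] + 1L),
        mark = c(paste0(pre, "_on"), peak_mark, paste0(pre, "_off")))
    }
    signal <- c(signal, seg)
    offset <- offset + L
  }
  ann <- do.call(rbind, ann)
  # offsets are half-open; clamp the final offset inside the signal
  ann$sample <- pmin(ann$sample, length(signal) - 1L)
  annotated_record(signal, fs, ann, record_id = record_id)
}
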