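#' Ordered T-peak amplitude series
#'
#' @param amplitudes Numeric vector of T-peak amplitudes in beat order
#'   (consistent units; microvolts for clinical data).
#' @param heart_rate Heart rate in BPM (> 0).
#' @param record_id Record identifier.
#' @return An object of class `t_peak_series`.
#' @export
t_peak_series <- function(amplitudes, heart_rate, record_id = "rec") {
  amplitudes <- as.numeric(amplitudes)
  if (!all(is.finite(amplitudes)))
    stop("t_peak_series: amplitudes must be finite")
  if (!is.finite(heart_rate) || heart_rate <= 0)
    stop("t_peak_series: heart_rate must be > 0")
  structure(list(amplitudes = amplitudes, heart_rate = heart_rate,
                 record_id = record_id), class = "t_peak_series")
}

#' @export
print.t_peak_series <- function(x, ...) {
  cat(sprintf("<t_peak_series> %s: %d T-peaks, heart rate %.1f BPM\n",
              x$record_id, length(x$amplitudes), x$heart_rate))
  invisible(x)
}

#' Split T-peaks into even- and odd-indexed groups
#'
#' Beats at even 0-based positions (the 1st, 3rd, ... beat) go to the even
#' group; the rest to the odd group. Swapping the parity convention flips the
#' sign of the difference series and leaves its absolute values, the
#' zero-crossing count and the detection verdict unchanged.
#'
#' @param series A [t_peak_series()] or numeric vector with >= 2 peaks.
#' @return List with numeric elements `even` and `odd`.
#' @export
split_even_odd <- function(series) {
  a <- if (inherits(series, "t_peak_series")) series$amplitudes else as.numeric(series)
  if (length(a) < 2L) stop("split_even_odd: need at least 2 T-peaks")
  idx0 <- seq_along(a) - 1L
  list(even = a[idx0 %% 2L == 0L], odd = a[idx0 %% 2L == 1L])
}

#' Even/odd T-peak difference series
#'
#' Elementwise `odd - even` over the first `min(length(even), length(odd))`
#' pairs.
#'
#' @param even,odd Numeric amplitude groups (both non-empty).
#' @return Numeric difference series (the "TW" series).
#' @export
tw_difference <- function(even, odd) {
  if (length(even) == 0L || length(odd) == 0L)
    stop("tw_difference: both groups must be non-empty")
  n <- min(length(even), length(odd))
  odd[seq_len(n)] - even[seq_len(n)]
}

#' Count zero-crossings of a series
#'
#' Number of consecutive pairs with strictly opposite signs. Exact zeros are
#' transparent: the sign is carried from the last nonzero element, so a zero
#' sitting between opposite signs still yields exactly one crossing, and a
#' constant-sign or all-zero series has none.
#'
#' @param tw Numeric vector, length >= 1.
#' @return Integer count in `[0, length(tw) - 1]`.
#' @export
count_zero_crossings <- function(tw) {
  if (length(tw) < 1L) stop("count_zero_crossings: empty series")
  s <- sign(tw)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(diff(s) != 0)
}

#' T-wave alternans magnitude
#'
#' Maximum absolute value of the difference series excluding its first and
#' last elements (endpoints are dropped as edge-contaminated).
#'
#' @param tw Numeric difference series, length >= 3.
#' @return Non-negative amplitude.
#' @export
twa_magnitude <- function(tw) {
  if (length(tw) < 3L)
    stop("twa_magnitude: need length >= 3 (interior must be non-empty)")
  max(abs(tw[2:(length(tw) - 1L)]))
}

#' T-wave alternans detection rule
#'
#' TWA is declared present when the even/odd T-peak difference series keeps a
#' consistent sign (few zero-crossings) at an elevated heart rate:
#' `zero_crossings < 0.35 * tw_length` AND `heart_rate > 80` BPM, both
#' strict.
#'
#' @param zero_crossings Integer zero-crossing count of the difference series.
#' @param tw_length Length of the difference series (>= 1).
#' @param heart_rate Heart rate in BPM (> 0).
#' @return Logical verdict.
#' @export
twa_detect <- function(zero_crossings, tw_length, heart_rate) {
  stopifnot(tw_length >= 1, heart_rate > 0, zero_crossings >= 0)
  (zero_crossings < 0.35 * tw_length) && (heart_rate > 80)
}

#' Quantify T-wave alternans for one record
#'
#' Composes the whole rule: split the T-peaks into even/odd groups, form the
#' difference series, count its zero-crossings, apply the detection rule, and
#' — only when detected — report the alternans magnitude (otherwise 0).
#'
#' @param series A [t_peak_series()] with >= 4 peaks.
#' @return An object of class `twa_result`: fields `record_id`,
#'   `zero_crossings`, `tw_length`, `heart_rate`, `twa_magnitude`,
#'   `detected`.
#' @export
quantify_record <- function(series) {
  stopifnot(inherits(series, "t_peak_series"))
  if (length(series$amplitudes) < 4L)
    stop("quantify_record: need >= 4 T-peaks")
  g <- split_even_odd(series)
  tw <- tw_difference(g$even, g$odd)
  zc <- count_zero_crossings(tw)
  det <- twa_detect(zc, length(tw), series$heart_rate)
  mag <- if (det) twa_magnitude(tw) else 0
  structure(list(record_id = series$record_id, zero_crossings = zc,
                 tw_length = length(tw), heart_rate = series$heart_rate,
                 twa_magnitude = mag, detected = det),
            class = "twa_result")
}

#' @export
print.twa_result <- function(x, ...) {
  cat(sprintf("<twa_result> %s: zc %d / length %d, HR %.1f BPM -> %s (magnitude %.4g)\n",
              x$record_id, x$zero_crossings, x$tw_length, x$heart_rate,
              if (x$detected) "Detected" else "Non-detected", x$twa_magnitude))
  invisible(x)
}

#' Coerce a TWA result to a one-row data frame
#' @param x A `twa_result`.
#' @param ... Unused.
#' @return Data frame mirroring the reference decision-table columns.
#' @export
as.data.frame.twa_result <- function(x, ...) {
  data.frame(record = x$record_id, zero_crossings = x$zero_crossings,
             tw_length = x$tw_length, heart_rate = x$heart_rate,
             twa_magnitude = x$twa_magnitude,
             result = if (x$detected) "Detected" else "Non-detected")
}

#' Apply the detection rule to a table of record summaries
#'
#' Each row must carry `record`, `zero_crossings`, `tw_length`,
#' `heart_rate`. The rule [twa_detect()] is applied row-wise; verdicts and
#' detected / non-detected counts are returned.
#'
#' @param rows Data frame of record summaries.
#' @return List with `table` (input plus a `result` column) and counts
#'   `n_detected`, `n_non_detected`.
#' @export
evaluate_reference_decisions <- function(rows) {
  needed <- c("record", "zero_crossings", "tw_length", "heart_rate")
  if (!all(needed %in% names(rows)))
    stop("rows must have columns: ", paste(needed, collapse = ", "))
  verdict <- mapply(twa_detect, rows$zero_crossings, rows$tw_length,
                    rows$heart_rate)
  out <- rows
  out$result <- ifelse(verdict, "Detected", "Non-detected")
  list(table = out, n_detected = sum(verdict),
       n_non_detected = sum(!verdict))
}

#' Reference TWA decision table
#'
#' Published per-record summaries for the 30 synthesized-alternans records of
#' the PhysioNet T-Wave Alternans Challenge Database: zero-crossing count of
#' the even/odd T-peak difference series, its length, the record's heart
#' rate, the reported alternans magnitude (microvolts; descriptive only — it
#' is not recomputable from these columns), and the reference verdict.
#'
#' @return Data frame with 30 rows and columns `record`, `zero_crossings`,
#'   `tw_length`, `heart_rate`, `twa_magnitude`, `result`.
#' @export
twa_reference_table <- function() {
  path <- system.file("extdata", "twa_challenge_reference.csv",
                      package = "ecgwave", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
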