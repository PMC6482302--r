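# The two heart-sound emotion indicators. For a segmentation with arrays
# thb/tha (1-based odd entries S1, even entries S2; N cycles):
#
#   S1 midpoint:   S_M(i) = thb(2i-1) + (tha(2i-1) - thb(2i-1)) / 2
#   HS HRV:        RR_i   = S_M(i+1) - S_M(i),                 i = 1..N-1
#   HS DSV:        DS_i   = (thb(2i+1) - thb(2i)) /
#                           (thb(2i)   - thb(2i-1)),           i = 1..N-1
#
# The DSV denominator is the systole of cycle i (S1 onset to S2 onset); the
# numerator is its diastole (S2 onset to the next S1 onset), so the series
# has N-1 entries, like the RR series.

#' Construct an interval series
#'
#' @param values positive numeric values: seconds for RR kinds,
#'   dimensionless ratios for the DS kind.
#' @param kind `"hs_rr"`, `"hs_ds"` or `"ecg_rr"`.
#' @param source_id identifier of the originating recording.
#' @return an object of class `interval_series`.
#' @export
interval_series <- function(values, kind = c("hs_rr", "hs_ds", "ecg_rr"),
                            source_id = "") {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (length(values) == 0L) stop_pcg("interval series is empty")
  if (any(!is.finite(values)) || any(values <= 0))
    stop_pcg("interval series values must be finite and > 0")
  structure(list(values = values, kind = kind,
                 source_id = as.character(source_id)),
            class = "interval_series")
}

#' @export
print.interval_series <- function(x, ...) {
  cat(sprintf("<interval_series> kind=%s n=%d mean=%.4f\n",
              x$kind, length(x$values), mean(x$values)))
  invisible(x)
}

is_rr_kind <- function(series) series$kind %in% c("hs_rr", "ecg_rr")

#' S1 midpoints of a segmentation
#'
#' `S_M(i) = thb(2i-1) + (tha(2i-1) - thb(2i-1)) / 2`, the reference points
#' of the heart-sound beat-interval series.
#'
#' @param seg a [segmentation].
#' @return strictly increasing numeric vector of length `n_cycles`.
#' @export
s1_midpoints <- function(seg) {
  stopifnot(inherits(seg, "segmentation"))
  on <- s1_onsets(seg)
  on + (s1_offsets(seg) - on) / 2
}

#' Heart-sound HRV interval series
#'
#' Successive differences of S1 midpoints: `RR_i = S_M(i+1) - S_M(i)`.
#'
#' @param seg a [segmentation] with at least 2 cycles.
#' @param source_id identifier carried into the result.
#' @return an [interval_series] of kind `"hs_rr"`, length `N - 1`.
#' @export
hs_hrv <- function(seg, source_id = "") {
  stopifnot(inherits(seg, "segmentation"))
  if (seg$n_cycles < 2L) stop_pcg("insufficient cycles: need N >= 2")
  interval_series(diff(s1_midpoints(seg)), "hs_rr", source_id)
}

#' Heart-sound diastole/systole ratio series (DSV)
#'
#' `DS_i = (thb(2i+1) - thb(2i)) / (thb(2i) - thb(2i-1))`: the diastolic
#' duration of cycle `i` (S2 onset to next S1 onset) over its systolic
#' duration (S1 onset to S2 onset).
#'
#' @inheritParams hs_hrv
#' @return an [interval_series] of kind `"hs_ds"`, length `N - 1`.
#' @export
hs_dsv <- function(seg, source_id = "") {
  stopifnot(inherits(seg, "segmentation"))
  if (seg$n_cycles < 2L) stop_pcg("insufficient cycles: need N >= 2")
  i <- seq_len(seg$n_cycles - 1L)
  sys_d <- seg$thb[2 * i] - seg$thb[2 * i - 1]
  dia_d <- seg$thb[2 * i + 1] - seg$thb[2 * i]
  if (any(sys_d <= 0)) stop_pcg("degenerate cycle: zero systolic interval")
  interval_series(dia_d / sys_d, "hs_ds", source_id)
}

#' ECG RR interval series from R-peak times
#'
#' @param rpeaks strictly increasing R-peak times in seconds (length >= 2).
#' @param source_id identifier carried into the result.
#' @return an [interval_series] of kind `"ecg_rr"`.
#' @export
ecg_rr <- function(rpeaks, source_id = "") {
  rpeaks <- as.numeric(rpeaks)
  if (length(rpeaks) < 2L) stop_pcg("need at least 2 R-peaks")
  if (any(diff(rpeaks) <= 0)) stop_pcg("R-peak times must be strictly increasing")
  interval_series(diff(rpeaks), "ecg_rr", source_id)
}

#' Median-filter interval cleaner (optional)
#'
#' Replaces values deviating from a running median by more than `limit`
#' relative units with that median. Off by default throughout the pipeline;
#' provided for recordings with occasional ectopic or mis-detected beats.
#'
#' @param series an [interval_series].
#' @param width odd window width of the running median.
#' @param limit relative deviation triggering replacement.
#' @return a cleaned [interval_series].
#' @export
median_filter_intervals <- function(series, width = 5L, limit = 0.2) {
  stopifnot(inherits(series, "interval_series"))
  v <- series$values
  if (length(v) >= width) {
    med <- stats::runmed(v, width, endrule = "median")
    bad <- abs(v - med) / med > limit
    v[bad] <- med[bad]
  }
  interval_series(v, series$kind, series$source_id)
}

#' Write / read an interval series as CSV
#'
#' Two columns (`index`, `value`); the kind travels in a comment-style
#' header column.
#' @param series an [interval_series].
#' @param path CSV path.
#' @return `path` (write) or an [interval_series] (read).
#' @export
write_interval_series <- function(series, path) {
  df <- data.frame(index = seq_along(series$values), value = series$values,
                   kind = series$kind)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_interval_series
#' @export
read_interval_series <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  interval_series(df$value, df$kind[1])
}
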