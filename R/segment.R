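# S1/S2 segmentation. The result is stored in the interleaved two-array
# form: `thb` holds event onsets and `tha` event offsets, both of length 2N
# for N cardiac cycles; odd (1-based) positions are S1 events, even
# positions S2 events.

#' Construct and validate a segmentation
#'
#' @param thb event onsets in seconds, length `2N`, odd entries S1, even S2.
#' @param tha event offsets in seconds, same length.
#' @param check validate physiological duration bounds (S1 in
#'   `[0.04, 0.25]` s, S2 in `[0.03, 0.20]` s) in addition to ordering.
#' @return an object of class `segmentation` with fields `thb`, `tha`,
#'   `n_cycles`.
#' @export
segmentation <- function(thb, tha, check = TRUE) {
  thb <- as.numeric(thb); tha <- as.numeric(tha)
  if (length(thb) != length(tha)) stop_pcg("thb and tha must have equal length")
  if (length(thb) == 0L || length(thb) %% 2L != 0L)
    stop_pcg("thb/tha length must be a positive even number (2N)")
  n <- length(thb) %/% 2L
  if (any(tha < thb)) stop_pcg("event offsets must not precede onsets")
  if (any(diff(thb) <= 0)) stop_pcg("thb must be strictly increasing")
  if (any(tha[-length(tha)] >= thb[-1]))
    stop_pcg("events must not overlap (tha[k] < thb[k+1])")
  if (check) {
    s1_dur <- tha[c(TRUE, FALSE)] - thb[c(TRUE, FALSE)]
    s2_dur <- tha[c(FALSE, TRUE)] - thb[c(FALSE, TRUE)]
    if (any(s1_dur < 0.04 - 1e-9 | s1_dur > 0.25 + 1e-9))
      stop_pcg("S1 duration outside [0.04, 0.25] s")
    if (any(s2_dur < 0.03 - 1e-9 | s2_dur > 0.20 + 1e-9))
      stop_pcg("S2 duration outside [0.03, 0.20] s")
  }
  structure(list(thb = thb, tha = tha, n_cycles = n), class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %d cycles over [%.2f, %.2f] s\n",
              x$n_cycles, x$thb[1], x$tha[length(x$tha)]))
  invisible(x)
}

# 1-based cycle accessors mirroring the odd/even array convention.
s1_onsets <- function(seg) seg$thb[c(TRUE, FALSE)]
s1_offsets <- function(seg) seg$tha[c(TRUE, FALSE)]
s2_onsets <- function(seg) seg$thb[c(FALSE, TRUE)]
s2_offsets <- function(seg) seg$tha[c(FALSE, TRUE)]

#' @export
as.data.frame.segmentation <- function(x, ...) {
  data.frame(cycle = rep(seq_len(x$n_cycles), each = 2L),
             event = rep(c("S1", "S2"), x$n_cycles),
             onset_s = x$thb, offset_s = x$tha)
}

#' Write / read a segmentation as CSV
#'
#' Columns: `cycle, event, onset_s, offset_s`.
#' @param seg a [segmentation].
#' @param path CSV path.
#' @return `path` (write) or a [segmentation] (read).
#' @export
write_segmentation <- function(seg, path) {
  write.csv(as.data.frame(seg), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_segmentation
#' @export
read_segmentation <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  segmentation(df$onset_s, df$offset_s)
}

# --- Detection --------------------------------------------------------------

#' Detect S1/S2 events in a PCG recording
#'
#' Template-threshold segmentation on the Shannon energy envelope:
#' \enumerate{
#'   \item peak picking with an adaptive threshold (a fraction of a robust
#'     envelope maximum) and a refractory separation;
#'   \item event boundaries at the 10%-of-peak crossings of a short
#'     moving-RMS amplitude envelope around each peak;
#'   \item S1/S2 disambiguation by the interval-alternation rule: the
#'     shorter of the two alternating onset gaps is the systole (S1 to S2),
#'     i.e. diastole exceeds systole at rest (DS ratio > 1);
#'   \item a duration-constrained correction pass drops sub-physiologic
#'     detections; incomplete leading/trailing cycles are dropped.
#' }
#'
#' @param rec a (low-pass filtered) [pcg_recording].
#' @param env its [shannon_envelope]; recomputed if `NULL`.
#' @param peak_frac adaptive peak threshold as a fraction of the 99.5th
#'   envelope percentile.
#' @param min_separation minimal separation between event peaks in seconds.
#' @param boundary_frac boundary threshold as a fraction of lobe peak
#'   amplitude.
#' @param rms_window moving-RMS window for boundary refinement, seconds.
#' @return a [segmentation].
#' @export
segment_pcg <- function(rec, env = NULL, peak_frac = 0.25,
                        min_separation = 0.10, boundary_frac = 0.10,
                        rms_window = 0.006) {
  stopifnot(inherits(rec, "pcg_recording"))
  if (is.null(env)) env <- shannon_envelope(rec)
  v <- env$values
  rate <- env$rate
  n <- length(v)

  thr <- peak_frac * quantile(v, 0.995, names = FALSE)
  # local maxima above threshold
  cand <- which(v > thr)
  cand <- cand[cand > 1L & cand < n]
  cand <- cand[v[cand] >= v[cand - 1L] & v[cand] >= v[cand + 1L]]
  if (length(cand) == 0L) stop_pcg("insufficient cycles: no events detected")
  # enforce refractory separation, keeping the larger peak
  keep <- logical(length(cand))
  ord <- order(v[cand], decreasing = TRUE)
  taken <- rep(FALSE, n)
  min_sep <- round(min_separation * rate)
  for (i in ord) {
    lo <- max(1L, cand[i] - min_sep); hi <- min(n, cand[i] + min_sep)
    if (!any(taken[lo:hi])) { keep[i] <- TRUE; taken[cand[i]] <- TRUE }
  }
  peaks <- sort(cand[keep])

  # boundary refinement on the amplitude envelope
  aenv <- amplitude_envelope(rec, window = rms_window)
  half <- round(0.03 * rate)
  ev <- lapply(peaks, function(p) {
    lo <- max(1L, p - half); hi <- min(n, p + half)
    ap <- lo - 1L + which.max(aenv[lo:hi])
    lim <- boundary_frac * aenv[ap]
    i0 <- ap
    while (i0 > 1L && aenv[i0 - 1L] >= lim) i0 <- i0 - 1L
    i1 <- ap
    while (i1 < n && aenv[i1 + 1L] >= lim) i1 <- i1 + 1L
    c(onset = (i0 - 1) / rate, offset = (i1 - 1) / rate, peak = (ap - 1) / rate)
  })
  ev <- do.call(rbind, ev)
  ev <- ev[order(ev[, "onset"]), , drop = FALSE]
  # merge events whose refined extents overlap (split lobes)
  merged <- list()
  for (i in seq_len(nrow(ev))) {
    m <- length(merged)
    if (m > 0L && ev[i, "onset"] <= merged[[m]]["offset"]) {
      merged[[m]]["offset"] <- max(merged[[m]]["offset"], ev[i, "offset"])
    } else merged[[length(merged) + 1L]] <- ev[i, ]
  }
  ev <- do.call(rbind, merged)

  # drop sub-physiologic blips (shorter than the minimal S2 duration)
  dur <- ev[, "offset"] - ev[, "onset"]
  ev <- ev[dur >= 0.03, , drop = FALSE]
  if (nrow(ev) < 6L) stop_pcg("insufficient cycles: fewer than 3 complete cycles")

  # interval-alternation labeling: gaps between successive onsets alternate
  # systole (S1->S2, shorter) and diastole (S2->S1, longer)
  on <- ev[, "onset"]
  gaps <- diff(on)
  odd_mean <- mean(gaps[seq(1, length(gaps), by = 2)])
  even_mean <- mean(gaps[seq_len(length(gaps)) %% 2 == 0])
  first_is_s1 <- odd_mean < even_mean
  if (!first_is_s1) ev <- ev[-1L, , drop = FALSE]
  if (nrow(ev) %% 2L == 1L) ev <- ev[-nrow(ev), , drop = FALSE]
  if (nrow(ev) < 6L) stop_pcg("insufficient cycles: fewer than 3 complete cycles")

  # alternation consistency check: every systolic gap must be shorter than
  # its neighbouring diastolic gaps
  on <- ev[, "onset"]
  gaps <- diff(on)
  sys_g <- gaps[seq(1, length(gaps), by = 2)]
  dia_g <- gaps[seq_len(length(gaps)) %% 2 == 0]
  if (median(sys_g) >= median(dia_g))
    stop_pcg("segmentation failed: systole/diastole alternation inconsistent")

  # duration-constrained repair: clamp event extents to physiologic bounds
  is_s1 <- rep(c(TRUE, FALSE), length.out = nrow(ev))
  dmax <- ifelse(is_s1, 0.25, 0.20)
  dmin <- ifelse(is_s1, 0.04, 0.03)
  onset <- ev[, "onset"]; offset <- ev[, "offset"]
  dur <- offset - onset
  over <- dur > dmax
  if (any(over)) {   # symmetric clamp around the peak
    c0 <- ev[over, "peak"]
    onset[over] <- pmax(onset[over], c0 - dmax[over] / 2)
    offset[over] <- pmin(offset[over], c0 + dmax[over] / 2)
  }
  under <- (offset - onset) < dmin
  if (any(under)) {
    c0 <- (onset[under] + offset[under]) / 2
    onset[under] <- c0 - dmin[under] / 2
    offset[under] <- c0 + dmin[under] / 2
  }
  segmentation(onset, offset)
}

#' Fraction of true events recovered by a segmentation
#'
#' One-to-one greedy matching of detected S1 (S2) onsets to true S1 (S2)
#' onsets within `tol` seconds; the score is matched events over true
#' events. Used as the corpus retention gate (keep only 1.0 when ground
#' truth is available).
#'
#' @param seg a [segmentation].
#' @param truth a `pcg_truth` object.
#' @param tol matching tolerance in seconds (`> 0`).
#' @return fraction in `[0, 1]`.
#' @export
segmentation_accuracy <- function(seg, truth, tol = 0.01) {
  stopifnot(inherits(seg, "segmentation"), inherits(truth, "pcg_truth"))
  if (tol <= 0) stop_pcg("tol must be > 0")
  n_true <- length(truth$s1_onsets) + length(truth$s2_onsets)
  if (n_true == 0L) stop_pcg("empty ground truth")
  match_count <- function(det, tru) {
    used <- rep(FALSE, length(det))
    hits <- 0L
    for (t0 in tru) {
      d <- abs(det - t0)
      d[used] <- Inf
      j <- which.min(d)
      if (length(j) && is.finite(d[j]) && d[j] <= tol) {
        hits <- hits + 1L
        used[j] <- TRUE
      }
    }
    hits
  }
  hits <- match_count(s1_onsets(seg), truth$s1_onsets) +
    match_count(s2_onsets(seg), truth$s2_onsets)
  hits / n_true
}
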