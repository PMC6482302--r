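#' Construct a PCG (or ECG) recording object
#'
#' The entry object of the pipeline: a mono signal with its sampling rate.
#'
#' @param samples numeric vector of finite amplitudes.
#' @param rate sampling rate in Hz, positive.
#' @param channel `"pcg"` or `"ecg"`.
#' @param id free-form identifier carried through downstream objects.
#' @return an object of class `pcg_recording`.
#' @export
pcg_recording <- function(samples, rate, channel = c("pcg", "ecg"), id = "") {
  channel <- match.arg(channel)
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop_pcg("recording has no samples")
  if (!all(is.finite(samples))) stop_pcg("recording contains non-finite samples")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop_pcg("`rate` must be a positive scalar (Hz)")
  structure(list(samples = samples, rate = as.numeric(rate),
                 channel = channel, id = as.character(id)),
            class = "pcg_recording")
}

#' @export
print.pcg_recording <- function(x, ...) {
  cat(sprintf("<pcg_recording> id='%s' channel=%s rate=%g Hz n=%d (%.1f s)\n",
              x$id, x$channel, x$rate, length(x$samples),
              length(x$samples) / x$rate))
  invisible(x)
}

#' Read a recording from a WAV file
#'
#' @inheritParams pcg_recording
#' @param path WAV file (16-bit PCM mono).
#' @return a [pcg_recording].
#' @export
read_recording <- function(path, channel = "pcg", id = basename(path)) {
  w <- read_wav(path)
  pcg_recording(w$samples, w$rate, channel = channel, id = id)
}

# --- Butterworth design -----------------------------------------------------

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0i) - c(0i, p * rt)
  p
}

# Digital low-pass Butterworth (b, a) via bilinear transform with
# prewarping; DC gain pinned to exactly 1.
butter_lowpass <- function(order, cutoff, rate) {
  if (order < 1) stop_pcg("filter order must be >= 1")
  if (cutoff <= 0 || cutoff >= rate / 2)
    stop_pcg("cutoff must satisfy 0 < cutoff < rate/2 (Nyquist)")
  k <- seq_len(order)
  # analog prototype poles on the unit circle, left half-plane
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  wc <- 2 * rate * tan(pi * cutoff / rate)   # prewarped cutoff (rad/s)
  p <- p * wc
  fs2 <- 2 * rate
  pz <- (fs2 + p) / (fs2 - p)                # bilinear transform
  b <- Re(poly_from_roots(rep(-1 + 0i, order)))
  a <- Re(poly_from_roots(pz))
  gain <- sum(a) / sum(b)                    # H(z=1) = 1
  list(b = b * gain, a = a)
}

# Steady-state initial filter state for a constant input of 1 (direct-form
# II transposed), so zero-phase filtering is transient-free at the edges.
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  bb <- c(b, rep(0, n - length(b))) / a[1]
  aa <- c(a, rep(0, n - length(a))) / a[1]
  if (n == 1L) return(numeric(0))
  A <- matrix(0, n - 1, n - 1)
  A[, 1] <- -aa[-1]
  if (n > 2L) A[cbind(1:(n - 2), 2:(n - 1))] <- 1
  B <- bb[-1] - aa[-1] * bb[1]
  solve(diag(n - 1) - A, B)
}

# Zero-phase filtering: odd-reflection padding, forward and reverse passes,
# each started from the step-response steady state.
filtfilt_pcg <- function(b, a, x) {
  n <- length(x)
  ntaps <- max(length(a), length(b))
  edge <- min(n - 1L, 3L * ntaps)
  if (edge < 1L) stop_pcg("signal too short to filter")
  xpad <- c(2 * x[1] - x[(edge + 1):2], x, 2 * x[n] - x[(n - 1):(n - edge)])
  zi <- lfilter_zi(b, a)
  y <- iir_filter_cpp(b, a, xpad, zi * xpad[1])
  y <- rev(y)
  y <- iir_filter_cpp(b, a, y, zi * y[1])
  y <- rev(y)
  y[(edge + 1):(edge + n)]
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies an order-`order` Butterworth low-pass forward and backward
#' (zero phase, squared magnitude response). Defaults retain S1/S2 energy
#' (most of it lies below ~150 Hz) while suppressing broadband background.
#'
#' @param rec a [pcg_recording].
#' @param cutoff cutoff frequency in Hz; must be below Nyquist.
#' @param order filter order (per pass), `>= 1`.
#' @return a filtered [pcg_recording] of identical length.
#' @export
lowpass <- function(rec, cutoff = 200, order = 4) {
  stopifnot(inherits(rec, "pcg_recording"))
  ba <- butter_lowpass(order, cutoff, rec$rate)
  out <- rec
  out$samples <- filtfilt_pcg(ba$b, ba$a, rec$samples)
  out
}

# --- Envelope ---------------------------------------------------------------

#' Normalized Shannon energy envelope
#'
#' Computes `-u^2 * log(u^2)` of the amplitude-normalized signal
#' (`u = x / max|x|`) and smooths it with a centered moving average. The
#' Shannon energy emphasises mid-intensity components, which makes the S1/S2
#' lobes stand out against both the noise floor and isolated spikes. The
#' result is invariant under amplitude rescaling of the input.
#'
#' @param rec a [pcg_recording].
#' @param window smoothing window length in seconds.
#' @return an object of class `pcg_envelope` with fields `values` and `rate`.
#' @export
shannon_envelope <- function(rec, window = 0.02) {
  stopifnot(inherits(rec, "pcg_recording"))
  if (window <= 0) stop_pcg("`window` must be positive")
  x <- rec$samples
  m <- max(abs(x))
  if (m == 0) {
    vals <- numeric(length(x))
  } else {
    u2 <- (x / m)^2
    e <- ifelse(u2 > 0, -u2 * log(u2), 0)
    vals <- moving_average(e, round(window * rec$rate))
    vals[vals < 0] <- 0
  }
  structure(list(values = vals, rate = rec$rate), class = "pcg_envelope")
}

# Moving-RMS amplitude envelope; used for boundary refinement where the
# Shannon energy (which dips at |x| ~ max) is unsuitable.
amplitude_envelope <- function(rec, window = 0.006) {
  sqrt(moving_average(rec$samples^2, round(window * rec$rate)))
}

# --- Quality preselection ---------------------------------------------------

#' Quality gate ("preselection") for a PCG recording
#'
#' Operationalizes the screening applied before segmentation: recordings
#' dominated by speech/laughter-band noise, aperiodic signals and clipped
#' recordings are rejected. Three checks are applied:
#' \itemize{
#'   \item periodicity: the envelope autocorrelation must show a dominant
#'     peak at some lag in `[0.3, 1.5]` s (a plausible cardiac period);
#'   \item broadband noise: the fraction of spectral power above
#'     `broadband_hz` must not exceed `max_broadband`;
#'   \item clipping: runs of samples pinned at the amplitude extreme.
#' }
#'
#' @param rec a [pcg_recording].
#' @param env its [shannon_envelope].
#' @param min_periodicity minimum normalized autocorrelation peak.
#' @param broadband_hz frequency above which power counts as broadband noise.
#' @param max_broadband maximal allowed broadband power fraction.
#' @param max_clip maximal allowed fraction of pinned samples.
#' @return list with `pass` (logical), `reasons` (character) and `metrics`.
#' @export
preselect <- function(rec, env, min_periodicity = 0.25,
                      broadband_hz = 400, max_broadband = 0.25,
                      max_clip = 0.001) {
  stopifnot(inherits(rec, "pcg_recording"), inherits(env, "pcg_envelope"))
  reasons <- character(0)

  # (a) dominant periodicity of the envelope in [0.3, 1.5] s; the envelope
  # is decimated to ~50 Hz first (it is already smoothed well below that),
  # keeping the autocorrelation cheap on long recordings
  dec <- max(1L, floor(env$rate / 50))
  v <- env$values[seq(1L, length(env$values), by = dec)]
  v <- v - mean(v)
  dec_rate <- env$rate / dec
  lag_max <- min(length(v) - 1L, ceiling(1.5 * dec_rate))
  ac <- acf(v, lag.max = lag_max, plot = FALSE, demean = FALSE)$acf[, 1, 1]
  lags <- seq_along(ac) - 1L
  sel <- lags >= 0.3 * dec_rate & lags <= 1.5 * dec_rate
  peak_ac <- if (any(sel) && ac[1] > 0) max(ac[sel]) else 0
  if (!is.finite(peak_ac)) peak_ac <- 0
  if (peak_ac < min_periodicity)
    reasons <- c(reasons, sprintf(
      "aperiodicity: envelope autocorrelation peak %.3f < %.3f in [0.3, 1.5] s",
      peak_ac, min_periodicity))

  # (b) broadband (speech-band and above) power fraction; zero-padded to a
  # highly composite length (mixed-radix fft degrades badly on prime sizes)
  x <- rec$samples - mean(rec$samples)
  x <- c(x, numeric(stats::nextn(length(x)) - length(x)))
  pw <- Mod(fft(x))^2
  nf <- floor(length(x) / 2)
  freqs <- (seq_len(nf)) * rec$rate / length(x)
  pw <- pw[seq_len(nf) + 1L]
  tot <- sum(pw)
  frac_hi <- if (tot > 0) sum(pw[freqs > broadband_hz]) / tot else 0
  if (frac_hi > max_broadband)
    reasons <- c(reasons, sprintf(
      "broadband noise: %.1f%% of power above %g Hz (limit %.1f%%)",
      100 * frac_hi, broadband_hz, 100 * max_broadband))

  # (c) clipping: >= 3 consecutive samples pinned within 0.1% of the extreme
  a <- abs(rec$samples)
  pinned <- a >= 0.999 * max(a) & max(a) > 0
  r <- rle(pinned)
  clip_n <- sum(r$lengths[r$values & r$lengths >= 3L])
  clip_frac <- clip_n / length(a)
  if (clip_frac > max_clip)
    reasons <- c(reasons, sprintf(
      "clipping: %.2f%% of samples pinned at the amplitude extreme",
      100 * clip_frac))

  list(pass = length(reasons) == 0L, reasons = reasons,
       metrics = list(periodicity = peak_ac, broadband_fraction = frac_hi,
                      clip_fraction = clip_frac))
}
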