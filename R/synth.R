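# Synthetic emotion PCG generator. Stands in for recorded emotion heart
# sounds: per-emotion RR/DS interval dynamics are sampled from a stated
# stochastic model, then rendered as a PCG waveform with exact ground-truth
# annotations for every S1/S2 packet.

#' Per-emotion cardiac dynamics profile
#'
#' Describes the stationary RR-interval process (AR(1): mean, SD, lag-1
#' correlation) and the diastole/systole-ratio process (i.i.d. lognormal:
#' mean, coefficient of variation) of one emotion class.
#'
#' @param emotion one of `"relaxed"`, `"happy"`, `"sad"`, `"angry"`.
#' @param mean_rr mean RR interval in seconds (`> 0`).
#' @param sdnn stationary SD of the RR series in seconds (`>= 0`).
#' @param rr_lag1_corr lag-1 autocorrelation of the RR series, `|.| < 1`.
#' @param mean_ds mean diastole-to-systole duration ratio (`> 0`).
#' @param ds_cv coefficient of variation of the DS ratio (`>= 0`).
#' @param n_beats number of cardiac cycles to generate (`>= 1`).
#' @return an object of class `emotion_profile`.
#' @export
emotion_profile <- function(emotion = c("relaxed", "happy", "sad", "angry"),
                            mean_rr, sdnn, rr_lag1_corr, mean_ds, ds_cv,
                            n_beats) {
  emotion <- match.arg(emotion)
  if (mean_rr <= 0) stop_pcg("mean_rr must be > 0")
  if (sdnn < 0) stop_pcg("sdnn must be >= 0")
  if (abs(rr_lag1_corr) >= 1) stop_pcg("|rr_lag1_corr| must be < 1")
  if (mean_ds <= 0) stop_pcg("mean_ds must be > 0")
  if (ds_cv < 0) stop_pcg("ds_cv must be >= 0")
  n_beats <- as.integer(n_beats)
  if (is.na(n_beats) || n_beats < 1L) stop_pcg("n_beats must be positive")
  if (mean_rr / (1 + mean_ds) <= 0)
    stop_pcg("profile implies non-positive systolic duration")
  structure(list(emotion = emotion, mean_rr = mean_rr, sdnn = sdnn,
                 rr_lag1_corr = rr_lag1_corr, mean_ds = mean_ds,
                 ds_cv = ds_cv, n_beats = n_beats),
            class = "emotion_profile")
}

#' Default emotion profiles
#'
#' The stated synthetic world. Contrasts follow the qualitative regularities
#' of lagged-Poincare point clouds of emotional heart data: high-arousal
#' states (happy, angry) beat faster with denser, less variable interval
#' clouds (lower SDNN) and stronger short-range correlation (hence lower
#' SD1/SD2 across lags); low-arousal states (relaxed, sad) are slower, more
#' variable and less correlated. Valence separates within each arousal level
#' through heart rate and DS-ratio level. Absolute values are physiologically
#' plausible resting figures for young adults, chosen once and fixed.
#'
#' @param n_beats cycles per generated segment.
#' @return named list of four [emotion_profile] objects.
#' @export
default_profiles <- function(n_beats = 200L) {
  list(
    relaxed = emotion_profile("relaxed", mean_rr = 0.92, sdnn = 0.060,
                              rr_lag1_corr = 0.30, mean_ds = 1.80,
                              ds_cv = 0.08, n_beats = n_beats),
    happy   = emotion_profile("happy",   mean_rr = 0.75, sdnn = 0.035,
                              rr_lag1_corr = 0.65, mean_ds = 1.50,
                              ds_cv = 0.05, n_beats = n_beats),
    sad     = emotion_profile("sad",     mean_rr = 0.86, sdnn = 0.050,
                              rr_lag1_corr = 0.40, mean_ds = 1.70,
                              ds_cv = 0.10, n_beats = n_beats),
    angry   = emotion_profile("angry",   mean_rr = 0.68, sdnn = 0.025,
                              rr_lag1_corr = 0.75, mean_ds = 1.35,
                              ds_cv = 0.04, n_beats = n_beats)
  )
}

#' Sample RR and DS interval series for one emotion profile
#'
#' RR intervals follow a stationary AR(1) process with the profile's mean,
#' SD and lag-1 correlation, truncated to `rr > 0.25` s. DS ratios are
#' i.i.d. lognormal with the profile's mean and CV, truncated so the implied
#' systolic duration `rr / (1 + ds)` stays `>= 0.15` s. Truncation redraws
#' the innovation (up to 100 times, then clamps); with the default profiles
#' it essentially never triggers.
#'
#' @param profile an [emotion_profile].
#' @param seed integer seed; identical seeds give identical output.
#' @return list with `rr` and `ds`, both of length `profile$n_beats`
#'   (one value per rendered cardiac cycle).
#' @export
sample_interval_series <- function(profile, seed) {
  stopifnot(inherits(profile, "emotion_profile"))
  n <- profile$n_beats
  if (n < 1L) stop_pcg("n_beats must be positive")
  mu <- profile$mean_rr
  sig <- profile$sdnn
  phi <- profile$rr_lag1_corr
  with_seed(seed, {
    rr <- numeric(n)
    innov_sd <- sig * sqrt(1 - phi^2)
    draw_trunc <- function(gen, ok) {
      for (i in seq_len(100L)) {
        v <- gen()
        if (ok(v)) return(v)
      }
      v
    }
    prev <- draw_trunc(function() rnorm(1, mu, sig), function(v) v > 0.25)
    rr[1] <- max(prev, 0.2500001)
    if (n > 1L) for (i in 2:n) {
      v <- draw_trunc(function() mu + phi * (rr[i - 1] - mu) +
                        rnorm(1, 0, innov_sd),
                      function(v) v > 0.25)
      rr[i] <- max(v, 0.2500001)
    }
    if (sig == 0) rr <- rep(mu, n)

    if (profile$ds_cv == 0) {
      ds <- rep(profile$mean_ds, n)
    } else {
      sdlog <- sqrt(log(1 + profile$ds_cv^2))
      meanlog <- log(profile$mean_ds) - sdlog^2 / 2
      ds <- numeric(n)
      for (i in seq_len(n)) {
        ds[i] <- draw_trunc(function() exp(rnorm(1, meanlog, sdlog)),
                            function(v) rr[i] / (1 + v) >= 0.15)
        ds[i] <- min(ds[i], rr[i] / 0.15 - 1)
      }
    }
    if (any(rr / (1 + ds) <= 0))
      stop_pcg("parameters imply non-positive systolic durations")
    list(rr = rr, ds = ds)
  })
}

# S1/S2 wave-packet constants: textbook auscultation figures. The Gaussian
# window sigma = dur / (2*sqrt(2*log(10))) puts the 10%-amplitude points of
# each packet exactly at its annotated onset/offset, so envelope-threshold
# boundary detection has a well-defined target.
.pcg_packets <- list(
  s1 = list(freq = 80,  dur = 0.12, amp = 1.0),
  s2 = list(freq = 120, dur = 0.09, amp = 0.8)
)

packet_wave <- function(tt, center, freq, dur, amp) {
  sigma <- dur / (2 * sqrt(2 * log(10)))
  amp * exp(-(tt - center)^2 / (2 * sigma^2)) * sin(2 * pi * freq * (tt - center))
}

#' Render a PCG waveform from RR and DS interval series
#'
#' Each cardiac cycle `i` starts with an S1 packet (Gaussian-windowed 80 Hz
#' tone burst, 0.12 s) at the cycle start `t_i`, followed by an S2 packet
#' (120 Hz, 0.09 s) at `t_i + systole_i`, where
#' `systole = rr / (1 + ds)` and `diastole = rr * ds / (1 + ds)`.
#' Additive white Gaussian noise is scaled to the requested SNR
#' (`snr_db = Inf` disables noise). Ground truth records every packet
#' boundary plus the implied RR/DS series.
#'
#' @param rr RR intervals in seconds, one per cycle.
#' @param ds DS ratios, same length as `rr`.
#' @param rate sampling rate in Hz (`>= 1000`).
#' @param snr_db signal-to-noise ratio in dB; `Inf` for noise-free.
#' @param seed integer seed for the noise.
#' @param lead_in leading silence in seconds.
#' @return list with `rec` (a [pcg_recording]) and `truth` (class
#'   `pcg_truth`: `s1_onsets`, `s1_offsets`, `s2_onsets`, `s2_offsets`,
#'   `rpeaks`, `rr_true`, `ds_true`, all in seconds from record start).
#' @export
render_pcg <- function(rr, ds, rate = 2000, snr_db = 20, seed = 1,
                       lead_in = 0.25) {
  if (length(rr) != length(ds)) stop_pcg("rr and ds must have equal length")
  if (length(rr) < 1L) stop_pcg("need at least one cycle")
  if (rate < 1000) stop_pcg("rate must be >= 1000 Hz")
  if (any(rr <= 0) || any(ds <= 0)) stop_pcg("rr and ds must be positive")
  if (is.na(snr_db)) stop_pcg("snr_db must be a number or Inf")
  n <- length(rr)
  sys_d <- rr / (1 + ds)
  dia_d <- rr - sys_d
  p1 <- .pcg_packets$s1; p2 <- .pcg_packets$s2
  if (any(sys_d <= p1$dur)) stop_pcg("systole shorter than the S1 packet")
  if (any(dia_d <= p2$dur)) stop_pcg("diastole shorter than the S2 packet")

  starts <- lead_in + c(0, cumsum(rr))[seq_len(n)]
  s1_on <- starts
  s1_off <- starts + p1$dur
  s2_on <- starts + sys_d
  s2_off <- s2_on + p2$dur

  total <- lead_in + sum(rr) + lead_in
  nsamp <- ceiling(total * rate)
  t <- (seq_len(nsamp) - 1) / rate
  x <- numeric(nsamp)
  place <- function(on, off, freq, dur, amp) {
    i0 <- max(1L, floor(on * rate) + 1L)
    i1 <- min(nsamp, ceiling(off * rate))
    idx <- i0:i1
    idx <- idx[t[idx] >= on & t[idx] < off]
    x[idx] <<- x[idx] + packet_wave(t[idx], (on + off) / 2, freq, dur, amp)
  }
  for (i in seq_len(n)) {
    place(s1_on[i], s1_off[i], p1$freq, p1$dur, p1$amp)
    place(s2_on[i], s2_off[i], p2$freq, p2$dur, p2$amp)
  }
  if (is.finite(snr_db)) {
    sig_pow <- mean(x^2)
    if (sig_pow <= 0) stop_pcg("SNR specified but the signal has zero power")
    noise_sd <- sqrt(sig_pow / 10^(snr_db / 10))
    x <- x + with_seed(seed, rnorm(nsamp, 0, noise_sd))
  }

  truth <- structure(list(
    s1_onsets = s1_on, s1_offsets = s1_off,
    s2_onsets = s2_on, s2_offsets = s2_off,
    rpeaks = starts,
    rr_true = if (n > 1L) rr[-n] else numeric(0),
    ds_true = if (n > 1L) ds[-n] else numeric(0)
  ), class = "pcg_truth")
  list(rec = pcg_recording(x, rate, channel = "pcg"), truth = truth)
}

#' Ground-truth segmentation arrays
#'
#' Converts a `pcg_truth` annotation into the interleaved onset/offset array
#' representation used by the segmenter (odd entries S1, even entries S2),
#' for identity checks of the interval-series computations.
#'
#' @param truth a `pcg_truth` object.
#' @return a [segmentation] object.
#' @export
truth_segmentation <- function(truth) {
  stopifnot(inherits(truth, "pcg_truth"))
  n <- length(truth$s1_onsets)
  thb <- as.vector(rbind(truth$s1_onsets, truth$s2_onsets))
  tha <- as.vector(rbind(truth$s1_offsets, truth$s2_offsets))
  segmentation(thb, tha)
}

#' Generate a labeled synthetic emotion heart-sound corpus
#'
#' Writes one WAV per segment, a JSON ground-truth sidecar per WAV, and a
#' CSV manifest with columns `path,emotion,subject,session`. The default
#' segment length of 150 s mirrors splitting 300-s emotion recordings in
#' half; default class counts (43/21/18/14 for relaxed/happy/sad/angry, 96
#' segments) mirror a published emotion heart-sound corpus layout.
#'
#' @param dir output directory (created if missing).
#' @param profiles named list of [emotion_profile]s.
#' @param counts integer vector of segment counts, aligned with `profiles`.
#' @param segment_seconds nominal duration of each segment.
#' @param rate sampling rate in Hz.
#' @param snr_db rendering SNR in dB.
#' @param seed base integer seed; each segment uses a deterministic offset.
#' @param n_subjects subjects to cycle segment attribution over.
#' @return the manifest as a data frame, invisibly; written to
#'   `dir/manifest.csv`.
#' @export
make_dataset <- function(dir, profiles = default_profiles(),
                         counts = c(43L, 21L, 18L, 14L),
                         segment_seconds = 150, rate = 2000, snr_db = 20,
                         seed = 1, n_subjects = 16L) {
  if (length(counts) != length(profiles))
    stop_pcg("`counts` must align with `profiles`")
  if (any(counts < 0)) stop_pcg("counts must be non-negative")
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop_pcg("cannot create output directory '%s'", dir)
  rows <- list()
  gidx <- 0L
  for (ci in seq_along(profiles)) {
    prof <- profiles[[ci]]
    for (si in seq_len(counts[ci])) {
      gidx <- gidx + 1L
      seg_seed <- (as.integer(seed) %% 100000L) * 10000L + gidx
      p <- prof
      p$n_beats <- as.integer(ceiling(segment_seconds / prof$mean_rr)) + 2L
      iv <- sample_interval_series(p, seg_seed)
      rend <- render_pcg(iv$rr, iv$ds, rate = rate, snr_db = snr_db,
                         seed = seg_seed + 1L)
      fname <- sprintf("%s_%03d.wav", prof$emotion, si)
      write_wav(rend$rec$samples * 0.9 / max(abs(rend$rec$samples)),
                rate, file.path(dir, fname))
      tr <- unclass(rend$truth)
      jsonlite::write_json(tr, file.path(dir, sub("\\.wav$", ".json", fname)),
                           digits = NA, auto_unbox = FALSE)
      rows[[gidx]] <- data.frame(
        path = fname, emotion = prof$emotion,
        subject = sprintf("s%02d", ((gidx - 1L) %% n_subjects) + 1L),
        session = si, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  if (is.null(manifest)) stop_pcg("no segments requested")
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a ground-truth sidecar written by [make_dataset()]
#'
#' @param path JSON sidecar path.
#' @return a `pcg_truth` object.
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- lapply(tr, as.numeric)
  structure(tr, class = "pcg_truth")
}
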