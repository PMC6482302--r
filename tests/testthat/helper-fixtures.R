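# Shared fixtures, built in code at test time.

# Short synthetic recording with ground truth.
make_fixture_pcg <- function(n_beats = 30L, emotion = "relaxed",
                             snr_db = 20, seed = 1L) {
  prof <- default_profiles(n_beats)[[emotion]]
  iv <- sample_interval_series(prof, seed)
  c(render_pcg(iv$rr, iv$ds, snr_db = snr_db, seed = seed + 1L),
    list(rr = iv$rr, ds = iv$ds))
}

# Worked example of the interleaved boundary arrays (3 cycles).
example_segmentation <- function() {
  segmentation(thb = c(0.00, 0.30, 0.80, 1.10, 1.62, 1.93),
               tha = c(0.12, 0.40, 0.92, 1.20, 1.74, 2.03),
               check = FALSE)
}

# Independent naive double-loop evaluation of the lagged-Poincare
# dispersions (the oracle for lpp()).
naive_lpp <- function(x, M) {
  n <- length(x)
  xb <- mean(x)
  s1 <- 0
  s2 <- 0
  for (i in 1:(n - M)) {
    s1 <- s1 + (x[i] - x[i + M])^2 / 2
    s2 <- s2 + (x[i] + x[i + M] - 2 * xb)^2 / 2
  }
  list(sd1 = sqrt(s1 / (n - M)), sd2 = sqrt(s2 / (n - M)))
}

# Independent Lomb power via per-frequency least squares: the classic
# tau-rotated periodogram equals the explained sum of squares of fitting
# centered data on span{sin, cos} without intercept (the tau rotation is
# just an orthogonal change of basis within that span).
naive_lomb <- function(x, t, f) {
  xc <- x - mean(x)
  vapply(f, function(fi) {
    s <- sin(2 * pi * fi * t); cc <- cos(2 * pi * fi * t)
    fit <- stats::lm(xc ~ 0 + s + cc)
    (sum(xc^2) - sum(stats::residuals(fit)^2)) / length(x)
  }, numeric(1))
}

# Two-class Gaussian toy classification problem.
make_two_class <- function(n_per = 30L, sep = 2, d = 2L, seed = 1L) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * d, -sep / 2), ncol = d),
             matrix(rnorm(n_per * d, sep / 2), ncol = d))
  list(x = x, y = factor(rep(c("low", "high"), each = n_per),
                         levels = c("low", "high")))
}
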