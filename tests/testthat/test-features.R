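test_that("lpp reproduces hand-computed and degenerate cases", {
  r <- lpp(c(0.7, 0.8, 0.9), M = 1)
  expect_equal(r$sd1, 0.0707107, tolerance = 1e-6)
  expect_equal(r$sd2, 0.0707107, tolerance = 1e-6)
  expect_equal(r$sd12, 1.0, tolerance = 1e-9)
  expect_equal(r$area, pi * r$sd1 * r$sd2)

  const <- lpp(rep(0.8, 10), M = 3)
  expect_equal(const$sd1, 0)
  expect_equal(const$sd2, 0)
  expect_true(is.na(const$sd12))

  # lag-2 pairs of an alternating series are equal: sd1 = 0
  alt <- lpp(c(0.8, 1.0, 0.8, 1.0), M = 2)
  expect_equal(alt$sd1, 0)

  expect_error(lpp(c(0.8, 0.9), M = 2), "M")
  expect_error(lpp(c(0.8, 0.9), M = 0), "M")
})

test_that("lpp equals the naive double-loop oracle on random series", {
  set.seed(123)
  for (k in 1:100) {
    n <- sample(10:200, 1)
    x <- rnorm(n, 0.8, 0.1)
    M <- sample(seq_len(min(20, n - 1)), 1)
    naive <- naive_lpp(x, M)
    got <- lpp(x, M)
    expect_equal(got$sd1, naive$sd1, tolerance = 1e-12)
    expect_equal(got$sd2, naive$sd2, tolerance = 1e-12)
    # algebraic identity: sd1^2 + sd2^2 equals the summed squared
    # deviations of both cloud coordinates around the series mean
    i <- seq_len(n - M)
    rhs <- sum((x[i] - mean(x))^2 + (x[i + M] - mean(x))^2) / (n - M)
    expect_equal(got$sd1^2 + got$sd2^2, rhs, tolerance = 1e-9)
  }
})

test_that("lpp dispersion is translation invariant and scales linearly", {
  set.seed(5)
  x <- rnorm(80, 0.9, 0.08)
  base <- lpp(x, 4)
  shift <- lpp(x + 2, 4)
  expect_equal(shift$sd1, base$sd1, tolerance = 1e-12)
  expect_equal(shift$sd2, base$sd2, tolerance = 1e-12)
  scl <- lpp(3 * x, 4)
  expect_equal(scl$sd1, 3 * base$sd1, tolerance = 1e-12)
  expect_equal(scl$sd2, 3 * base$sd2, tolerance = 1e-12)
  expect_equal(scl$sd12, base$sd12, tolerance = 1e-12)
})

test_that("time-domain features match hand arithmetic", {
  s <- interval_series(c(0.7, 0.8, 0.9), "hs_rr")
  td <- time_domain(s)
  expect_equal(td[["mean"]], 0.8)
  expect_equal(td[["sdnn"]], 0.1)
  expect_equal(td[["rmssd"]], 0.1)
  expect_equal(td[["cv"]], 0.125)
  expect_equal(td[["median"]], 0.8)
  expect_named(td, c("mean", "sdnn", "rmssd", "pnn50", "cv", "median", "mad"))

  cs <- interval_series(rep(0.75, 10), "hs_rr")
  tdc <- time_domain(cs)
  expect_equal(unname(tdc[c("sdnn", "rmssd", "pnn50", "cv")]), rep(0, 4))

  # 1 jump > 50 ms among 10 successive differences
  v <- c(0.8, 0.8 + cumsum(c(rep(0.01, 9), 0.06)))
  d <- interval_series(v, "hs_rr")
  expect_equal(time_domain(d)[["pnn50"]], 0.1)

  # DS-kind series omit pnn50
  ds <- interval_series(c(1.5, 1.6, 1.7), "hs_ds")
  expect_named(time_domain(ds), c("mean", "sdnn", "rmssd", "cv", "median", "mad"))
  expect_error(time_domain(interval_series(c(1, 2), "hs_rr")), "length >= 3")
})

test_that("lomb band powers localize a planted modulation", {
  # RR modulated sinusoidally at 0.10 Hz (LF band)
  set.seed(31)
  n <- 120
  rr <- numeric(n); t <- 0
  for (i in seq_len(n)) {
    rr[i] <- 0.8 + 0.05 * sin(2 * pi * 0.10 * t)
    t <- t + rr[i]
  }
  fd <- frequency_domain(interval_series(rr, "hs_rr"))
  expect_gt(fd[["lf"]] / (fd[["lf"]] + fd[["hf"]]), 0.9)
  expect_equal(fd[["lf_nu"]] + fd[["hf_nu"]], 1, tolerance = 1e-9)

  # same tone in the HF band
  rr2 <- numeric(n); t <- 0
  for (i in seq_len(n)) {
    rr2[i] <- 0.8 + 0.05 * sin(2 * pi * 0.30 * t)
    t <- t + rr2[i]
  }
  fd2 <- frequency_domain(interval_series(rr2, "hs_rr"))
  expect_gt(fd2[["hf"]] / (fd2[["lf"]] + fd2[["hf"]]), 0.9)
})

test_that("lomb power agrees with a per-frequency least-squares oracle", {
  set.seed(77)
  x <- rnorm(60, 1.5, 0.2)
  t <- cumsum(runif(60, 0.7, 1.0))
  f <- c(0.05, 0.11, 0.23, 0.37)
  expect_equal(pcgemotion:::lomb_power(x, t, f), naive_lomb(x, t, f),
               tolerance = 1e-9)
})

test_that("degenerate frequency-domain inputs are handled", {
  const <- interval_series(rep(0.8, 40), "hs_rr")
  fd <- frequency_domain(const)
  expect_equal(unname(fd[c("vlf", "lf", "hf")]), rep(0, 3))
  expect_true(is.na(fd[["lf_hf"]]))
  expect_error(frequency_domain(interval_series(rep(0.8, 10), "hs_rr")),
               "length >= 32")
  # white-noise series: neither band dominates wildly
  set.seed(41)
  lfhf <- replicate(5, {
    s <- interval_series(rnorm(100, 0.8, 0.05), "hs_rr")
    fd <- frequency_domain(s)
    fd[["lf"]] / fd[["hf"]]
  })
  expect_true(all(lfhf > 0.1 & lfhf < 10))
})

test_that("feature blocks close the 79/75/154 dimension budget", {
  fx <- make_fixture_pcg(40, "relaxed", seed = 29)
  seg <- truth_segmentation(fx$truth)
  fv_rr <- feature_block(hs_hrv(seg))
  fv_ds <- feature_block(hs_dsv(seg))
  expect_length(fv_rr$values, 79)
  expect_length(fv_ds$values, 75)
  expect_equal(fv_rr$block, "hs_hrv")
  expect_equal(fv_ds$block, "hs_dsv")
  expect_false(anyDuplicated(fv_rr$names) > 0)

  hd <- combine_blocks(fv_rr, fv_ds)
  expect_length(hd$values, 154)
  expect_false(anyDuplicated(hd$names) > 0)
  expect_equal(hd$block, "hs_hd")

  # ECG RR block has the RR layout
  fv_ecg <- feature_block(ecg_rr(fx$truth$rpeaks))
  expect_length(fv_ecg$values, 79)
  expect_equal(fv_ecg$block, "ecg_hrv")

  short <- interval_series(rep(c(0.8, 0.82), 8), "hs_rr")
  expect_error(feature_block(short), "too short")
})

test_that("build_matrix stacks, validates and median-imputes", {
  fx1 <- make_fixture_pcg(40, "relaxed", seed = 1)
  fx2 <- make_fixture_pcg(40, "happy", seed = 2)
  fv <- lapply(list(fx1, fx2), function(f)
    feature_block(hs_hrv(truth_segmentation(f$truth))))
  m <- build_matrix(fv)
  expect_equal(dim(m), c(2L, 79L))
  expect_equal(colnames(m), fv[[1]]$names)
  expect_error(build_matrix(list()), "empty")
  expect_equal(dim(build_matrix(fv[1])), c(1L, 79L))

  # a planted NA is imputed with the column median and recorded
  fv[[1]]$values[5] <- NA_real_
  m2 <- build_matrix(fv)
  expect_equal(unname(m2[1, 5]), fv[[2]]$values[5])
  expect_true(attr(m2, "imputed")[1, 5])
  # inconsistent names rejected
  fvx <- fv
  fvx[[2]]$names[1] <- "bogus"
  expect_error(build_matrix(fvx), "inconsistent")
})
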