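# Feature extraction from interval series: time-domain statistics,
# Lomb-Scargle band powers, and lagged-Poincare (LPP) descriptors. The
# default registry closes the published block sizes exactly:
#   RR-kind block: 7 time + 6 frequency + 3 x 22 LPP = 79 features
#   DS-kind block: 6 time + 3 frequency + 3 x 22 LPP = 75 features
#   combined heart-sound block (hs_hd): 79 + 75 = 154 features.

#' Lagged-Poincare summary of an interval series
#'
#' For lag `M`, the Poincare cloud plots `x_i` against `x_{i+M}`. Its
#' short- and long-axis dispersions are
#' \deqn{SD1 = \sqrt{\frac{1}{N-M}\sum_{i=1}^{N-M} (x_i - x_{i+M})^2 / 2}}
#' \deqn{SD2 = \sqrt{\frac{1}{N-M}\sum_{i=1}^{N-M} (x_i + x_{i+M} - 2\bar x)^2 / 2}}
#' with \eqn{\bar x} the full-series mean, and `SD12 = SD1/SD2`. Note the
#' `1/(N-M)` normalization (not `N-M-1`), implemented exactly as defined.
#' `SD12` is `NA` when `SD2 = 0` (recorded as missing; median-imputed at
#' matrix assembly).
#'
#' @param series an [interval_series] (or bare numeric vector).
#' @param M lag, `1 <= M < length(series)`.
#' @return list of class `lpp_summary`: `M`, `sd1`, `sd2`, `sd12`, `area`
#'   (`pi * sd1 * sd2`).
#' @export
lpp <- function(series, M = 1L) {
  x <- if (inherits(series, "interval_series")) series$values else as.numeric(series)
  n <- length(x)
  M <- as.integer(M)
  if (M < 1L) stop_pcg("lag M must be >= 1")
  if (M >= n) stop_pcg("lag M must be < series length")
  i <- seq_len(n - M)
  xb <- mean(x)
  sd1 <- sqrt(sum((x[i] - x[i + M])^2 / 2) / (n - M))
  sd2 <- sqrt(sum((x[i] + x[i + M] - 2 * xb)^2 / 2) / (n - M))
  sd12 <- if (sd2 > 0) sd1 / sd2 else NA_real_
  structure(list(M = M, sd1 = sd1, sd2 = sd2, sd12 = sd12,
                 area = pi * sd1 * sd2), class = "lpp_summary")
}

#' Time-domain interval statistics
#'
#' Standard beat-interval statistics: `mean`, `sdnn` (sample SD, `N-1`
#' denominator), `rmssd`, `cv = sdnn/mean`, `median`, `mad`, and for
#' RR-kind series additionally `pnn50` (fraction of successive differences
#' exceeding 50 ms).
#'
#' @param series an [interval_series], length >= 3.
#' @return named numeric vector (7 values for RR kinds, 6 for DS).
#' @export
time_domain <- function(series) {
  stopifnot(inherits(series, "interval_series"))
  x <- series$values
  if (length(x) < 3L) stop_pcg("series too short: need length >= 3")
  d <- diff(x)
  out <- c(mean = mean(x), sdnn = sd(x),
           rmssd = sqrt(mean(d^2)), cv = sd(x) / mean(x),
           median = median(x), mad = mad(x))
  if (is_rr_kind(series)) {
    out <- c(out[1:3], pnn50 = mean(abs(d) > 0.05), out[4:6])
  }
  out
}

# Lomb-Scargle periodogram (classic tau-shifted form) of x observed at
# times t, evaluated at frequencies f. Unnormalized power; only band
# ratios and relative magnitudes are consumed downstream.
lomb_power <- function(x, t, f) {
  xc <- x - mean(x)
  vapply(f, function(fi) {
    w <- 2 * pi * fi
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
    (sum(xc * ct)^2 / sum(ct^2) + sum(xc * st)^2 / sum(st^2)) / length(x)
  }, numeric(1))
}

#' Frequency-domain interval features (Lomb-Scargle band powers)
#'
#' RR-kind series are treated as unevenly sampled in beat time (the
#' cumulative RR sum) and summarized by standard short-term HRV bands:
#' VLF 0.003-0.04, LF 0.04-0.15, HF 0.15-0.4 Hz, plus `lf_hf` and the
#' normalized powers `lf_nu`, `hf_nu` (fractions of LF+HF). DS-kind series
#' live on the cycle-index axis; the LF/HF bands are reused in units of
#' cycles per beat, yielding `lf`, `hf`, `lf_hf`.
#'
#' @param series an [interval_series], length >= 32.
#' @param oversample frequency-grid oversampling factor.
#' @return named numeric vector (6 values for RR kinds, 3 for DS).
#'   Ratios are `NA` when their denominator is zero (e.g. constant input).
#' @export
frequency_domain <- function(series, oversample = 4) {
  stopifnot(inherits(series, "interval_series"))
  x <- series$values
  if (length(x) < 32L) stop_pcg("series too short: need length >= 32")
  rr_kind <- is_rr_kind(series)
  t <- if (rr_kind) cumsum(x) else seq_along(x)
  span <- t[length(t)] - t[1]
  df <- 1 / (span * oversample)
  fmax <- 0.4
  f <- seq(df, fmax, by = df)
  if (sd(x) == 0) {
    p <- rep(0, length(f))
  } else {
    p <- lomb_power(x, t, f)
  }
  band <- function(lo, hi) sum(p[f > lo & f <= hi]) * df
  vlf <- band(0.003, 0.04); lf <- band(0.04, 0.15); hf <- band(0.15, 0.4)
  lf_hf <- if (hf > 0) lf / hf else NA_real_
  if (rr_kind) {
    tot <- lf + hf
    c(vlf = vlf, lf = lf, hf = hf, lf_hf = lf_hf,
      lf_nu = if (tot > 0) lf / tot else NA_real_,
      hf_nu = if (tot > 0) hf / tot else NA_real_)
  } else {
    c(lf = lf, hf = hf, lf_hf = lf_hf)
  }
}

#' Full named feature block for one interval series
#'
#' Concatenates time-domain, frequency-domain and lagged-Poincare features
#' (`sd1`, `sd2`, `sd12` for every lag `M = 1..m_max`). With the default
#' `m_max = 22` this yields 79 features for RR-kind series and 75 for DS
#' series; names are deterministic and ordered.
#'
#' @param series an [interval_series] of length `> m_max`.
#' @param m_max maximal Poincare lag.
#' @return object of class `feature_vector`: fields `names`, `values`,
#'   `block` (`"hs_hrv"`, `"hs_dsv"` or `"ecg_hrv"`).
#' @export
feature_block <- function(series, m_max = 22L) {
  stopifnot(inherits(series, "interval_series"))
  if (length(series$values) <= m_max)
    stop_pcg("series too short for lag sweep: need length > %d", m_max)
  td <- time_domain(series)
  fd <- frequency_domain(series)
  lp <- lapply(seq_len(m_max), function(m) lpp(series, m))
  lp_vals <- unlist(lapply(lp, function(s) c(s$sd1, s$sd2, s$sd12)))
  lp_names <- unlist(lapply(seq_len(m_max), function(m)
    paste0(c("sd1_m", "sd2_m", "sd12_m"), m)))
  block <- switch(series$kind, hs_rr = "hs_hrv", hs_ds = "hs_dsv",
                  ecg_rr = "ecg_hrv")
  structure(list(names = c(names(td), names(fd), lp_names),
                 values = unname(c(td, fd, lp_vals)),
                 block = block),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> block=%s D=%d (%d missing)\n",
              x$block, length(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' Combine heart-sound HRV and DSV blocks into the joint block
#'
#' Names are block-prefixed (`hrv_`, `dsv_`), so the 79 + 75 features
#' concatenate without collisions into the 154-dimensional combined block.
#'
#' @param fv_hrv a `feature_vector` with block `"hs_hrv"`.
#' @param fv_dsv a `feature_vector` with block `"hs_dsv"`.
#' @return a `feature_vector` with block `"hs_hd"`.
#' @export
combine_blocks <- function(fv_hrv, fv_dsv) {
  stopifnot(inherits(fv_hrv, "feature_vector"),
            inherits(fv_dsv, "feature_vector"))
  if (fv_hrv$block != "hs_hrv" || fv_dsv$block != "hs_dsv")
    stop_pcg("combine_blocks() expects an hs_hrv and an hs_dsv block")
  structure(list(names = c(paste0("hrv_", fv_hrv$names),
                           paste0("dsv_", fv_dsv$names)),
                 values = c(fv_hrv$values, fv_dsv$values),
                 block = "hs_hd"),
            class = "feature_vector")
}

#' Assemble a feature matrix from per-segment feature vectors
#'
#' Rows are segments, columns features in the (uniform) name order of the
#' first vector. Missing values (e.g. `sd12` of a constant series) are
#' imputed by the column median; the imputation positions are recorded in
#' the `"imputed"` attribute.
#'
#' @param fvs list of `feature_vector`s sharing one block.
#' @return numeric matrix with feature names as columns and attributes
#'   `block` and `imputed` (logical matrix).
#' @export
build_matrix <- function(fvs) {
  if (length(fvs) == 0L) stop_pcg("empty corpus")
  nm <- fvs[[1]]$names
  blk <- fvs[[1]]$block
  rows <- lapply(fvs, function(fv) {
    if (!identical(fv$names, nm) || !identical(fv$block, blk))
      stop_pcg("inconsistent feature names/blocks across segments")
    fv$values
  })
  m <- do.call(rbind, rows)
  colnames(m) <- nm
  imputed <- is.na(m)
  for (j in which(colSums(imputed) > 0L)) {
    med <- median(m[, j], na.rm = TRUE)
    if (is.na(med)) med <- 0
    m[imputed[, j], j] <- med
  }
  attr(m, "block") <- blk
  attr(m, "imputed") <- imputed
  m
}

#' Write a feature matrix as CSV with a JSON sidecar
#'
#' @param m matrix from [build_matrix()].
#' @param path CSV path; the sidecar is written next to it.
#' @param labels optional label vector stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(m, path, labels = NULL) {
  write.csv(as.data.frame(m), path, row.names = FALSE)
  side <- list(block = attr(m, "block"),
               n_imputed = sum(attr(m, "imputed") %||% FALSE),
               labels = labels)
  jsonlite::write_json(side, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
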