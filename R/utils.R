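#' @useDynLib pcgemotion, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats acf fft nextn mad median quantile rnorm runif runmed sd
#' @importFrom utils read.csv write.csv
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All package randomness flows through this helper; no global state leaks.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Centered moving average; window in samples, edges use shrunken windows.
moving_average <- function(x, k) {
  moving_average_cpp(as.numeric(x), as.integer(max(1L, k)))
}

stop_pcg <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
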