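#' @keywords internal
#' @useDynLib glycohrv, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

# Deterministic 31-bit sub-seed derived from a master seed and a stage tag,
# so each generator stage has its own reproducible RNG stream.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(as.numeric(seed)) * 69069 + h * 1013 + 1) %% 2147483647)
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  invisible(x)
}

# Fisher skewness g1 = m3 / m2^{3/2} (population moments).
moment_skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  mean((x - m)^3) / m2^1.5
}

# Excess kurtosis g2 = m4 / m2^2 - 3 (population moments).
moment_kurtosis <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  mean((x - m)^4) / m2^2 - 3
}

`%||%` <- function(a, b) if (is.null(a)) b else a
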