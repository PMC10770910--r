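#' @useDynLib mmnpipe, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rchisq qt pt pchisq sd mad median quantile
#'   cor integrate t.test fft mvfft nextn approx lm coef logLik rpois rbinom
#'   setNames aggregate complete.cases
NULL

# Derive n reproducible child seeds (< 2^31) from a master seed without
# disturbing the caller's RNG state beyond one set.seed().
derive_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(master_seed)
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  expr
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

assert_scalar_pos <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stopf("invalid argument: %s must be a positive finite scalar", what)
}
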