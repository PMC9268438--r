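#' @useDynLib ginsengms, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor cov lm coef predict rnorm runif sd var
#' @importFrom utils read.csv write.csv
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Documented sub-seed scheme: every stochastic stage draws its own seed from
# the master seed and a small stage offset, keeping results < 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 99991 * as.numeric(offset)) %% 2147483629) + 1L
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, lower = -Inf, upper = Inf, len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x))
    stop_field(field, sprintf("must be a numeric vector of length %d", len))
  if (any(x < lower) || any(x > upper))
    stop_field(field, sprintf("must lie in [%s, %s]", format(lower), format(upper)))
  invisible(x)
}
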