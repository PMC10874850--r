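#' @importFrom stats sd median mad quantile rnorm runif rgamma rbinom fft
#'   complete.cases aggregate predict coef vcov pt setNames na.omit var cor
#' @importFrom utils read.csv write.csv head tail
NULL

# Sample (n-1) standard deviation is used everywhere in the package.

#' Evaluate an expression under a local RNG seed
#'
#' All stochastic operations in the package route their randomness through a
#' caller-supplied integer seed; the global RNG stream is left untouched.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Derive a child seed from a master seed and a stream index, kept < 2^31.
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 8191) %% 2147483647L)
}

#' Z-score a numeric vector using the sample standard deviation
#'
#' @param x numeric vector.
#' @return z-scored vector, or all-`NA` if the vector is constant.
#' @keywords internal
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(NA_real_, length(x)))
  (x - mean(x)) / s
}

stop_mea <- function(class, msg, ...) {
  stop(structure(class = c(class, "meaphys_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
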