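#' @importFrom stats coef glm lm median na.omit optim pt qnorm quantile rbinom
#'   rlnorm rnorm rpois runif sd setNames t.test var binomial cor.test fitted
#'   nls.control predict
#' @importFrom utils head read.csv write.csv tail
NULL

# Internal: stop with a message naming the violated invariant.
fail_invariant <- function(what, msg) {
  stop(sprintf("invalid %s: %s", what, msg), call. = FALSE)
}

check_that <- function(cond, what, msg) {
  if (!isTRUE(cond)) fail_invariant(what, msg)
  invisible(TRUE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Multiplicative lognormal noise with unit mean and coefficient of variation cv.
lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Derive a stream of child seeds from a master seed, all below 2^31.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

# Evaluate fn() under a temporary seed when one is given, untouched otherwise.
with_opt_seed <- function(seed, fn) {
  if (is.null(seed)) fn() else withr::with_seed(as.integer(seed), fn())
}
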