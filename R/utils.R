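#' @importFrom rlang abort warn inform .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats kmeans lm.fit pnorm qlogis plogis rnorm runif rbinom rpois
#'   rlnorm sd var cor coef quantile setNames
NULL

#' Derive a reproducible sub-seed from a master seed
#'
#' Stream-splitting helper: every internal source of randomness draws its own
#' seed as a deterministic function of the user-supplied master seed and an
#' integer offset (a counter), so stages can be re-run independently without
#' sharing RNG state. Results stay below 2^31 so they are valid R seeds.
#'
#' @param seed Master seed (single integer-valued number).
#' @param offset Non-negative integer counter distinguishing the consumer.
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(42, 1)
derive_seed <- function(seed, offset = 0) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(offset))
  m <- 2147483629
  a <- ((as.double(seed) %% m) * 48271) %% m
  b <- (as.double(offset) * 16807) %% m
  as.integer((a + b) %% m) + 1L
}

# error function (no extra dependency needed)
erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

`%||%` <- function(a, b) if (is.null(a)) b else a

# run expr with a locally-set seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s].", name, lower, upper))
  }
  invisible(x)
}

#' Canonical diffusion metric names
#'
#' Column names used throughout the package for lesion feature tables:
#' DTI metrics (`fa`, `md`, `rd`, `ad`), single micro-tensor spherical-mean
#' metrics (`ufa`, `umd`, `urd`, `uad`) and two-compartment metrics
#' (`f_in`, `lambda_diff`, `v_ad`, `v_md`). Diffusivities in feature tables
#' are expressed in 1e-3 mm^2/s; `fa`, `ufa` and `f_in` are unitless.
#'
#' @return Character vector of the 12 metric names.
#' @export
diffusion_metric_names <- function() {
  c("fa", "md", "rd", "ad", "ufa", "umd", "urd", "uad",
    "f_in", "lambda_diff", "v_ad", "v_md")
}
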