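#' @keywords internal
"_PACKAGE"

#' @useDynLib bgsem, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm rbinom runif rlnorm rcauchy rt qnorm quantile
#'   var sd cor glm.fit binomial plogis qlogis uniroot pchisq fft
#'   setNames median
#' @importFrom utils read.csv write.csv head
NULL

# logistic helpers ------------------------------------------------------------

inv_logit <- function(x) plogis(x)

#' Numerically stable log(1 + exp(x))
#' @noRd
log1pexp <- function(x) {
  out <- numeric(length(x))
  big <- x > 0
  out[big] <- x[big] + log1p(exp(-x[big]))
  out[!big] <- log1p(exp(x[!big]))
  out
}

#' Numerically stable log(sum(exp(x)))
#' @noRd
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

log_mean_exp <- function(x) log_sum_exp(x) - log(length(x))

# rounding --------------------------------------------------------------------

#' Round half away from zero
#'
#' Commercial ("half-up") rounding used for report tables, so that e.g.
#' 0.9044 prints as 0.90 and 0.565 as 0.57 (base R's `round()` rounds half
#' to even). A tiny epsilon absorbs binary representation error in values
#' that are exact at four decimals.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# seed streams ----------------------------------------------------------------

# Derive k reproducible 31-bit sub-seeds from one master seed without
# disturbing the caller's RNG state. Used so each random source (controls,
# exposure, each mediator, outcome, weights, missingness, each chain) has
# its own stream and adding a variable does not perturb earlier ones.
derive_seeds <- function(seed, n, salt = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(as.integer(seed %% .Machine$integer.max) + as.integer(salt))
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

with_seed <- function(seed, code) {
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(as.integer(seed))
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a
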