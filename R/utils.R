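#' @importFrom rlang abort warn inform %||% hash
#' @importFrom tibble tibble as_tibble
#' @importFrom stats fft dgamma rnorm runif sd cor pnorm plnorm optim
#' @importFrom utils head tail
NULL

# Derive k reproducible child seeds (< 2^31) from one master seed.
derive_seeds <- function(master_seed, k, salt = 0L) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((as.integer(master_seed) + 97L * as.integer(salt)) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, k)
}

# Evaluate an expression with a locally-set RNG seed, restoring global state.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}

ms_to_s <- function(x) x / 1000
s_to_ms <- function(x) round(x * 1000)
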