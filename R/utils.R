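#' @importFrom stats rpois runif setNames optim pchisq quantile rnbinom rbinom sd
#' @importFrom utils head tail
NULL

# run code under a fixed seed without disturbing the caller's RNG;
# seed = NULL leaves the RNG stream alone
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# deterministic child seeds for replicate simulations
spawn_seeds <- function(seed, n) {
  with_seed_if(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_if_not_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    stop(sprintf("`%s` must be a single finite number >= %g", name, min),
         call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mutation_types <- c("hetA", "hetB", "hetAB", "fixed")
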