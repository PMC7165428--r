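## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom stats plogis qlogis rnorm rbinom rpois runif rbeta dbinom
#'   dpois qnorm pnorm var sd cor quantile setNames aggregate
#' @importFrom utils read.csv write.csv read.delim write.table modifyList
NULL

## set RNG state reproducibly; no-op when seed is NULL
set_seed_if <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

## derive a stream of sub-seeds (< 2^31) from one master seed
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  set.seed(as.integer(seed))
  as.list(sample.int(.Machine$integer.max - 1L, n))
}

check_prob <- function(x, name = deparse(substitute(x))) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("'%s' must contain probabilities in [0, 1]", name),
         call. = FALSE)
  invisible(x)
}

check_count <- function(x, name = deparse(substitute(x)), min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  as.integer(x)
}

## log(a + b) from log a, log b without underflow
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Bernoulli log pmf that treats 0 * log(0) as 0 elementwise on matrices
bern_loglik <- function(y, p) {
  ll <- y * log(p) + (1 - y) * log1p(-p)
  ll[y == 1 & p == 1] <- 0
  ll[y == 0 & p == 0] <- 0
  ll
}
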