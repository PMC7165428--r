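#' Gelman-Rubin potential scale reduction factor
#'
#' The classic between/within-chain variance ratio for one scalar
#' parameter monitored across multiple chains: with m chains of length n,
#' `W` is the mean within-chain variance, `B/n` the variance of the chain
#' means, and
#' `R-hat = sqrt(((n - 1)/n * W + B/n) / W)`.
#' Values below 1.1 are conventionally taken as adequate convergence.
#'
#' @param chains List of numeric vectors (>= 2 chains, equal length >= 2),
#'   or a matrix with one column per chain.
#' @return The R-hat statistic; `NA` (with attribute `undefined = TRUE`)
#'   when every chain has zero within-chain variance, in which case the
#'   ratio is not defined.
#' @examples
#' gelman_rubin(list(c(0, 1), c(1, 2)))  # sqrt(0.75 / 0.5)
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)),
                                          function(j) chains[, j])
  m <- length(chains)
  if (m < 2) stop("need at least 2 chains", call. = FALSE)
  n <- unique(lengths(chains))
  if (length(n) != 1 || n < 2)
    stop("chains must have equal length >= 2", call. = FALSE)
  W <- mean(vapply(chains, var, numeric(1)))
  mns <- vapply(chains, mean, numeric(1))
  B_over_n <- var(mns)
  if (W == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Randomized quantile (Dunn-Smyth) residuals for Bernoulli responses
#'
#' For a discrete response the probability-integral transform is made
#' continuous by drawing `u ~ Uniform(F(y - 1), F(y))` under the fitted
#' distribution and returning `r = qnorm(u)`.  Under a correctly
#' specified model the residuals are standard normal, which is what makes
#' them usable for goodness-of-fit checks on binary occupancy and
#' detection data where raw residuals are uninformative.
#'
#' With `mode = "midpoint"` the uniform draw is replaced by the interval
#' midpoint, giving deterministic residuals for testing: for example
#' `y = 0, prob = 0.5` gives `u = 0.25`, `r = qnorm(0.25)`.
#'
#' @param y Binary observations (0/1).
#' @param prob Fitted probabilities `P(y = 1)` per observation.
#' @param mode `"randomized"` (default) or `"midpoint"`.
#' @param seed Optional seed for the randomized mode.
#' @return Numeric residual vector.  A fitted probability of exactly 0 or
#'   1 that contradicts the observation yields an infinite residual and a
#'   warning.
#' @export
dunn_smyth_residuals <- function(y, prob, mode = c("randomized", "midpoint"),
                                 seed = NULL) {
  mode <- match.arg(mode)
  if (any(!y %in% c(0, 1))) stop("y must be binary", call. = FALSE)
  check_prob(prob)
  if (length(prob) == 1L) prob <- rep(prob, length(y))
  stopifnot(length(prob) == length(y))
  set_seed_if(seed)
  ## Bernoulli cdf: F(-1..0) = [0, 1 - p], F(0..1) = [1 - p, 1]
  lo <- ifelse(y == 0, 0, 1 - prob)
  hi <- ifelse(y == 0, 1 - prob, 1)
  u <- if (mode == "midpoint") (lo + hi) / 2 else
    runif(length(y), lo, hi)
  r <- qnorm(u)
  if (any(!is.finite(r))) {
    warning("infinite residuals: fitted probability 0 or 1 contradicts ",
            "the observation", call. = FALSE)
  }
  r
}

#' Dunn-Smyth residuals for a fitted occupancy model
#'
#' Computes per-observation residuals against the fitted marginal
#' detection probability `P(y_ijk = 1) = psi_ik * p_ijk`, using
#' posterior-mean (plug-in) taxon parameters.  Intended as the standard
#' graphical goodness-of-fit check per taxon.
#'
#' @param fit An `msom_fit`.
#' @param mode,seed Passed to [dunn_smyth_residuals()].
#' @return Data.frame with columns `visit`, `replicate`, `taxon`, `y`,
#'   `fitted`, `residual`.
#' @export
residuals_msom <- function(fit, mode = c("randomized", "midpoint"),
                           seed = NULL) {
  mode <- match.arg(mode)
  fp <- fitted_probabilities(fit)
  data.frame(visit = fp$visit, replicate = fp$replicate, taxon = fp$taxon,
             y = fp$y, fitted = fp$prob,
             residual = dunn_smyth_residuals(fp$y, fp$prob, mode = mode,
                                             seed = seed))
}

## Plug-in fitted psi, p and marginal detection probability per sampled
## observation, from posterior means of taxon-level parameters.
fitted_probabilities <- function(fit) {
  data <- fit$data
  s <- summary_means(fit)
  K <- fit$n_data_taxa
  prep <- prepare_fit_data(data, K)
  lpsi <- s[paste0("lpsi[", seq_len(K), "]")]
  lp <- s[paste0("lp[", seq_len(K), "]")]
  e_occ <- matrix(lpsi, prep$n_v, K, byrow = TRUE)
  if (prep$Po) {
    b <- matrix(s[grep("^betalpsi\\[", names(s))], K, prep$Po)
    e_occ <- e_occ + prep$Xocc %*% t(b)
  }
  e_det <- matrix(lp, prep$n_s, K, byrow = TRUE)
  if (prep$Pd) {
    b <- matrix(s[grep("^betalp\\[", names(s))], K, prep$Pd)
    e_det <- e_det + prep$Wdet %*% t(b)
  }
  psi <- plogis(e_occ)[prep$slot_unit, , drop = FALSE]
  p <- plogis(e_det)
  rep_of_slot <- sequence(tabulate(prep$slot_unit, prep$n_v))
  list(visit = rep(prep$slot_unit, K),
       replicate = rep(rep_of_slot, K),
       taxon = rep(fit$taxa[seq_len(K)], each = prep$n_s),
       y = as.vector(prep$Y[, seq_len(K), drop = FALSE]),
       prob = as.vector(psi * p), psi = as.vector(psi), p = as.vector(p))
}

summary_means <- function(fit) {
  all_d <- do.call(rbind, fit$draws)
  colMeans(all_d)
}
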