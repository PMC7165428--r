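#' Marginal log-likelihood of one taxon's replicate history at one site
#'
#' The occupancy-model likelihood for a single site visit and taxon with
#' the latent presence state summed out:
#' `psi * prod_j p_j^y_j (1 - p_j)^(1 - y_j) + (1 - psi) * I(all y = 0)`.
#' This is the exact enumeration over the two latent states and serves as
#' the reference kernel for the MCMC updates.
#'
#' @param y_vec Binary detection history across replicate samples.
#' @param psi Occupancy probability.
#' @param p_vec Per-replicate detection probabilities (same length as
#'   `y_vec`).
#' @return The log marginal probability of `y_vec`.
#' @examples
#' marginal_loglik_site_taxon(c(0, 0), 0.5, c(0.5, 0.5))  # log(0.625)
#' @export
marginal_loglik_site_taxon <- function(y_vec, psi, p_vec) {
  if (length(y_vec) < 1L)
    stop("empty replicate vector", call. = FALSE)
  if (length(y_vec) != length(p_vec))
    stop("y_vec and p_vec lengths differ", call. = FALSE)
  check_prob(psi); check_prob(p_vec)
  if (any(!y_vec %in% c(0, 1)))
    stop("y_vec must be binary", call. = FALSE)
  ll_det <- sum(bern_loglik(y_vec, p_vec))
  if (any(y_vec == 1)) {
    log(psi) + ll_det
  } else {
    log(psi * exp(ll_det) + (1 - psi))
  }
}

#' Draw the latent occupancy state from its full conditional
#'
#' Given a detection history, occupancy `psi` and detection probabilities,
#' returns a Bernoulli draw of `z`.  Any detection forces `z = 1`; for an
#' all-zero history the conditional probability is
#' `psi * q / (psi * q + 1 - psi)` with `q = prod_j (1 - p_j)`.
#'
#' @inheritParams marginal_loglik_site_taxon
#' @param prob_only If `TRUE`, return the conditional probability instead
#'   of a draw.
#' @return 0/1 draw (or a probability when `prob_only = TRUE`).
#' @export
update_z <- function(y_vec, psi, p_vec, prob_only = FALSE) {
  if (length(y_vec) < 1L) stop("empty replicate vector", call. = FALSE)
  check_prob(psi); check_prob(p_vec)
  pr <- if (any(y_vec == 1)) 1 else {
    q <- prod(1 - p_vec)
    if (psi == 0) 0 else psi * q / (psi * q + 1 - psi)
  }
  if (prob_only) return(pr)
  rbinom(1L, 1L, pr)
}

#' Full-conditional membership probability for a never-detected taxon
#'
#' Under data augmentation each taxon carries a membership indicator
#' `w_k ~ Bernoulli(Omega)`.  A taxon with at least one detection has
#' `w = 1` with probability 1; for a taxon never detected anywhere the
#' conditional mixes `Omega` against the probability of total
#' nondetection across all surveyed sites:
#' `P(w = 1 | y = 0) = Omega * L / (Omega * L + 1 - Omega)` where
#' `L = prod_i [psi_i * prod_j (1 - p_ij) + 1 - psi_i]`.
#'
#' @param psi Vector of occupancy probabilities per site visit.
#' @param log_q Vector of log nondetection probabilities per site visit
#'   (`sum_j log(1 - p_ij)` over that visit's replicates).
#' @param omega Inclusion probability.
#' @return The conditional probability `P(w = 1)`.
#' @export
membership_prob_undetected <- function(psi, log_q, omega) {
  check_prob(psi); check_prob(omega)
  logL <- sum(log(psi * exp(log_q) + (1 - psi)))
  a <- log(omega) + logL
  if (omega == 0) return(0)
  if (omega == 1) return(1)
  1 / (1 + exp(log(1 - omega) - a))
}

#' Conjugate update of the augmentation inclusion probability
#'
#' With a `Beta(a, b)` prior, `Omega | w ~ Beta(a + sum(w), b + M - sum(w))`.
#'
#' @param w Binary membership indicators over all M superpopulation taxa.
#' @param a,b Beta prior parameters.
#' @param draw If `FALSE`, return the posterior Beta parameters instead of
#'   a draw.
#' @return A draw of Omega (or `c(a, b)` posterior parameters).
#' @export
update_omega <- function(w, a = 1, b = 1, draw = TRUE) {
  stopifnot(all(w %in% c(0, 1)))
  post <- c(a + sum(w), b + length(w) - sum(w))
  if (!draw) return(post)
  rbeta(1L, post[1], post[2])
}
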