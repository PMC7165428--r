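#' Community hyperparameters for taxon-level occupancy and detection
#'
#' In a multispecies occupancy model every taxon has its own logit-scale
#' occupancy intercept (`lpsi`), occupancy slopes (`betalpsi`), detection
#' intercept (`lp`) and detection slopes (`betalp`), but these are tied
#' together as random effects drawn from community-level normal
#' distributions.  This constructor bundles the community means and
#' standard deviations of those distributions.
#'
#' @param mu_lpsi,sigma_lpsi Mean and SD of taxon occupancy intercepts
#'   (logit scale).
#' @param mu_betalpsi,sigma_betalpsi Mean(s) and SD(s) of taxon occupancy
#'   slopes; scalars are recycled to `n_occ_covariates`.
#' @param mu_lp,sigma_lp Mean and SD of taxon detection intercepts (logit
#'   scale).
#' @param mu_betalp,sigma_betalp Mean(s) and SD(s) of taxon detection
#'   slopes.
#' @return An object of class `community_hyperparams`.
#' @examples
#' community_hyperparams(mu_lpsi = -0.5, sigma_lpsi = 1,
#'                       mu_lp = 0, sigma_lp = 1)
#' @export
community_hyperparams <- function(mu_lpsi = 0, sigma_lpsi = 1,
                                  mu_betalpsi = numeric(),
                                  sigma_betalpsi = numeric(),
                                  mu_lp = 0, sigma_lp = 1,
                                  mu_betalp = numeric(),
                                  sigma_betalp = numeric()) {
  h <- list(mu_lpsi = mu_lpsi, sigma_lpsi = sigma_lpsi,
            mu_betalpsi = mu_betalpsi, sigma_betalpsi = sigma_betalpsi,
            mu_lp = mu_lp, sigma_lp = sigma_lp,
            mu_betalp = mu_betalp, sigma_betalp = sigma_betalp)
  for (nm in grep("^sigma", names(h), value = TRUE)) {
    if (any(h[[nm]] < 0))
      stop(sprintf("'%s' must be >= 0", nm), call. = FALSE)
  }
  structure(h, class = "community_hyperparams")
}

## recycle slope hyperparameters to the covariate count, with checks
expand_hyper <- function(mu, sigma, n, what) {
  if (n == 0L) return(list(mu = numeric(), sigma = numeric()))
  if (length(mu) == 0L) mu <- 0
  if (length(sigma) == 0L) sigma <- 1
  if (length(mu) == 1L) mu <- rep(mu, n)
  if (length(sigma) == 1L) sigma <- rep(sigma, n)
  if (length(mu) != n || length(sigma) != n)
    stop(sprintf("%s hyperparameter length must be 1 or %d", what, n),
         call. = FALSE)
  list(mu = mu, sigma = sigma)
}

#' Draw taxon-level parameters from community distributions
#'
#' Draws independent per-taxon logit-scale intercepts and slopes from the
#' community normal distributions: `lpsi_k ~ Normal(mu_lpsi, sigma_lpsi^2)`,
#' `lp_k ~ Normal(mu_lp, sigma_lp^2)`, and analogous draws for every
#' occupancy and detection slope.  A zero community SD is allowed and
#' collapses all taxa onto the community mean.
#'
#' @param hyperparams A [community_hyperparams()] object (or plain list
#'   with the same fields).
#' @param n_taxa Number of taxa to draw.
#' @param n_occ_covariates Number of occupancy slopes per taxon.
#' @param n_det_covariates Number of detection slopes per taxon (including
#'   any primer contrast columns).
#' @param seed Optional integer seed; identical seeds give identical draws.
#' @return An object of class `community_params`: list with vector `lpsi`,
#'   `lp` (length `n_taxa`), matrices `betalpsi`
#'   (`n_taxa x n_occ_covariates`) and `betalp`
#'   (`n_taxa x n_det_covariates`), and the `hyper` list used.
#' @export
draw_community_params <- function(hyperparams, n_taxa,
                                  n_occ_covariates = 0L,
                                  n_det_covariates = 0L,
                                  seed = NULL) {
  if (!inherits(hyperparams, "community_hyperparams"))
    hyperparams <- do.call(community_hyperparams, hyperparams)
  n_taxa <- check_count(n_taxa)
  n_occ <- check_count(n_occ_covariates, min = 0L)
  n_det <- check_count(n_det_covariates, min = 0L)
  ho <- expand_hyper(hyperparams$mu_betalpsi, hyperparams$sigma_betalpsi,
                     n_occ, "occupancy slope")
  hd <- expand_hyper(hyperparams$mu_betalp, hyperparams$sigma_betalp,
                     n_det, "detection slope")
  set_seed_if(seed)
  draw_mat <- function(mu, sigma, n) {
    if (length(mu) == 0L)
      return(matrix(numeric(), nrow = n, ncol = 0L))
    m <- vapply(seq_along(mu),
                function(p) rnorm(n, mu[p], sigma[p]),
                numeric(n))
    matrix(m, nrow = n)
  }
  out <- list(
    lpsi = rnorm(n_taxa, hyperparams$mu_lpsi, hyperparams$sigma_lpsi),
    betalpsi = draw_mat(ho$mu, ho$sigma, n_taxa),
    lp = rnorm(n_taxa, hyperparams$mu_lp, hyperparams$sigma_lp),
    betalp = draw_mat(hd$mu, hd$sigma, n_taxa),
    hyper = c(hyperparams[c("mu_lpsi", "sigma_lpsi", "mu_lp", "sigma_lp")],
              list(mu_betalpsi = ho$mu, sigma_betalpsi = ho$sigma,
                   mu_betalp = hd$mu, sigma_betalp = hd$sigma))
  )
  structure(out, class = "community_params")
}

#' @export
print.community_params <- function(x, ...) {
  cat("Community parameters for", length(x$lpsi), "taxa:",
      ncol(x$betalpsi), "occupancy slope(s),",
      ncol(x$betalp), "detection slope(s)\n")
  cat(sprintf("  lpsi: mean %.3f sd %.3f | lp: mean %.3f sd %.3f\n",
              mean(x$lpsi), stats::sd(x$lpsi),
              mean(x$lp), stats::sd(x$lp)))
  invisible(x)
}
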