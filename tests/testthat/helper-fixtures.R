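## Shared fixture builders; everything is generated in code.

## constant-probability presence-absence community, no covariates
make_flat_params <- function(n_taxa, psi, p) {
  structure(list(
    lpsi = rep(qlogis(psi), n_taxa),
    betalpsi = matrix(numeric(), n_taxa, 0),
    lp = rep(qlogis(p), n_taxa),
    betalp = matrix(numeric(), n_taxa, 0),
    hyper = list()), class = "community_params")
}

make_count_params <- function(n_taxa, lambda, p) {
  structure(list(
    lpsi = rep(log(lambda), n_taxa),
    betalpsi = matrix(numeric(), n_taxa, 0),
    lp = rep(qlogis(p), n_taxa),
    betalp = matrix(numeric(), n_taxa, 0),
    hyper = list()), class = "community_params")
}

## hand-built tiny dataset: y[visit, replicate, taxon]
tiny_dataset <- function(y, mode = "presence_absence") {
  n_v <- dim(y)[1]
  visits <- data.frame(site_id = paste0("s", seq_len(n_v)),
                       year = 1L,
                       visit_id = paste0("v", seq_len(n_v)),
                       stringsAsFactors = FALSE)
  detection_dataset(y, visits, mode = mode)
}

## independent grid oracle for the 1-taxon occupancy posterior:
## p(lpsi, lp | y) on a grid, priors Normal(mu0, sd0) on both logits.
## Likelihood is written out directly (enumeration over z per site) so it
## shares no code with the sampler.
grid_oracle_psi_p <- function(y, mu0 = 0, sd0 = 1.5, n_grid = 201) {
  lpsi_g <- seq(-6, 6, length.out = n_grid)
  lp_g <- seq(-6, 6, length.out = n_grid)
  loglik <- matrix(0, n_grid, n_grid)
  for (a in seq_len(n_grid)) {
    psi <- plogis(lpsi_g[a])
    for (b in seq_len(n_grid)) {
      p <- plogis(lp_g[b])
      ll <- 0
      for (i in seq_len(nrow(y))) {
        yi <- y[i, ]
        det_part <- prod(p^yi * (1 - p)^(1 - yi))
        ll <- ll + if (any(yi == 1)) log(psi * det_part)
        else log(psi * det_part + (1 - psi))
      }
      loglik[a, b] <- ll
    }
  }
  lp_prior <- dnorm(lpsi_g, mu0, sd0, log = TRUE)
  post <- exp(loglik + outer(lp_prior, dnorm(lp_g, mu0, sd0, log = TRUE),
                             `+`))
  post <- post / sum(post)
  list(lpsi = lpsi_g, lp = lp_g, post = post,
       marg_psi = rowSums(post), marg_p = colSums(post))
}

## total variation distance between a sample and grid marginal, binned on
## the probability scale
tv_sample_vs_grid <- function(draws_prob, grid_logit, grid_marg,
                              breaks = seq(0, 1, by = 0.05)) {
  gp <- plogis(grid_logit)
  bin_grid <- vapply(seq_len(length(breaks) - 1), function(b) {
    sum(grid_marg[gp > breaks[b] & gp <= breaks[b + 1]])
  }, numeric(1))
  bin_grid[1] <- bin_grid[1] + sum(grid_marg[gp <= breaks[1]])
  h <- hist(draws_prob, breaks = breaks, plot = FALSE)
  bin_mcmc <- h$counts / length(draws_prob)
  0.5 * sum(abs(bin_grid - bin_mcmc))
}

## binomial 99% CI half-width check
within_binom_ci99 <- function(phat, p_true, n) {
  abs(phat - p_true) <= qnorm(0.995) * sqrt(p_true * (1 - p_true) / n) +
    1 / n
}
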