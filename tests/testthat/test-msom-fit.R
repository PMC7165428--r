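## Short-chain fits: these checks target correctness of the conditional
## structure, not posterior precision.

test_that("saturated data drive psi and p toward 1 for every taxon", {
  y <- array(1L, dim = c(8, 2, 3))
  d <- tiny_dataset(y)
  fit <- fit_msom(d, mcmc_control(n_chains = 1, n_iter = 1200,
                                  n_burnin = 400, thin = 2, M = 3),
                  seed = 1)
  s <- summary(fit)
  lpsi <- s$mean[grep("^lpsi\\[", s$parameter)]
  lp <- s$mean[grep("^lp\\[", s$parameter)]
  expect_true(all(plogis(lpsi) > 0.95))
  expect_true(all(plogis(lp) > 0.95))
})

test_that("latent states are consistent in every retained draw", {
  pars <- make_flat_params(6, 0.5, 0.4)
  d <- simulate_dataset(pars, survey_design(n_sites = 15,
                                            replicates_per_visit = 2,
                                            n_taxa_true = 6), seed = 2)
  fit <- fit_msom(d, mcmc_control(n_chains = 1, n_iter = 800,
                                  n_burnin = 300, thin = 2,
                                  store_z = TRUE), seed = 3)
  obs <- observed_matrix(d)
  gamma <- posterior_draws(fit, "gamma")
  ## gamma never below observed richness
  expect_true(all(gamma >= observed_richness(d)))
  ## z = 1 wherever a detection occurred, in every draw
  zd <- fit$z_draws[[1]]
  for (i in seq_len(dim(zd)[1])) {
    z <- zd[i, , seq_len(6)]
    expect_true(all(z[obs == 1] == 1))
  }
  ## corrected alpha never below observed alpha
  cm <- corrected_matrices(fit)
  expect_true(all(t(cm$alpha) >= rowSums(obs)))
})

test_that("tiny-instance posterior mean matches the quadrature oracle", {
  ## 2 visits x 2 replicates x 1 taxon, hyperparameters fixed so the
  ## taxon-level prior is known exactly
  y <- array(c(1, 0, 0, 0), dim = c(2, 2, 1))
  d <- tiny_dataset(y)
  pr <- prior_spec(fixed = list(mu_lpsi = 0, sigma_lpsi = 1.5,
                                mu_lp = 0, sigma_lp = 1.5))
  fit <- fit_msom(d, mcmc_control(n_chains = 1, n_iter = 10000,
                                  n_burnin = 2000, thin = 1, M = 1),
                  prior = pr, seed = 4)
  oracle <- grid_oracle_psi_p(y[, , 1], mu0 = 0, sd0 = 1.5)
  psi_mcmc <- mean(plogis(posterior_draws(fit, "lpsi[1]")))
  psi_grid <- sum(plogis(oracle$lpsi) * oracle$marg_psi)
  expect_lt(abs(psi_mcmc - psi_grid), 0.03)
  p_mcmc <- mean(plogis(posterior_draws(fit, "lp[1]")))
  p_grid <- sum(plogis(oracle$lp) * oracle$marg_p)
  expect_lt(abs(p_mcmc - p_grid), 0.03)
})

test_that("a zero covariate is likelihood-free: prior recovered through the sampler", {
  ## covariate column identically zero: its slopes never touch the
  ## likelihood, so their posterior must reproduce the (fixed) prior
  pars <- make_flat_params(5, 0.6, 0.5)
  d <- simulate_dataset(pars, survey_design(n_sites = 12,
                                            replicates_per_visit = 2,
                                            n_taxa_true = 5), seed = 5)
  d$occ_covariates <- matrix(0, nrow(d$visits), 1)
  pr <- prior_spec(fixed = list(mu_betalpsi = 0.4, sigma_betalpsi = 0.8))
  fit <- fit_msom(d, mcmc_control(n_chains = 1, n_iter = 3000,
                                  n_burnin = 500, thin = 1, M = 5),
                  prior = pr, seed = 6)
  b <- unlist(lapply(1:5, function(k)
    posterior_draws(fit, sprintf("betalpsi[%d,1]", k))))
  expect_lt(abs(mean(b) - 0.4), 3 * 0.8 / sqrt(200))  # generous MC error
  expect_lt(abs(sd(b) - 0.8), 0.15)
})

test_that("augmentation bookkeeping and input validation hold", {
  y <- array(c(1, 0), dim = c(2, 1, 1))
  d <- tiny_dataset(y)
  ## M below the number of data taxa is a configuration error
  expect_error(fit_msom(d, mcmc_control(M = 0, n_iter = 100,
                                        n_burnin = 10)), "smaller")
  ## count data rejected
  dc <- tiny_dataset(array(c(2, 0), dim = c(2, 1, 1)), mode = "count")
  expect_error(fit_msom(dc), "presence-absence")
  ## no augmentation: gamma is exactly observed richness in every draw
  fit <- fit_msom(d, mcmc_control(n_chains = 1, n_iter = 400,
                                  n_burnin = 100, M = 1), seed = 7)
  expect_true(all(posterior_draws(fit, "gamma") == 1))
  ## determinism under a fixed seed
  f1 <- fit_msom(d, mcmc_control(n_chains = 2, n_iter = 300,
                                 n_burnin = 100, M = 2), seed = 11)
  f2 <- fit_msom(d, mcmc_control(n_chains = 2, n_iter = 300,
                                 n_burnin = 100, M = 2), seed = 11)
  expect_identical(f1$draws, f2$draws)
})

test_that("adaptive proposals land acceptance rates in the target band", {
  pars <- make_flat_params(8, 0.5, 0.5)
  d <- simulate_dataset(pars, survey_design(n_sites = 25,
                                            replicates_per_visit = 3,
                                            n_taxa_true = 8), seed = 8)
  fit <- fit_msom(d, mcmc_control(n_chains = 1, n_iter = 2000,
                                  n_burnin = 1000, M = 8), seed = 9)
  acc <- fit$accept[[1]]
  expect_gt(acc[["lpsi"]], 0.15)
  expect_lt(acc[["lpsi"]], 0.6)
  expect_gt(acc[["lp"]], 0.15)
  expect_lt(acc[["lp"]], 0.6)
})
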