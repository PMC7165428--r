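test_that("latent-abundance full conditional is exact", {
  ## perfect detection pins N at the observed count
  expect_identical(update_N(2, lambda = 3, p_vec = 1), 2L)
  pm <- update_N(2, lambda = 3, p_vec = 1, prob_only = TRUE)
  expect_equal(pm$prob[pm$n == 2], 1)

  ## single all-zero replicate: surplus is Poisson(lambda * (1 - p))
  pm0 <- update_N(0, lambda = 1, p_vec = 0.5, prob_only = TRUE)
  expect_equal(pm0$prob[pm0$n == 0], exp(-0.5), tolerance = 1e-9)
  expect_equal(pm0$prob[pm0$n == 2], dpois(2, 0.5), tolerance = 1e-9)

  ## multi-replicate case against brute-force enumeration over N=3..60
  n_grid <- 3:60
  w <- dpois(n_grid, 4) * dbinom(3, n_grid, 0.5) * dbinom(1, n_grid, 0.5)
  brute <- w / sum(w)
  pm2 <- update_N(c(3, 1), lambda = 4, p_vec = c(0.5, 0.5),
                  prob_only = TRUE)
  common <- intersect(pm2$n, n_grid)
  tv <- 0.5 * (sum(abs(pm2$prob[match(common, pm2$n)] -
                         brute[match(common, n_grid)])) +
                 sum(brute[!n_grid %in% common]) +
                 sum(pm2$prob[!pm2$n %in% common]))
  expect_lt(tv, 1e-8)

  ## guard rails
  expect_error(update_N(0, lambda = 0, p_vec = 0.5), "lambda")
  expect_error(update_N(0, lambda = 1e6, p_vec = 0.5, n_cap = 50), "cap")
  expect_error(update_N(-1, lambda = 1, p_vec = 0.5), "nonnegative")
})

test_that("truncating abundance at 1 recovers the occupancy likelihood", {
  ## one site, binary y: N-mixture with N <= 1 and psi = P(N=1 | N<=1)
  ## gives the same marginal data probability as the occupancy model
  lambda <- 0.8; p <- c(0.6, 0.3)
  psi <- dpois(1, lambda) / (dpois(0, lambda) + dpois(1, lambda))
  for (y in list(c(0, 0), c(1, 0), c(1, 1))) {
    occ_ll <- marginal_loglik_site_taxon(y, psi, p)
    pn <- dpois(0:1, lambda) / sum(dpois(0:1, lambda))
    nmix <- pn[1] * all(y == 0) +
      pn[2] * prod(dbinom(y, 1, p))
    expect_equal(occ_ll, log(nmix))
  }
})

test_that("community N-mixture fit recovers abundance structure", {
  hp <- community_hyperparams(mu_lpsi = 0, sigma_lpsi = 1,
                              mu_lp = qlogis(0.6), sigma_lp = 0.3)
  des <- survey_design(n_sites = 30, replicates_per_visit = 3,
                       n_taxa_true = 25)
  pars <- draw_community_params(hp, 25, seed = 80)
  d <- simulate_count_dataset(pars, des, seed = 81)
  fit <- fit_nmixture(d, mcmc_control(n_chains = 1, n_iter = 1500,
                                      n_burnin = 600, thin = 2, M = 25),
                      seed = 82)
  s <- summary(fit)
  hrow <- function(p) s[s$parameter == p, ]
  ## 95% CIs cover the realized community draws (what a single community
  ## of 25 taxa can inform)
  m_re <- mean(pars$lpsi); s_re <- sd(pars$lpsi); mp_re <- mean(pars$lp)
  expect_gt(hrow("mu_lpsi")$upper, m_re)
  expect_lt(hrow("mu_lpsi")$lower, m_re)
  expect_gt(hrow("sigma_lpsi")$upper, s_re)
  expect_lt(hrow("sigma_lpsi")$lower, s_re)
  expect_gt(hrow("mu_lp")$upper, mp_re)
  expect_lt(hrow("mu_lp")$lower, mp_re)
  ## latent N never fell below the observed maximum count
  maxy <- apply(d$y, c(1, 3), max)
  expect_true(all(fit$N_min >= maxy))
  ## posterior-mean N at least the observed maximum too
  expect_true(all(fit$N_mean >= maxy - 1e-9))
})

test_that("a truly absent augmented taxon is down-weighted", {
  ## all-zero counts for one taxon with one well-detected taxon present:
  ## the absent taxon's membership falls below the Omega prior mean
  y <- array(0L, dim = c(12, 2, 2))
  set.seed(83)
  y[, , 1] <- rpois(24, 2)
  d <- tiny_dataset(y, mode = "count")
  fit <- fit_nmixture(d, mcmc_control(n_chains = 1, n_iter = 1500,
                                      n_burnin = 500, thin = 2, M = 2),
                      seed = 84)
  gamma <- posterior_draws(fit, "gamma")
  expect_lt(mean(gamma == 2), 0.5)  # w_2 posterior below its 0.5 prior
  expect_true(all(gamma >= 1))
})

test_that("expected richness under random individual sampling is exact", {
  expect_equal(expected_richness_under_count_model(c(0.5, 0.5), 1), 1)
  expect_equal(expected_richness_under_count_model(c(0.9, 0.1), 2), 1.18)
  ## monotone nondecreasing in n, bounded by the taxon count
  lam <- c(5, 1, 0.2, 0.2)
  vals <- vapply(c(1, 2, 5, 20, 200, 2000), function(n)
    expected_richness_under_count_model(lam, n), numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_true(all(vals <= 4))
  expect_equal(vals[length(vals)], 4, tolerance = 0.01)
  expect_error(expected_richness_under_count_model(c(0, 0), 5), "zero")
})
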