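test_that("community parameter draws follow the stated normal laws", {
  ## degenerate variance collapses every taxon onto the community mean
  hp <- community_hyperparams(mu_lpsi = 0.5, sigma_lpsi = 0)
  pars <- draw_community_params(hp, 20, seed = 1)
  expect_equal(pars$lpsi, rep(0.5, 20))

  ## CLT bound on the sample mean at n = 10000
  hp2 <- community_hyperparams(mu_lp = 0, sigma_lp = 1)
  pars2 <- draw_community_params(hp2, 10000, seed = 2)
  expect_lt(abs(mean(pars2$lp)), 4 / sqrt(10000))

  ## bit-identical under an identical seed
  a <- draw_community_params(hp2, 50, 2, 3, seed = 99)
  b <- draw_community_params(hp2, 50, 2, 3, seed = 99)
  expect_identical(a, b)

  ## negative community SD is rejected
  expect_error(community_hyperparams(sigma_lpsi = -1), "sigma")
})

test_that("simulated detections obey the occupancy-detection hierarchy", {
  ## saturated probabilities give all-ones data
  pars <- make_flat_params(4, psi = plogis(30), p = plogis(30))
  des <- survey_design(n_sites = 5, replicates_per_visit = 3,
                       n_taxa_true = 4)
  d <- simulate_dataset(pars, des, seed = 1)
  expect_true(all(d$y == 1))

  ## empirical site occupancy near psi = 0.6 at 5000 sites
  des2 <- survey_design(n_sites = 5000, replicates_per_visit = 1,
                        n_taxa_true = 1)
  d2 <- simulate_dataset(make_flat_params(1, 0.6, plogis(30)), des2,
                         seed = 2)
  expect_true(within_binom_ci99(mean(attr(d2, "z")), 0.6, 5000))

  ## P(>=1 detection) = 1 - (1-p)^3 when psi = 1
  des3 <- survey_design(n_sites = 5000, replicates_per_visit = 3,
                        n_taxa_true = 1)
  d3 <- simulate_dataset(make_flat_params(1, plogis(30), 0.3), des3,
                         seed = 3)
  frac <- mean(apply(d3$y[, , 1], 1, max))
  expect_true(within_binom_ci99(frac, 1 - 0.7^3, 5000))

  ## no detection without presence, ever
  d4 <- simulate_dataset(make_flat_params(3, 0.5, 0.5),
                         survey_design(n_sites = 200,
                                       replicates_per_visit = 2,
                                       n_taxa_true = 3), seed = 4)
  z4 <- attr(d4, "z")
  for (j in 1:2) expect_true(all(d4$y[, j, ] <= z4))

  ## detection frequency among occupied visits converges to p
  occ <- z4[, 1] == 1
  phat <- mean(d4$y[occ, , 1])
  expect_true(within_binom_ci99(phat, 0.5, sum(occ) * 2))

  ## identical seed, identical dataset
  e1 <- simulate_dataset(make_flat_params(3, 0.5, 0.5),
                         survey_design(n_sites = 10,
                                       n_taxa_true = 3), seed = 7)
  e2 <- simulate_dataset(make_flat_params(3, 0.5, 0.5),
                         survey_design(n_sites = 10,
                                       n_taxa_true = 3), seed = 7)
  expect_identical(e1$y, e2$y)
})

test_that("occupancy covariate effects are recoverable by regression", {
  hp <- community_hyperparams(mu_lpsi = 0, sigma_lpsi = 0,
                              mu_betalpsi = 1.2, sigma_betalpsi = 0)
  des <- survey_design(n_sites = 3000, replicates_per_visit = 1,
                       n_taxa_true = 1, n_occ_covariates = 1)
  pars <- draw_community_params(hp, 1, n_occ_covariates = 1, seed = 5)
  d <- simulate_dataset(pars, des, seed = 6)
  z <- attr(d, "z")[, 1]
  g <- glm(z ~ d$occ_covariates[, 1], family = binomial())
  est <- coef(summary(g))[2, ]
  expect_lt(abs(est["Estimate"] - 1.2), 3 * est["Std. Error"])
})

test_that("count data follow the Poisson-binomial thinning process", {
  des <- survey_design(n_sites = 4000, replicates_per_visit = 1,
                       n_taxa_true = 1)
  ## p = 1 reveals N exactly
  d1 <- simulate_count_dataset(make_count_params(1, 2, plogis(30)), des,
                               seed = 1)
  expect_identical(as.integer(d1$y[, 1, 1]), as.integer(attr(d1, "N")))

  ## thinned mean lambda * p
  d2 <- simulate_count_dataset(make_count_params(1, 2, 0.5), des,
                               seed = 2)
  expect_lt(abs(mean(d2$y[, 1, 1]) - 1),
            qnorm(0.995) * sqrt(1 / 4000) * 2)

  ## P(y = 0) = exp(-lambda * p)
  d3 <- simulate_count_dataset(make_count_params(1, 0.5, 0.5), des,
                               seed = 3)
  expect_true(within_binom_ci99(mean(d3$y[, 1, 1] == 0), exp(-0.25),
                                4000))

  ## y never exceeds N
  expect_true(all(d2$y[, 1, 1] <= attr(d2, "N")))
})

test_that("missing replicates are masked, not zero-filled", {
  d <- simulate_dataset(make_flat_params(2, 0.7, 0.6),
                        survey_design(n_sites = 200,
                                      replicates_per_visit = 3,
                                      n_taxa_true = 2),
                        seed = 8, missingness = 0.4)
  expect_gt(sum(is.na(d$y[, 2, 1])), 0)
  expect_false(anyNA(d$y[, 1, ]))  # first replicate always sampled
  ## a masked slice is masked for every taxon
  na1 <- is.na(d$y[, 2, 1]); na2 <- is.na(d$y[, 2, 2])
  expect_identical(na1, na2)
})

test_that("primer levels enter the detection design as contrasts", {
  des <- delta_wetland_design(n_taxa_true = 12)
  hp <- community_hyperparams()
  pars <- draw_community_params(hp, 12, des$n_occ_covariates,
                                des$n_det_total, seed = 1)
  d <- simulate_dataset(pars, des, seed = 2)
  expect_equal(dim(d$det_covariates)[3], des$n_det_total)
  expect_true(all(d$det_covariates[, , 3] %in% c(0, 1)))  # primer contrast
  expect_setequal(unique(as.vector(d$primer)), c("primer1", "primer2"))
  ## dimension mismatch is caught
  bad <- draw_community_params(hp, 12, 0, 0, seed = 1)
  expect_error(simulate_dataset(bad, des), "dimension")
})
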