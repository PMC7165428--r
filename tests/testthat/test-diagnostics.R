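test_that("Gelman-Rubin statistic matches the hand-worked formula", {
  ## W = 0.5, B/n = var(c(0.5, 1.5)) = 0.5, n = 2
  expect_equal(gelman_rubin(list(c(0, 1), c(1, 2))),
               sqrt(0.75 / 0.5))
  ## identical chains: B = 0, R-hat = sqrt((n-1)/n)
  expect_equal(gelman_rubin(list(1:4, 1:4)), sqrt(3 / 4))
  ## constant equal chains: undefined, flagged
  r <- gelman_rubin(list(rep(2, 5), rep(2, 5)))
  expect_true(is.na(r))
  expect_true(attr(r, "undefined"))
  expect_error(gelman_rubin(list(1:3)), "2 chains")
  expect_error(gelman_rubin(list(1:3, 1:4)), "equal length")
})

test_that("fit summary flags non-converged parameters by R-hat >= 1.1", {
  fit <- structure(list(draws = list(
    cbind(a = rnorm(100), b = 1:100),
    cbind(a = rnorm(100), b = 101:200))), class = "msom_fit")
  s <- summary(fit)
  expect_true(s$converged[s$parameter == "a"])
  expect_false(s$converged[s$parameter == "b"])
})

test_that("midpoint Dunn-Smyth residuals are exact quantile transforms", {
  expect_equal(dunn_smyth_residuals(0, 0.5, mode = "midpoint"),
               qnorm(0.25))
  expect_equal(dunn_smyth_residuals(1, 0.5, mode = "midpoint"),
               qnorm(0.75))
  ## symmetry at p = 0.5
  expect_equal(dunn_smyth_residuals(1, 0.5, mode = "midpoint"),
               -dunn_smyth_residuals(0, 0.5, mode = "midpoint"))
  ## contradictory certain fit yields infinite residual with a warning
  expect_warning(r <- dunn_smyth_residuals(c(1, 0), c(0, 0.5),
                                           mode = "midpoint"),
                 "infinite")
  expect_true(is.infinite(r[1]))
})

test_that("randomized residuals are standard normal under the true model", {
  ## probability-integral-transform property, no fitting involved
  set.seed(1)
  pass <- 0
  for (s in 1:20) {
    p <- runif(600, 0.05, 0.95)
    y <- rbinom(600, 1, p)
    r <- dunn_smyth_residuals(y, p, seed = 1000 + s)
    if (stats::ks.test(r, "pnorm")$p.value > 0.01) pass <- pass + 1
  }
  expect_gte(pass, 18)
})

test_that("model residuals from a fit carry fitted marginal probabilities", {
  pars <- make_flat_params(4, 0.6, 0.5)
  d <- simulate_dataset(pars, survey_design(n_sites = 12,
                                            replicates_per_visit = 2,
                                            n_taxa_true = 4), seed = 10)
  fit <- fit_msom(d, mcmc_control(n_chains = 1, n_iter = 600,
                                  n_burnin = 200, M = 4), seed = 11)
  rr <- residuals_msom(fit, mode = "midpoint")
  expect_equal(nrow(rr), 12 * 2 * 4)
  expect_true(all(rr$fitted >= 0 & rr$fitted <= 1))
  expect_true(all(is.finite(rr$residual)))
  ## marginal fitted probability is psi * p, strictly below either factor
  expect_true(all(rr$fitted < 1))
})
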