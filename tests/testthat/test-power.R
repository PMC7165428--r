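test_that("curveball trades preserve margins exactly", {
  set.seed(1)
  m <- matrix(rbinom(20 * 50, 1, 0.3), 20, 50)
  mp <- permute_fixed_margins(m, 1e4, seed = 2)
  expect_identical(rowSums(mp), rowSums(m))
  expect_identical(colSums(mp), colSums(m))
  ## zero trades: identity
  expect_identical(permute_fixed_margins(m, 0), m)
  ## 2x2 checkerboard: result stays inside the two-matrix margin class
  cb <- rbind(c(1, 0), c(0, 1))
  for (s in 1:20) {
    r <- permute_fixed_margins(cb, 3, seed = s)
    expect_true(identical(r, cb) || identical(r, rbind(c(0, 1), c(1, 0))))
  }
})

test_that("curveball sampling agrees with vegan's curveball null model", {
  ## margin class of this matrix has exactly 3 states, each with the
  ## top-left cell occupied in 2 of them: uniform sampling gives 2/3
  cb <- rbind(c(1, 0, 1), c(0, 1, 0))
  ours <- mean(vapply(1:400, function(s)
    permute_fixed_margins(cb, 10, seed = s)[1, 1], numeric(1)))
  nm <- vegan::nullmodel(cb, "curveball")
  sim <- simulate(nm, nsim = 400, thin = 10, seed = 1)
  theirs <- mean(sim[1, 1, ])
  expect_lt(abs(ours - 2 / 3), 0.08)
  expect_lt(abs(ours - theirs), 0.12)
})

test_that("baseline construction follows the occupancy distribution", {
  b1 <- build_baseline(rep(1, 5), gamma = 5, n_sites = 4, seed = 1)
  expect_true(all(b1$matrices[[1]] == 1))
  b2 <- build_baseline(0.3, gamma = 3, n_sites = 5000, seed = 2)
  cm <- colMeans(b2$matrices[[1]])
  expect_true(all(abs(cm - 0.3) <=
                    qnorm(0.995) * sqrt(0.3 * 0.7 / 5000) + 1 / 5000))
  expect_identical(build_baseline(0.4, 10, 20, seed = 3)$matrices[[1]],
                   build_baseline(0.4, 10, 20, seed = 3)$matrices[[1]])
})

test_that("turnover calibration finds the trade count for a target", {
  set.seed(3)
  b <- build_baseline(0.3, gamma = 100, n_sites = 20, seed = 4)
  expect_equal(calibrate_turnover(b, 0)$n_swaps, 0L)
  cal <- calibrate_turnover(b, 0.4, n_rep = 3, seed = 5)
  expect_lt(abs(cal$achieved - 0.4), 0.25)
  ## achieved turnover grows with trade count on average
  path <- cal$path
  expect_gt(cor(path$n_swaps, path$turnover, method = "spearman"), 0)
  ## an impossible target warns and returns the closest achievable
  expect_warning(calibrate_turnover(b, 0.999, n_rep = 2, seed = 6),
                 "unattainable")
})

test_that("tolerances covary with occupancy at the requested rank correlation", {
  psi <- plogis(rnorm(360, -1, 1.2))
  t1 <- make_tolerances(psi, 1, seed = 1)
  expect_identical(rank(t1$tolerance), rank(psi))
  tm1 <- make_tolerances(psi, -1, seed = 2)
  expect_identical(rank(tm1$tolerance), length(psi) + 1 - rank(psi))
  t0 <- make_tolerances(psi, 0, seed = 3)
  expect_lt(abs(cor(t0$tolerance, psi, method = "spearman")), 0.15)
  t5 <- make_tolerances(psi, 0.5, seed = 4)
  expect_lt(abs(cor(t5$tolerance, psi, method = "spearman") - 0.5), 0.15)
  expect_error(make_tolerances(psi, 1.5), "rho")
})

test_that("stressor removes an exact occurrence count weighted by intolerance", {
  set.seed(5)
  m <- matrix(rbinom(20 * 25, 1, 0.4), 20, 25)
  tol <- runif(25)
  expect_identical(apply_stressor(m, tol, 0), m)
  for (sv in c(0.2, 0.5, 1)) {
    ms <- apply_stressor(m, tol, sv, seed = 6)
    expect_equal(sum(ms), sum(m) - round(sv * sum(m)))
    expect_true(all(ms <= m))
  }
  ## a fully tolerant taxon is untouched while intolerant occurrences last
  tol2 <- c(1, rep(0, 24))
  ms2 <- apply_stressor(m, tol2, 0.3, seed = 7)
  expect_identical(ms2[, 1], m[, 1])
  ## removals shift toward intolerant taxa
  tol3 <- make_tolerances(colMeans(m), 0, seed = 8)$tolerance
  ms3 <- apply_stressor(m, tol3, 0.4, seed = 9)
  lost <- colSums(m) - colSums(ms3)
  expect_lt(cor(lost / pmax(colSums(m), 1), tol3, method = "spearman"), 0)
  expect_error(apply_stressor(m, tol, 1.2), "severity")
})

test_that("detection sampling is Bernoulli thinning of the truth", {
  truth <- matrix(rbinom(5000 * 2, 1, 0.5), 5000, 2)
  expect_identical(sample_detection(truth, 1, 2, seed = 1,
                                    collapse = TRUE), truth)
  expect_true(all(sample_detection(truth, 0, 3, seed = 2,
                                   collapse = TRUE) == 0))
  det <- sample_detection(truth, 0.5, 3, seed = 3, collapse = TRUE)
  occ <- truth[, 1] == 1
  expect_true(within_binom_ci99(mean(det[occ, 1]), 1 - 0.5^3, sum(occ)))
  ## full dataset form carries replicate structure
  ds <- sample_detection(truth[1:10, ], 0.7, 3, seed = 4)
  expect_s3_class(ds, "detection_dataset")
  expect_equal(dim(ds$y), c(10, 3, 2))
  for (j in 1:3) expect_true(all(ds$y[, j, ] <= truth[1:10, ]))
})

test_that("summed-LR community test matches hand calculation and is calibrated", {
  ## hand example: taxon at 2/2 sites in A, 0/2 in B
  A <- matrix(c(1, 1), 2, 1); B <- matrix(c(0, 0), 2, 1)
  r <- suppressMessages(manyglm_test(A, B, n_resamples = 99, seed = 1))
  expect_equal(r$statistic, 2 * (0 - 4 * log(0.5)), tolerance = 1e-10)
  ## identical groups: zero statistic, p = 1
  set.seed(2)
  m <- matrix(rbinom(40, 1, 0.5), 4, 10)
  r2 <- suppressMessages(manyglm_test(m, m, n_resamples = 49, seed = 3))
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 1)
  ## invariant taxa are dropped with a notice
  m2 <- cbind(m, 1)
  expect_message(manyglm_test(m2, m2, n_resamples = 9), "invariant")
  ## small groups rejected
  expect_error(manyglm_test(m[1, , drop = FALSE], m), "at least 2")
})

test_that("power workflow detects severe impacts and respects the null", {
  psi <- plogis(rnorm(60, -1, 1))
  tax <- make_taxonomy(60, 20, seed = 1)
  grid <- data.frame(n_sites = 8, replicates = 3,
                     approach = "DNA_genus")
  res <- power_curve(psi, grid, severities = c(0, 0.9), taxonomy = tax,
                     n_sim = 20, n_resamples = 99, seed = 2)
  pw <- res$power
  expect_equal(nrow(pw), 2)
  expect_true(all(pw$power >= 0 & pw$power <= 1))
  ## near-total removal is essentially always detected
  expect_gt(pw$power[pw$severity == 0.9], 0.9)
  ## no impact: rare detections only
  expect_lt(pw$power[pw$severity == 0], 0.35)
  ## minimum detectable severity interpolates the 0.5 crossing
  expect_true(res$minimum_detectable$min_detectable > 0 &&
                res$minimum_detectable$min_detectable <= 0.9)
})

test_that("power-curve crossing interpolation is linear", {
  expect_equal(msompower:::min_detectable_severity(c(0, 0.2, 0.4), c(0.1, 0.3, 0.7)),
               0.2 + 0.2 * (0.5 - 0.3) / (0.7 - 0.3))
  expect_true(is.na(msompower:::min_detectable_severity(c(0, 0.5), c(0.1, 0.4))))
  expect_equal(msompower:::min_detectable_severity(c(0, 0.5), c(0.6, 0.9)), 0)
})
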