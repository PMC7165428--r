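test_that("observed matrix collapses replicates by any-detection", {
  y <- array(NA_real_, dim = c(3, 3, 2))
  y[1, , 1] <- c(0, 0, 1); y[1, , 2] <- c(0, 0, 0)
  y[2, , 1] <- c(0, NA, NA); y[2, , 2] <- c(1, NA, NA)
  y[3, , 1] <- NA; y[3, , 2] <- NA  # fully masked visit
  visits <- data.frame(site_id = c("a", "b", "c"), year = 1,
                       visit_id = c("a1", "b1", "c1"))
  d <- detection_dataset(y, visits)
  m <- observed_matrix(d)
  expect_equal(nrow(m), 2)  # masked visit dropped
  expect_equal(unname(m["a1", ]), c(1, 0))
  expect_equal(unname(m["b1", ]), c(0, 1))
})

test_that("pairwise dissimilarity matches hand-computed Jaccard/Sorensen", {
  m <- rbind(A = c(1, 1, 1, 0), B = c(0, 1, 1, 1))
  colnames(m) <- paste0("t", 1:4)
  dj <- pairwise_dissimilarity(m, "jaccard")
  expect_equal(dj["A", "B"], 1 - 2 / 4)      # shared 2 of union 4
  ds <- pairwise_dissimilarity(m, "sorensen")
  expect_equal(ds["A", "B"], 1 - 2 * 2 / 6)  # 1 - 2a/(2a+b+c)
  ## identical and disjoint rows
  m2 <- rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1))
  d2 <- pairwise_dissimilarity(m2)
  expect_equal(d2[1, 2], 0)
  expect_equal(d2[1, 3], 1)
  expect_true(isSymmetric(d2))
  expect_true(all(diag(d2) == 0))
  ## jaccard dominates sorensen pairwise; double zeros carry nothing
  set.seed(1)
  m3 <- matrix(rbinom(60, 1, 0.4), 6, 10)
  m3[, 1] <- 0  # taxon absent everywhere must not increase similarity
  dj3 <- pairwise_dissimilarity(m3, "jaccard")
  ds3 <- pairwise_dissimilarity(m3, "sorensen")
  expect_true(all(dj3 >= ds3 - 1e-12))
  expect_equal(pairwise_dissimilarity(m3[, -1], "jaccard"), dj3)
  ## empty site flagged, maximally dissimilar
  m4 <- rbind(c(0, 0), c(1, 0), c(0, 0))
  expect_warning(d4 <- pairwise_dissimilarity(m4), "zero taxa")
  expect_equal(d4[1, 2], 1)
  expect_equal(d4[1, 3], 0)  # two empty sites agree
})

test_that("taxonomic aggregation is an OR and behaves monotonically", {
  tax <- data.frame(taxon_id = c("g1", "g2", "g3"),
                    genus = c("g1", "g2", "g3"),
                    family = c("f1", "f1", "f2"))
  m <- rbind(s1 = c(1, 0, 0), s2 = c(0, 1, 0), s3 = c(0, 0, 1))
  colnames(m) <- tax$taxon_id
  fam <- aggregate_taxa(m, tax, "family")
  ## two genera at disjoint sites: family present at the union
  expect_equal(unname(fam[, "f1"]), c(1, 1, 0))
  expect_equal(unname(fam[, "f2"]), c(0, 0, 1))
  ## family prevalence >= each member genus prevalence
  for (g in tax$taxon_id)
    expect_true(all(fam[, tax$family[tax$taxon_id == g]] >= m[, g]))
  ## idempotent: aggregating the family matrix changes nothing
  tax2 <- data.frame(taxon_id = c("f1", "f2"), genus = c("f1", "f2"),
                     family = c("f1", "f2"))
  expect_equal(unname(aggregate_taxa(fam, tax2, "family")), unname(fam))
  ## unmapped taxon is an error
  colnames(m)[1] <- "mystery"
  expect_error(aggregate_taxa(m, tax, "family"), "not found")
})

test_that("aggregation of a count dataset sums member counts", {
  y <- array(c(2, 1, 3, 0), dim = c(1, 2, 2),
             dimnames = list(NULL, NULL, c("g1", "g2")))
  tax <- data.frame(taxon_id = c("g1", "g2"), genus = c("g1", "g2"),
                    family = c("f1", "f1"))
  d <- detection_dataset(y, data.frame(site_id = "s", year = 1,
                                       visit_id = "v"),
                         taxonomy = tax, mode = "count")
  agg <- aggregate_taxa(d, rank = "family")
  expect_equal(as.vector(agg$y[1, , "f1"]), c(2 + 3, 1 + 0))
})

test_that("resolution contrast reports both percent and point scales", {
  ## 1 genus per family: zero contrast
  m <- rbind(c(1, 0), c(0, 1)); colnames(m) <- c("g1", "g2")
  tax <- data.frame(taxon_id = c("g1", "g2"), genus = c("g1", "g2"),
                    family = c("f1", "f2"))
  fam <- aggregate_taxa(m, tax, "family")
  rc <- resolution_dissimilarity_contrast(m, fam)
  expect_equal(rc$percent, 0)
  expect_equal(rc$points, 0)
  ## 2 genera of one family arranged so genus Jaccard = 1, family = 0
  m2 <- rbind(c(1, 0), c(0, 1)); colnames(m2) <- c("g1", "g2")
  tax2 <- data.frame(taxon_id = c("g1", "g2"), genus = c("g1", "g2"),
                     family = c("f1", "f1"))
  fam2 <- aggregate_taxa(m2, tax2, "family")
  rc2 <- resolution_dissimilarity_contrast(m2, fam2)
  expect_equal(rc2$points, 100)
  ## synthetic community: genus-level dissimilarity >= family-level
  set.seed(42)
  tax3 <- make_taxonomy(60, 20, seed = 1)
  m3 <- matrix(rbinom(15 * 60, 1, 0.3), 15, 60)
  colnames(m3) <- tax3$taxon_id
  fam3 <- aggregate_taxa(m3, tax3, "family")
  rc3 <- resolution_dissimilarity_contrast(m3, fam3)
  expect_gte(rc3$points, 0)
})

test_that("percent increase uses integer rounding", {
  expect_equal(percent_increase(95, 74), 28)
  expect_equal(percent_increase(130, 109), 19)
  expect_equal(percent_increase(360, 263), 37)
  expect_equal(percent_increase(100, 100), 0)
  expect_error(percent_increase(10, 0), "> 0")
})
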