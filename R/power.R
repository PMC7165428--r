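#' Build a baseline metacommunity presence-absence matrix
#'
#' Draws a hypothetical site x taxon presence-absence matrix from a
#' distribution of taxon occupancy probabilities, the starting point of
#' the monitoring power analysis.  The occupancy source can be a numeric
#' vector of per-taxon probabilities, a `list(mu, sigma)` logit-normal
#' community distribution, or a fitted `msom_fit` (a posterior draw of
#' the community hyperparameters is used).
#'
#' @param occupancy_source Per-taxon occupancy probabilities, a
#'   `list(mu, sigma)`, or an `msom_fit`.
#' @param gamma Number of taxa (columns).
#' @param n_sites Number of sites (rows).
#' @param seed Optional seed.
#' @return A `metacommunity_sim`: list with `matrices` (list of year
#'   matrices, initially one), `psi`, `gamma`, `n_sites`.
#' @export
build_baseline <- function(occupancy_source, gamma, n_sites, seed = NULL) {
  gamma <- check_count(gamma)
  n_sites <- check_count(n_sites)
  set_seed_if(seed)
  psi <- occupancy_psi(occupancy_source, gamma)
  m <- matrix(rbinom(n_sites * gamma, 1L, rep(psi, each = n_sites)),
              n_sites, gamma)
  colnames(m) <- paste0("t", seq_len(gamma))
  structure(list(matrices = list(m), psi = psi, gamma = gamma,
                 n_sites = n_sites),
            class = "metacommunity_sim")
}

occupancy_psi <- function(src, gamma) {
  if (inherits(src, "msom_fit")) {
    mu <- posterior_draws(src, "mu_lpsi")
    sg <- posterior_draws(src, "sigma_lpsi")
    i <- sample.int(length(mu), 1L)
    return(plogis(rnorm(gamma, mu[i], sg[i])))
  }
  if (is.list(src)) return(plogis(rnorm(gamma, src$mu, src$sigma)))
  check_prob(src)
  rep_len(src, gamma)
}

#' Fixed-margin permutation of a binary matrix (curveball trades)
#'
#' Performs `n_swaps` curveball trades: each trade picks two random rows
#' and reshuffles the taxa unique to either row between them, which
#' preserves every row and column sum exactly while randomizing
#' co-occurrence structure.  This is the standard null model for "random
#' assembly" community turnover: taxon occupancy (row sums over sites
#' would be the transpose convention; here, per-site richness) and taxon
#' totals are held constant.
#'
#' @param m Binary matrix.
#' @param n_swaps Number of trades attempted; 0 returns `m` unchanged.
#' @param seed Optional seed.
#' @return A binary matrix with identical row and column sums.
#' @export
permute_fixed_margins <- function(m, n_swaps, seed = NULL) {
  if (any(!m %in% c(0, 1))) stop("matrix must be binary", call. = FALSE)
  n_swaps <- check_count(n_swaps, min = 0L)
  set_seed_if(seed)
  n_r <- nrow(m)
  if (n_r < 2 || n_swaps == 0) return(m)
  for (t in seq_len(n_swaps)) {
    rr <- sample.int(n_r, 2L)
    r1 <- m[rr[1], ]; r2 <- m[rr[2], ]
    d1 <- which(r1 == 1 & r2 == 0)
    d2 <- which(r1 == 0 & r2 == 1)
    n1 <- length(d1); n2 <- length(d2)
    if (n1 == 0 || n2 == 0) next
    pool <- c(d1, d2)
    take <- sample(pool, n1)
    r1[pool] <- 0; r1[take] <- 1
    r2[pool] <- 0; r2[setdiff(pool, take)] <- 1
    m[rr[1], ] <- r1; m[rr[2], ] <- r2
  }
  m
}

## mean within-site Jaccard turnover between two year matrices
site_turnover <- function(m1, m2) {
  a <- rowSums(m1 & m2)
  u <- rowSums(m1 | m2)
  mean(ifelse(u == 0, 0, 1 - a / u))
}

#' Calibrate trade count to a target year-to-year turnover
#'
#' Searches the number of curveball trades whose mean within-site
#' Jaccard turnover (between the baseline matrix and its permutation)
#' best matches a target.  Replicating strong observed turnover typically
#' requires complete redistribution of occurrences within the
#' fixed-margin class; if even that cannot reach the target, the closest
#' achievable trade count is returned with a warning.
#'
#' @param sim A `metacommunity_sim` (its first year matrix is used) or a
#'   binary matrix.
#' @param target_dissimilarity Target mean within-site turnover in (0, 1);
#'   0 returns 0 swaps.
#' @param n_rep Permutation replicates averaged per candidate.
#' @param seed Optional seed.
#' @return List with `n_swaps`, `achieved`, and the search `path`.
#' @export
calibrate_turnover <- function(sim, target_dissimilarity, n_rep = 5,
                               seed = NULL) {
  m <- if (inherits(sim, "metacommunity_sim")) sim$matrices[[1]] else sim
  if (target_dissimilarity < 0 || target_dissimilarity >= 1)
    stop("target must be in [0, 1)", call. = FALSE)
  if (target_dissimilarity == 0)
    return(list(n_swaps = 0L, achieved = 0, path = NULL))
  set_seed_if(seed)
  total <- sum(m)
  cand <- unique(pmax(1L, round(total * c(0.005, 0.01, 0.02, 0.05, 0.1,
                                          0.25, 0.5, 1, 2, 5))))
  ach <- vapply(cand, function(ns) {
    mean(vapply(seq_len(n_rep), function(r)
      site_turnover(m, permute_fixed_margins(m, ns)), numeric(1)))
  }, numeric(1))
  best <- which.min(abs(ach - target_dissimilarity))
  if (max(ach) < target_dissimilarity - 0.02)
    warning(sprintf(
      "target turnover %.2f unattainable within the margin class; best %.2f",
      target_dissimilarity, max(ach)), call. = FALSE)
  list(n_swaps = cand[best], achieved = ach[best],
       path = data.frame(n_swaps = cand, turnover = ach))
}

#' Generate taxon tolerances that covary with occupancy
#'
#' Draws per-taxon tolerance scores in \[0, 1\] via a Gaussian copula so
#' their Spearman rank correlation with the occupancy probabilities is
#' approximately `rho`.  `rho = 1` reproduces the occupancy rank order
#' exactly, `rho = -1` reverses it; positive `rho` means prevalent taxa
#' are also tolerant, the regime where stressor impacts are hardest to
#' see.
#'
#' @param occupancy Per-taxon occupancy probabilities.
#' @param rho Target Spearman correlation in `[-1, 1]`.
#' @param seed Optional seed.
#' @return A `tolerance_profile`: list with `tolerance` and `rho`.
#' @export
make_tolerances <- function(occupancy, rho, seed = NULL) {
  if (rho < -1 || rho > 1) stop("rho must be in [-1, 1]", call. = FALSE)
  set_seed_if(seed)
  n <- length(occupancy)
  z1 <- qnorm(rank(occupancy, ties.method = "random") / (n + 1))
  rho_p <- 2 * sin(pi * rho / 6)  # Spearman -> Pearson on normal scores
  z2 <- rho_p * z1 + sqrt(1 - rho_p^2) * rnorm(n)
  structure(list(tolerance = pnorm(z2), rho = rho),
            class = "tolerance_profile")
}

#' Remove a fraction of occurrences according to taxon tolerances
#'
#' Simulates a generalized stressor by deleting
#' `round(severity * total occurrences)` presences, allocating removals
#' across taxa with probability proportional to `1 - tolerance_k`; fully
#' tolerant taxa (`tolerance = 1`) lose occurrences only after every
#' intolerant occurrence is exhausted.  Severity is thus the reduction in
#' community occupancy.
#'
#' @param sim A binary matrix or `metacommunity_sim` (all year matrices
#'   are stressed).
#' @param tolerances A `tolerance_profile` or numeric vector in `[0, 1]`
#'   per taxon.
#' @param severity Fraction of all occurrences removed, in `[0, 1]`.
#' @param seed Optional seed.
#' @return Same type as `sim`.
#' @export
apply_stressor <- function(sim, tolerances, severity, seed = NULL) {
  if (severity < 0 || severity > 1)
    stop("severity must be in [0, 1]", call. = FALSE)
  tol <- if (inherits(tolerances, "tolerance_profile"))
    tolerances$tolerance else tolerances
  check_prob(tol)
  set_seed_if(seed)
  stress_one <- function(m) {
    occ <- which(m == 1)
    n_rm <- round(severity * length(occ))
    if (n_rm == 0) return(m)
    wts <- (1 - tol)[col(m)[occ]]
    pos <- occ[wts > 0]
    if (length(pos) >= n_rm) {
      rm_idx <- if (length(pos) == 1L) pos else
        sample(pos, n_rm, prob = wts[wts > 0])
    } else {
      extra <- occ[wts == 0]
      rm_idx <- c(pos, if (length(extra) == 1L) extra else
        sample(extra, n_rm - length(pos)))
    }
    m[rm_idx] <- 0L
    m
  }
  if (inherits(sim, "metacommunity_sim")) {
    sim$matrices <- lapply(sim$matrices, stress_one)
    sim
  } else stress_one(sim)
}

#' Sample imperfect detections from a metacommunity truth matrix
#'
#' Applies sampling error: each replicate sample detects a present taxon
#' independently with its detection probability,
#' `y_ijk ~ Bernoulli(presence_ik * p_k)`.
#'
#' @param truth Binary site x taxon matrix (or `metacommunity_sim`, first
#'   year).
#' @param detection_probs Per-taxon detection probability (recycled).
#' @param replicates Number of replicate samples per site.
#' @param seed Optional seed.
#' @param collapse If `TRUE`, return the site x taxon any-detection
#'   matrix instead of a `detection_dataset`.
#' @return A `detection_dataset` (presence-absence) or a binary matrix.
#' @export
sample_detection <- function(truth, detection_probs, replicates = 1L,
                             seed = NULL, collapse = FALSE) {
  if (inherits(truth, "metacommunity_sim")) truth <- truth$matrices[[1]]
  check_prob(detection_probs)
  replicates <- check_count(replicates)
  set_seed_if(seed)
  n_s <- nrow(truth); n_k <- ncol(truth)
  p <- rep_len(detection_probs, n_k)
  if (collapse) {
    pr <- truth * matrix(1 - (1 - p)^replicates, n_s, n_k, byrow = TRUE)
    out <- matrix(rbinom(n_s * n_k, 1L, pr), n_s, n_k)
    colnames(out) <- colnames(truth)
    return(out)
  }
  y <- array(0L, dim = c(n_s, replicates, n_k),
             dimnames = list(NULL, NULL,
                             colnames(truth) %||% paste0("t", seq_len(n_k))))
  for (j in seq_len(replicates)) {
    pr <- truth * matrix(p, n_s, n_k, byrow = TRUE)
    y[, j, ] <- matrix(rbinom(n_s * n_k, 1L, pr), n_s, n_k)
  }
  visits <- data.frame(site_id = paste0("s", seq_len(n_s)),
                       year = 1L,
                       visit_id = paste0("s", seq_len(n_s), "_y1"),
                       stringsAsFactors = FALSE)
  detection_dataset(y, visits, mode = "presence_absence")
}

#' Community-level composition test by summed likelihood-ratio resampling
#'
#' A multivariate-abundance style test for a composition shift between
#' two groups of sites: each taxon gets a binomial GLM likelihood-ratio
#' statistic for the group effect (intercept-only vs group model), the
#' statistics are summed across taxa into one community statistic, and
#' significance comes from permuting site group labels.  Taxa invariant
#' across all sites carry no information and are dropped with a notice.
#'
#' @param baseline_data,impacted_data Binary site x taxon matrices with
#'   identical columns (replicates already collapsed to site level).
#' @param n_resamples Number of label permutations.
#' @param seed Optional seed.
#' @return List with `statistic`, `p_value`
#'   (`(1 + #permuted >= observed) / (1 + n_resamples)`), `per_taxon`
#'   LR statistics, and `n_dropped`.
#' @export
manyglm_test <- function(baseline_data, impacted_data, n_resamples = 499L,
                         seed = NULL) {
  stopifnot(ncol(baseline_data) == ncol(impacted_data))
  nA <- nrow(baseline_data); nB <- nrow(impacted_data)
  if (nA < 2 || nB < 2)
    stop("each group needs at least 2 sites", call. = FALSE)
  set_seed_if(seed)
  X <- rbind(as.matrix(baseline_data), as.matrix(impacted_data))
  if (any(!X %in% c(0, 1))) stop("matrices must be binary", call. = FALSE)
  n <- nA + nB
  s <- colSums(X)
  keep <- s > 0 & s < n
  n_dropped <- sum(!keep)
  if (n_dropped)
    message(n_dropped, " taxa invariant across all sites dropped")
  X <- X[, keep, drop = FALSE]
  s <- s[keep]
  if (!ncol(X))
    return(list(statistic = 0, p_value = 1,
                per_taxon = numeric(0), n_dropped = n_dropped))
  ## binomial log-likelihood at the MLE proportion, vectorized
  ll <- function(succ, size) {
    p <- succ / size
    out <- succ * log(p) + (size - succ) * log1p(-p)
    out[succ == 0 | succ == size] <- 0
    out
  }
  lr_stat <- function(sA) {
    sB <- sweep(-sA, 2, s, `+`)  # s - sA, rowwise
    2 * (ll(sA, nA) + ll(sB, nB) -
           matrix(ll(s, n), nrow(sA), ncol(sA), byrow = TRUE))
  }
  sA_obs <- matrix(colSums(X[seq_len(nA), , drop = FALSE]), 1)
  per_taxon <- drop(lr_stat(sA_obs))
  obs <- sum(per_taxon)
  ## permutation null: each row of Pm selects nA sites for group A
  Pm <- matrix(0L, n_resamples, n)
  for (b in seq_len(n_resamples))
    Pm[b, sample.int(n, nA)] <- 1L
  sA_perm <- Pm %*% X
  stat_perm <- rowSums(lr_stat(sA_perm))
  p <- (1 + sum(stat_perm >= obs - 1e-12)) / (1 + n_resamples)
  list(statistic = obs, p_value = p,
       per_taxon = setNames(per_taxon, colnames(X)),
       n_dropped = n_dropped)
}

#' Detectability presets for the monitoring power comparison
#'
#' Logit-normal community distributions of per-taxon detectability, one
#' per sampling approach.  The morphology-based protocol has markedly
#' lower detectability than metabarcoding at the same (family) rank, and
#' genus-level taxa are somewhat harder to detect than their parent
#' families; the exact values are configuration, chosen to reproduce that
#' ordering.
#'
#' @param approach One of `"CABIN_family"`, `"DNA_family"`, `"DNA_genus"`.
#' @return List with `rank`, `mu`, `sigma` (logit scale).
#' @export
detection_preset <- function(approach = c("CABIN_family", "DNA_family",
                                          "DNA_genus")) {
  approach <- match.arg(approach)
  switch(approach,
         CABIN_family = list(rank = "family", mu = -1.5, sigma = 1),
         DNA_family = list(rank = "family", mu = 0.8, sigma = 1),
         DNA_genus = list(rank = "genus", mu = 0.2, sigma = 1))
}

#' Power of a monitoring design to detect a community-occupancy decline
#'
#' For every design point (sites per year, replicates per visit, sampling
#' approach) and stressor severity, simulates baseline years and
#' post-impact years of a turnover-rich metacommunity, samples imperfect
#' detections, and tests each post-impact year's composition against the
#' pooled baseline with [manyglm_test()].  A simulation counts as a
#' detection when at least one of the post-impact years rejects at level
#' `alpha` (a "detected within 2 years" rule; set `rule = "both"` to
#' require every year).  Power is the detection fraction over `n_sim`
#' simulations, and the minimum detectable severity is where the
#' power curve crosses 0.5 (linear interpolation).
#'
#' Year-to-year turnover is simulated as fixed-margin (curveball)
#' redistribution of occurrences, i.e. random assembly; the stressor
#' removes occurrences weighted by `1 - tolerance`.
#'
#' @param psi Genus-level per-taxon occupancy probabilities (the baseline
#'   metacommunity), or a source accepted by [build_baseline()].
#' @param design_grid Data.frame with columns `n_sites`, `replicates`,
#'   `approach` (names understood by [detection_preset()] or entries of
#'   `detection_sets`).
#' @param severities Sorted vector of severities in `[0, 1]`.
#' @param taxonomy Genus-to-family map (needed by family-rank
#'   approaches).
#' @param n_sim Simulations per design x severity cell.
#' @param alpha Test level.
#' @param n_resamples Permutations per test.
#' @param baseline_years,post_years Years simulated before and after
#'   impact.
#' @param rho_tolerance Spearman correlation between tolerance and
#'   occupancy.
#' @param detection_sets Optional named list overriding
#'   [detection_preset()] entries.
#' @param rule `"any"` or `"both"` post-impact years must reject.
#' @param seed Optional seed.
#' @return A `power_result`: list with the tidy `power` table, the
#'   `minimum_detectable` table, and settings.
#' @export
power_curve <- function(psi, design_grid, severities, taxonomy = NULL,
                        n_sim = 100L, alpha = 0.05, n_resamples = 499L,
                        baseline_years = 2L, post_years = 2L,
                        rho_tolerance = 0.5, detection_sets = NULL,
                        rule = c("any", "both"), seed = NULL) {
  rule <- match.arg(rule)
  stopifnot(nrow(design_grid) >= 1,
            all(c("n_sites", "replicates", "approach") %in%
                  names(design_grid)))
  if (is.unsorted(severities)) stop("severities must be sorted",
                                    call. = FALSE)
  set_seed_if(seed)
  gamma <- if (is.numeric(psi)) length(psi) else
    stop("psi must be a numeric occupancy vector", call. = FALSE)
  rows <- list()
  for (d in seq_len(nrow(design_grid))) {
    ap <- as.character(design_grid$approach[d])
    preset <- detection_sets[[ap]] %||% detection_preset(ap)
    for (sv in severities) {
      hits <- 0L
      for (sim_i in seq_len(n_sim)) {
        hits <- hits + run_one_power_sim(
          psi, design_grid$n_sites[d], design_grid$replicates[d],
          preset, sv, taxonomy, alpha, n_resamples,
          baseline_years, post_years, rho_tolerance, rule)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(approach = ap, n_sites = design_grid$n_sites[d],
                   replicates = design_grid$replicates[d],
                   severity = sv, power = hits / n_sim)
    }
  }
  pw <- do.call(rbind, rows)
  mds <- stats::aggregate(power ~ approach + n_sites + replicates,
                          data = pw, FUN = length)[, 1:3]
  mds$min_detectable <- NA_real_
  for (i in seq_len(nrow(mds))) {
    sub <- pw[pw$approach == mds$approach[i] &
                pw$n_sites == mds$n_sites[i] &
                pw$replicates == mds$replicates[i], ]
    sub <- sub[order(sub$severity), ]
    mds$min_detectable[i] <- min_detectable_severity(sub$severity,
                                                     sub$power)
  }
  structure(list(power = pw, minimum_detectable = mds,
                 settings = list(n_sim = n_sim, alpha = alpha,
                                 n_resamples = n_resamples,
                                 baseline_years = baseline_years,
                                 post_years = post_years,
                                 rho_tolerance = rho_tolerance,
                                 rule = rule)),
            class = "power_result")
}

## power-curve crossing of 0.5, linearly interpolated between grid points
min_detectable_severity <- function(sev, pow) {
  above <- which(pow > 0.5)
  if (!length(above)) return(NA_real_)
  i <- above[1]
  if (i == 1) return(sev[1])
  s0 <- sev[i - 1]; s1 <- sev[i]; p0 <- pow[i - 1]; p1 <- pow[i]
  if (p1 == p0) return(s1)
  s0 + (0.5 - p0) * (s1 - s0) / (p1 - p0)
}

## one simulation: returns 1 if the impact is detected under the rule
run_one_power_sim <- function(psi, n_sites, replicates, preset, severity,
                              taxonomy, alpha, n_resamples,
                              baseline_years, post_years, rho_tolerance,
                              rule) {
  gamma <- length(psi)
  base <- matrix(rbinom(n_sites * gamma, 1L, rep(psi, each = n_sites)),
                 n_sites, gamma)
  colnames(base) <- if (!is.null(taxonomy)) taxonomy$taxon_id[seq_len(gamma)]
    else paste0("t", seq_len(gamma))
  n_swaps <- 2L * max(sum(base), 1L)  # complete redistribution
  tol <- make_tolerances(psi, rho_tolerance)
  p_k <- plogis(rnorm(
    if (preset$rank == "genus") gamma else
      length(unique(taxonomy$family[seq_len(gamma)])),
    preset$mu, preset$sigma))
  observe <- function(truth) {
    if (preset$rank == "family")
      truth <- aggregate_taxa(truth, taxonomy, "family")
    sample_detection(truth, p_k, replicates, collapse = TRUE)
  }
  truth <- base
  base_obs <- vector("list", baseline_years)
  for (yindex in seq_len(baseline_years)) {
    truth <- permute_fixed_margins(truth, n_swaps)
    base_obs[[yindex]] <- observe(truth)
  }
  baseline_mat <- do.call(rbind, base_obs)
  rejections <- logical(post_years)
  for (yindex in seq_len(post_years)) {
    truth <- permute_fixed_margins(truth, n_swaps)
    impacted <- apply_stressor(truth, tol, severity)
    res <- suppressMessages(
      manyglm_test(baseline_mat, observe(impacted), n_resamples))
    rejections[yindex] <- res$p_value <= alpha
  }
  as.integer(if (rule == "any") any(rejections) else all(rejections))
}

#' @export
print.power_result <- function(x, ...) {
  cat("Monitoring power analysis (", x$settings$n_sim,
      " simulations/cell, alpha = ", x$settings$alpha, ")\n", sep = "")
  cat("Minimum detectable reduction in community occupancy ",
      "(power > 0.5):\n", sep = "")
  print(x$minimum_detectable, row.names = FALSE)
  invisible(x)
}
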