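#' Construct a replicated detection dataset
#'
#' The single input container for all model fitting: a ragged array of
#' detections (or counts) `y[i, j, k]` indexed by site visit `i`,
#' replicate sample `j` and taxon `k`, together with standardized
#' site-visit-level occupancy covariates, replicate-level detection
#' covariates, and a taxonomy map.  Missing replicates are `NA` (masked),
#' never zero-filled, so irregularly sampled designs are represented
#' faithfully.
#'
#' @param y Numeric array `n_visits x max_replicates x n_taxa`; `NA` marks
#'   a missing replicate (the whole `y[i, j, ]` slice must then be `NA`).
#' @param visits Data.frame describing each site visit: columns `site_id`,
#'   `year`, `visit_id`.
#' @param occ_covariates Numeric matrix `n_visits x P_occ` (may have 0
#'   columns).
#' @param det_covariates Numeric array `n_visits x max_replicates x P_det`
#'   (may have 0 slices), aligned with `y`'s first two dimensions.
#' @param taxonomy Data.frame with columns `taxon_id`, `genus`, `family`
#'   covering every taxon in `y`'s third dimension.
#' @param mode `"presence_absence"` (binary y) or `"count"` (nonnegative
#'   integer y).
#' @param primer Optional character/factor matrix `n_visits x
#'   max_replicates` recording the primer level of each replicate.
#' @return An object of class `detection_dataset`.
#' @export
detection_dataset <- function(y, visits, occ_covariates = NULL,
                              det_covariates = NULL, taxonomy = NULL,
                              mode = c("presence_absence", "count"),
                              primer = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.array(y), length(dim(y)) == 3L)
  n_visits <- dim(y)[1]; n_rep <- dim(y)[2]; n_taxa <- dim(y)[3]
  obs <- y[!is.na(y)]
  if (mode == "presence_absence") {
    if (any(!obs %in% c(0, 1)))
      stop("presence_absence mode requires y values in {0, 1}",
           call. = FALSE)
  } else {
    if (any(obs < 0) || any(obs != round(obs)))
      stop("count mode requires nonnegative integer y values",
           call. = FALSE)
  }
  if (is.null(occ_covariates))
    occ_covariates <- matrix(numeric(), n_visits, 0L)
  occ_covariates <- as.matrix(occ_covariates)
  stopifnot(nrow(occ_covariates) == n_visits)
  if (is.null(det_covariates))
    det_covariates <- array(numeric(), dim = c(n_visits, n_rep, 0L))
  stopifnot(length(dim(det_covariates)) == 3L,
            dim(det_covariates)[1] == n_visits,
            dim(det_covariates)[2] == n_rep)
  taxa <- dimnames(y)[[3]] %||% paste0("t", seq_len(n_taxa))
  if (is.null(taxonomy)) {
    taxonomy <- data.frame(taxon_id = taxa, genus = taxa,
                           family = taxa, stringsAsFactors = FALSE)
  }
  missing_tax <- setdiff(taxa, taxonomy$taxon_id)
  if (length(missing_tax))
    stop("taxa absent from taxonomy: ",
         paste(utils::head(missing_tax, 5), collapse = ", "), call. = FALSE)
  stopifnot(is.data.frame(visits), nrow(visits) == n_visits,
            all(c("site_id", "year", "visit_id") %in% names(visits)))
  structure(list(y = y, visits = visits,
                 occ_covariates = occ_covariates,
                 det_covariates = det_covariates,
                 taxonomy = taxonomy, mode = mode,
                 taxa = taxa, primer = primer),
            class = "detection_dataset")
}

#' @export
print.detection_dataset <- function(x, ...) {
  d <- dim(x$y)
  n_obs <- sum(!is.na(x$y[, , 1, drop = FALSE]))
  cat("Detection dataset (", x$mode, "): ", d[1], " site visits x ",
      d[2], " replicate slots x ", d[3], " taxa\n", sep = "")
  cat("  ", n_obs, " sampled visit-replicates; ",
      ncol(x$occ_covariates), " occupancy / ",
      dim(x$det_covariates)[3], " detection covariate(s)\n", sep = "")
  cat("  observed richness: ", observed_richness(x), " taxa detected\n",
      sep = "")
  invisible(x)
}

#' Number of taxa with at least one detection
#' @param data A `detection_dataset`.
#' @return Integer count of taxa ever detected.
#' @export
observed_richness <- function(data) {
  sum(apply(data$y, 3, function(m) any(m > 0, na.rm = TRUE)))
}

#' Specify covariate generating distributions for simulation
#'
#' Continuous covariates are simulated as Normal(mean, sd) and then used
#' directly by the model, so the defaults (mean 0, sd 1) generate
#' standardized covariates.  The primer covariate is categorical with the
#' given level probabilities and is expanded to treatment contrasts in the
#' detection design.
#'
#' @param occ_mean,occ_sd Mean/SD per occupancy covariate (recycled).
#' @param det_mean,det_sd Mean/SD per continuous detection covariate.
#' @param primer_probs Probabilities of each primer level (recycled to
#'   uniform when `NULL`).
#' @return A list of class `covariate_spec`.
#' @export
covariate_spec <- function(occ_mean = 0, occ_sd = 1,
                           det_mean = 0, det_sd = 1,
                           primer_probs = NULL) {
  structure(list(occ_mean = occ_mean, occ_sd = occ_sd,
                 det_mean = det_mean, det_sd = det_sd,
                 primer_probs = primer_probs),
            class = "covariate_spec")
}

## simulate covariates for a design; returns occ matrix, det array,
## primer factor matrix, and the detection design including contrasts
simulate_covariates <- function(design, spec) {
  n_v <- design$n_visits; n_r <- design$replicates_per_visit
  po <- design$n_occ_covariates; pd <- design$n_det_covariates
  occ_mean <- rep(spec$occ_mean, length.out = max(po, 1L))
  occ_sd <- rep(spec$occ_sd, length.out = max(po, 1L))
  det_mean <- rep(spec$det_mean, length.out = max(pd, 1L))
  det_sd <- rep(spec$det_sd, length.out = max(pd, 1L))
  occ <- matrix(0, n_v, po)
  if (po > 0L)
    for (p in seq_len(po)) occ[, p] <- rnorm(n_v, occ_mean[p], occ_sd[p])
  colnames(occ) <- if (po) paste0("occ_cov", seq_len(po)) else NULL
  det <- array(0, dim = c(n_v, n_r, design$n_det_total))
  if (pd > 0L)
    for (p in seq_len(pd))
      det[, , p] <- matrix(rnorm(n_v * n_r, det_mean[p], det_sd[p]), n_v)
  primer <- NULL
  if (design$primer_levels > 1L) {
    probs <- spec$primer_probs %||%
      rep(1 / design$primer_levels, design$primer_levels)
    stopifnot(length(probs) == design$primer_levels)
    lev <- paste0("primer", seq_len(design$primer_levels))
    primer <- matrix(sample(lev, n_v * n_r, TRUE, prob = probs), n_v)
    for (l in seq_len(design$primer_levels - 1L))
      det[, , pd + l] <- (primer == lev[l + 1L]) * 1
  }
  dn <- character(0)
  if (pd) dn <- paste0("det_cov", seq_len(pd))
  if (design$primer_levels > 1L)
    dn <- c(dn, paste0("primer", seq(2L, design$primer_levels)))
  dimnames(det) <- list(NULL, NULL, if (length(dn)) dn else NULL)
  list(occ = occ, det = det, primer = primer)
}

## visit bookkeeping table for a design
design_visits <- function(design) {
  g <- expand.grid(visit = seq_len(design$visits_per_site_year),
                   site_id = paste0("s", seq_len(design$n_sites)),
                   year = seq_len(design$n_years),
                   stringsAsFactors = FALSE)
  data.frame(site_id = g$site_id, year = g$year,
             visit_id = paste0(g$site_id, "_y", g$year, "_v", g$visit),
             stringsAsFactors = FALSE)
}

#' Simulate a presence-absence detection dataset from an occupancy model
#'
#' Generates data under the hierarchical occupancy model the package fits:
#' latent occupancy `z[i, k] ~ Bernoulli(psi[i, k])` with
#' `logit(psi) = lpsi_k + betalpsi_k . x_i`, and conditional detections
#' `y[i, j, k] | z ~ Bernoulli(z[i, k] * p[i, j, k])` with
#' `logit(p) = lp_k + betalp_k . v_ij`.  Detections therefore never occur
#' where a taxon is absent, and replicate detections are conditionally
#' independent given presence.
#'
#' @param params A `community_params` object from
#'   [draw_community_params()]; slope dimensions must match the design.
#' @param design A [survey_design()].
#' @param covariates A [covariate_spec()] (defaults to standardized
#'   normal covariates and uniform primer use).
#' @param seed Optional integer seed.
#' @param missingness Proportion of visit-replicates masked as missing
#'   (beyond the first replicate, which is always kept).
#' @return A `detection_dataset` in presence-absence mode with attributes
#'   `z` (true occupancy matrix) and `params` retained for testing.
#' @export
simulate_dataset <- function(params, design,
                             covariates = covariate_spec(),
                             seed = NULL, missingness = 0) {
  stopifnot(inherits(design, "survey_design"))
  if (length(params$lpsi) != design$n_taxa_true)
    stop("params has ", length(params$lpsi), " taxa but design expects ",
         design$n_taxa_true, call. = FALSE)
  if (ncol(params$betalpsi) != design$n_occ_covariates ||
      ncol(params$betalp) != design$n_det_total)
    stop("covariate dimensions of params do not match design",
         call. = FALSE)
  set_seed_if(seed)
  cov <- simulate_covariates(design, covariates)
  n_v <- design$n_visits; n_r <- design$replicates_per_visit
  n_k <- design$n_taxa_true
  ## occupancy
  eta_occ <- matrix(params$lpsi, n_v, n_k, byrow = TRUE)
  if (ncol(cov$occ)) eta_occ <- eta_occ + cov$occ %*% t(params$betalpsi)
  psi <- plogis(eta_occ)
  z <- matrix(rbinom(n_v * n_k, 1L, psi), n_v, n_k)
  ## detection
  y <- array(0L, dim = c(n_v, n_r, n_k))
  for (j in seq_len(n_r)) {
    eta_det <- matrix(params$lp, n_v, n_k, byrow = TRUE)
    if (dim(cov$det)[3])
      eta_det <- eta_det +
        matrix(cov$det[, j, ], n_v) %*% t(params$betalp)
    p <- plogis(eta_det)
    y[, j, ] <- z * matrix(rbinom(n_v * n_k, 1L, p), n_v, n_k)
  }
  taxa <- paste0("t", seq_len(n_k))
  dimnames(y)[[3]] <- taxa
  ## mask missing replicates (never the first)
  if (missingness > 0 && n_r > 1L) {
    for (j in seq(2L, n_r)) {
      drop <- runif(n_v) < missingness
      y[drop, j, ] <- NA
      if (dim(cov$det)[3]) cov$det[drop, j, ] <- NA
      if (!is.null(cov$primer)) cov$primer[drop, j] <- NA
    }
  }
  ds <- detection_dataset(y, design_visits(design),
                          occ_covariates = cov$occ,
                          det_covariates = cov$det,
                          taxonomy = make_taxonomy(n_k, max(1L, n_k %/% 3L),
                                                   seed = NULL),
                          mode = "presence_absence", primer = cov$primer)
  attr(ds, "z") <- z
  attr(ds, "params") <- params
  ds
}

#' Simulate a count dataset from a community N-mixture model
#'
#' Generates replicated counts under the latent-abundance model:
#' `N[i, k] ~ Poisson(lambda[i, k])` with
#' `log(lambda) = llambda_k + betalpsi_k . x_i`, and
#' `y[i, j, k] | N ~ Binomial(N[i, k], p[i, j, k])`.  The `lpsi`/`betalpsi`
#' fields of `params` are interpreted on the log-abundance scale.
#'
#' @inheritParams simulate_dataset
#' @return A `detection_dataset` in count mode with attribute `N` (true
#'   latent abundances).
#' @export
simulate_count_dataset <- function(params, design,
                                   covariates = covariate_spec(),
                                   seed = NULL) {
  stopifnot(inherits(design, "survey_design"))
  set_seed_if(seed)
  cov <- simulate_covariates(design, covariates)
  n_v <- design$n_visits; n_r <- design$replicates_per_visit
  n_k <- design$n_taxa_true
  eta_lam <- matrix(params$lpsi, n_v, n_k, byrow = TRUE)
  if (ncol(cov$occ)) eta_lam <- eta_lam + cov$occ %*% t(params$betalpsi)
  lambda <- exp(eta_lam)
  if (any(lambda <= 0)) stop("lambda must be positive", call. = FALSE)
  N <- matrix(rpois(n_v * n_k, lambda), n_v, n_k)
  y <- array(0L, dim = c(n_v, n_r, n_k))
  for (j in seq_len(n_r)) {
    eta_det <- matrix(params$lp, n_v, n_k, byrow = TRUE)
    if (dim(cov$det)[3])
      eta_det <- eta_det +
        matrix(cov$det[, j, ], n_v) %*% t(params$betalp)
    p <- plogis(eta_det)
    y[, j, ] <- matrix(rbinom(n_v * n_k, N, p), n_v, n_k)
  }
  dimnames(y)[[3]] <- paste0("t", seq_len(n_k))
  ds <- detection_dataset(y, design_visits(design),
                          occ_covariates = cov$occ,
                          det_covariates = cov$det,
                          taxonomy = make_taxonomy(n_k, max(1L, n_k %/% 3L)),
                          mode = "count", primer = cov$primer)
  attr(ds, "N") <- N
  attr(ds, "params") <- params
  ds
}
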