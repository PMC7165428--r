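#' Collapse replicates to an observed site-by-taxon matrix
#'
#' Presence of a taxon at a site visit is recorded when any replicate
#' sample detected it; visits whose replicates are all masked are
#' dropped.
#'
#' @param data A `detection_dataset` in presence-absence mode.
#' @return A binary matrix (class `community_matrix`) with one row per
#'   site visit and one column per taxon.
#' @export
observed_matrix <- function(data) {
  stopifnot(inherits(data, "detection_dataset"))
  if (data$mode != "presence_absence")
    stop("observed_matrix() needs presence-absence data", call. = FALSE)
  m <- apply(data$y, c(1, 3), function(v)
    if (all(is.na(v))) NA_integer_ else as.integer(any(v > 0, na.rm = TRUE)))
  keep <- !is.na(m[, 1])
  m <- m[keep, , drop = FALSE]
  rownames(m) <- data$visits$visit_id[keep]
  colnames(m) <- data$taxa
  structure(m, class = c("community_matrix", class(m)))
}

#' Detection-corrected community matrices from a fitted model
#'
#' Returns the posterior draws of the latent occupancy matrix `z` (the
#' detection-corrected analogue of the observed matrix), along with
#' per-draw alpha diversity (row sums) and gamma diversity (`sum(w_k)`).
#' Because `z = 1` wherever a detection occurred, corrected alpha never
#' falls below observed alpha.
#'
#' @param fit An `msom_fit` run with `store_z = TRUE` in
#'   [mcmc_control()].
#' @param max_draws Cap on the number of z draws returned (subsampled
#'   evenly; all are used for the alpha/gamma summaries).
#' @return List with `z` (list of binary visit x M matrices), `alpha`
#'   (draws x visits matrix), `gamma` (vector), `observed_alpha`.
#' @export
corrected_matrices <- function(fit, max_draws = Inf) {
  stopifnot(inherits(fit, "msom_fit"))
  if (is.null(fit$z_draws))
    stop("latent z draws were not stored; refit with ",
         "mcmc_control(store_z = TRUE)", call. = FALSE)
  zs <- fit$z_draws
  n_keep <- dim(zs[[1]])[1]
  ## apply over draws returns visits x draws; transpose per chain
  alpha <- do.call(rbind, lapply(zs, function(a) {
    t(apply(a, 1, rowSums))
  }))
  idx <- seq_len(min(n_keep, ceiling(max_draws / length(zs))))
  zmats <- list()
  for (ch in seq_along(zs))
    for (i in idx)
      zmats[[length(zmats) + 1L]] <- zs[[ch]][i, , ]
  obs <- observed_matrix(fit$data)
  list(z = zmats, alpha = alpha,
       gamma = posterior_draws(fit, "gamma"),
       observed_alpha = rowSums(obs))
}

#' Pairwise compositional dissimilarity between sites
#'
#' Jaccard or Sorensen dissimilarity on presence-absence rows, computed
#' with \pkg{vegan}.  Shared absences carry no similarity (double zeros
#' are ignored), the diagonal is zero and the matrix symmetric.  A site
#' with no taxa is maximally dissimilar (1) to any non-empty site and is
#' flagged with a warning; two empty sites get dissimilarity 0.
#'
#' @param m Binary site x taxon matrix.
#' @param metric `"jaccard"` or `"sorensen"`.
#' @return A symmetric `n x n` dissimilarity matrix in `[0, 1]`.
#' @export
pairwise_dissimilarity <- function(m, metric = c("jaccard", "sorensen")) {
  metric <- match.arg(metric)
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("need at least 2 sites", call. = FALSE)
  if (any(!m %in% c(0, 1))) stop("matrix must be binary", call. = FALSE)
  empty <- rowSums(m) == 0
  if (any(empty))
    warning(sum(empty), " site(s) with zero taxa: dissimilarity to ",
            "non-empty sites set to 1", call. = FALSE)
  ## vegan warns about empty rows itself; we already handle them
  d <- suppressWarnings(switch(metric,
              jaccard = vegan::vegdist(m, "jaccard", binary = TRUE),
              sorensen = vegan::vegdist(m, "bray", binary = TRUE)))
  d <- as.matrix(d)
  if (any(empty)) {
    d[empty, ] <- 1; d[, empty] <- 1
    d[empty, empty] <- 0
  }
  diag(d) <- 0
  d
}

#' Aggregate taxa to a coarser taxonomic rank
#'
#' Presence at a family is the logical OR over its member genera
#' (presence-absence data); counts are summed.  Aggregation is idempotent
#' and order-independent, and a family's prevalence is always at least
#' that of each member genus.
#'
#' @param x A `community_matrix` (columns named by taxon id) or a
#'   `detection_dataset`.
#' @param taxonomy Data.frame with `taxon_id`, `genus`, `family` covering
#'   every column/taxon of `x`; defaults to the dataset's own taxonomy.
#' @param rank Target rank: `"family"` or `"genus"`.
#' @return An object of the same type as `x` with columns at the coarser
#'   rank.
#' @export
aggregate_taxa <- function(x, taxonomy = NULL, rank = c("family", "genus")) {
  rank <- match.arg(rank)
  if (inherits(x, "detection_dataset")) {
    taxonomy <- taxonomy %||% x$taxonomy
    grp <- rank_groups(x$taxa, taxonomy, rank)
    n_v <- dim(x$y)[1]; n_r <- dim(x$y)[2]
    levs <- unique(grp)
    ynew <- array(NA_real_, dim = c(n_v, n_r, length(levs)),
                  dimnames = list(NULL, NULL, levs))
    for (li in seq_along(levs)) {
      sub <- x$y[, , grp == levs[li], drop = FALSE]
      ynew[, , li] <- if (x$mode == "count")
        apply(sub, c(1, 2), function(v)
          if (all(is.na(v))) NA_real_ else sum(v)) else
        apply(sub, c(1, 2), function(v)
          if (all(is.na(v))) NA_real_ else max(v))
    }
    tax <- unique(taxonomy[taxonomy[[rank]] %in% levs,
                           c(rank), drop = FALSE])
    taxnew <- data.frame(taxon_id = levs, genus = levs, family = levs,
                         stringsAsFactors = FALSE)
    if (rank == "genus") {
      fam <- taxonomy$family[match(levs, taxonomy$genus)]
      taxnew$family <- fam
    }
    return(detection_dataset(ynew, x$visits, x$occ_covariates,
                             x$det_covariates, taxnew, x$mode, x$primer))
  }
  m <- as.matrix(x)
  grp <- rank_groups(colnames(m), taxonomy, rank)
  agg <- t(rowsum(t(m), grp))
  if (max(m) <= 1) agg <- (agg > 0) * 1L
  structure(agg, class = c("community_matrix", class(agg)))
}

rank_groups <- function(taxa, taxonomy, rank) {
  if (is.null(taxonomy)) stop("taxonomy map required", call. = FALSE)
  pos <- match(taxa, taxonomy$taxon_id)
  if (anyNA(pos)) {
    ## columns may already be at genus/family rank
    pos <- match(taxa, taxonomy$genus)
    if (anyNA(pos)) pos <- match(taxa, taxonomy$family)
  }
  if (anyNA(pos))
    stop("taxa not found in taxonomy: ",
         paste(utils::head(taxa[is.na(pos)], 5), collapse = ", "),
         call. = FALSE)
  taxonomy[[rank]][pos]
}

#' Dissimilarity contrast between taxonomic resolutions
#'
#' Quantifies how much more compositional turnover is visible at genus
#' rank than at family rank: the difference between mean pairwise
#' dissimilarities, both relative to the family-rank mean (`percent`)
#' and as raw percentage points (`points`).  Because family presence is
#' the OR of member genera, genus-rank dissimilarity is expected to be
#' the larger.
#'
#' @param genus_m,family_m Binary site x taxon matrices on the same sites.
#' @param metric Dissimilarity metric, see [pairwise_dissimilarity()].
#' @return List with `genus_mean`, `family_mean`, `percent`
#'   (100 * (g - f) / f; `Inf` when the family mean is 0 and g > f) and
#'   `points` (100 * (g - f)).
#' @export
resolution_dissimilarity_contrast <- function(genus_m, family_m,
                                              metric = "jaccard") {
  if (nrow(genus_m) != nrow(family_m))
    stop("matrices must share sites", call. = FALSE)
  if (nrow(genus_m) < 2) stop("need at least 2 sites", call. = FALSE)
  md <- function(m) {
    d <- suppressWarnings(pairwise_dissimilarity(m, metric))
    mean(d[lower.tri(d)])
  }
  g <- md(genus_m); f <- md(family_m)
  pct <- if (f > 0) 100 * (g - f) / f else if (g == f) 0 else Inf
  list(genus_mean = g, family_mean = f, percent = pct,
       points = 100 * (g - f))
}

#' Percent increase of estimated over observed richness
#'
#' The reporting arithmetic for detection-corrected richness: the
#' increase of the model-estimated richness over the observed total,
#' rounded to integer percent.
#'
#' @param estimated Estimated richness (e.g. posterior mean gamma).
#' @param observed Observed richness (> 0).
#' @return Integer percent, `round(100 * (estimated - observed) / observed)`.
#' @examples
#' percent_increase(95, 74)   # 28
#' percent_increase(360, 263) # 37
#' @export
percent_increase <- function(estimated, observed) {
  if (any(observed <= 0)) stop("observed richness must be > 0",
                               call. = FALSE)
  round(100 * (estimated - observed) / observed)
}
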