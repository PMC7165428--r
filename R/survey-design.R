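#' Define a replicated biomonitoring survey design
#'
#' A survey design fixes the dimensions of a simulated metacommunity survey:
#' how many sites are visited, over how many years, how many replicate
#' samples are taken per visit, how many taxa truly make up the regional
#' pool (gamma diversity), and how many occupancy and detection covariates
#' (plus primer levels) are recorded.
#'
#' Replicate samples are simultaneous independent samples of the same site
#' visit; they are what lets an occupancy model separate the ecological
#' state (occupancy) from the observation process (detectability).
#'
#' @param n_sites Number of distinct sites.
#' @param n_years Number of survey years; every site is visited each year.
#' @param visits_per_site_year Visits to each site within a year.
#' @param replicates_per_visit Replicate samples per visit (typically 1-3).
#' @param n_taxa_true True regional richness (gamma) of the simulated pool.
#' @param n_occ_covariates Number of continuous site-visit-level occupancy
#'   covariates (e.g. flood frequency, days since ice melt, water
#'   temperature).
#' @param n_det_covariates Number of continuous sample-level detection
#'   covariates (e.g. sequencing depth, individuals counted).
#' @param primer_levels Number of primer-pair levels for the categorical
#'   detection covariate; 1 means no primer effect.
#' @return An object of class `survey_design`.
#' @seealso [draw_community_params()], [simulate_dataset()]
#' @examples
#' survey_design(n_sites = 12, n_years = 2, n_taxa_true = 40)
#' @export
survey_design <- function(n_sites, n_years = 1L, visits_per_site_year = 1L,
                          replicates_per_visit = 3L, n_taxa_true = 100L,
                          n_occ_covariates = 0L, n_det_covariates = 0L,
                          primer_levels = 1L) {
  d <- list(
    n_sites = check_count(n_sites),
    n_years = check_count(n_years),
    visits_per_site_year = check_count(visits_per_site_year),
    replicates_per_visit = check_count(replicates_per_visit),
    n_taxa_true = check_count(n_taxa_true),
    n_occ_covariates = check_count(n_occ_covariates, min = 0L),
    n_det_covariates = check_count(n_det_covariates, min = 0L),
    primer_levels = check_count(primer_levels)
  )
  d$n_visits <- d$n_sites * d$n_years * d$visits_per_site_year
  ## primer enters the detection design matrix as treatment contrasts
  d$n_det_total <- d$n_det_covariates + d$primer_levels - 1L
  structure(d, class = "survey_design")
}

#' @export
print.survey_design <- function(x, ...) {
  cat("Survey design:",
      x$n_sites, "sites x", x$n_years, "years x",
      x$visits_per_site_year, "visit(s);",
      x$replicates_per_visit, "replicate(s)/visit\n")
  cat("  regional pool:", x$n_taxa_true, "taxa;",
      x$n_occ_covariates, "occupancy covariate(s);",
      x$n_det_covariates, "detection covariate(s);",
      x$primer_levels, "primer level(s)\n")
  invisible(x)
}

#' Survey design emulating a boreal delta wetland monitoring program
#'
#' A convenience preset shaped like a multi-year wetland macroinvertebrate
#' metabarcoding program: ~30 sites visited across 6 years, triplicate
#' samples, 360 genera in 130 families, three occupancy covariates
#' (flood frequency, days since ice melt, maximum water temperature), two
#' detection covariates (sequencing depth, individuals counted) and two
#' primer pairs.
#'
#' @param n_taxa_true Regional genus richness.
#' @return A `survey_design`.
#' @export
delta_wetland_design <- function(n_taxa_true = 360L) {
  survey_design(n_sites = 30L, n_years = 6L, visits_per_site_year = 1L,
                replicates_per_visit = 3L, n_taxa_true = n_taxa_true,
                n_occ_covariates = 3L, n_det_covariates = 2L,
                primer_levels = 2L)
}

#' Generate a genus-to-family taxonomy map
#'
#' Assigns genera to families uniformly at random with 1-8 genera per
#' family, producing the skewed genus-per-family structure typical of
#' freshwater invertebrate reference libraries.
#'
#' @param n_genera Number of genera (taxon ids `t1..tn`).
#' @param n_families Number of families; must not exceed `n_genera`.
#' @param seed Optional integer seed.
#' @return A data.frame with columns `taxon_id`, `genus`, `family`.
#' @export
make_taxonomy <- function(n_genera = 360L, n_families = 130L, seed = NULL) {
  n_genera <- check_count(n_genera)
  n_families <- check_count(n_families)
  if (n_families > n_genera)
    stop("'n_families' cannot exceed 'n_genera'", call. = FALSE)
  set_seed_if(seed)
  fam <- paste0("f", seq_len(n_families))
  ## every family gets one genus; the rest are capped at 8 per family
  assign <- fam
  counts <- setNames(rep(1L, n_families), fam)
  extra <- n_genera - n_families
  if (extra > 0L) {
    for (i in seq_len(extra)) {
      open <- names(counts)[counts < 8L]
      if (!length(open)) open <- names(counts)  # all full: relax the cap
      pick <- sample(open, 1L)
      counts[pick] <- counts[pick] + 1L
      assign <- c(assign, pick)
    }
  }
  assign <- sample(assign)  # shuffle so genus index is not ordered by family
  data.frame(taxon_id = paste0("t", seq_len(n_genera)),
             genus = paste0("g", seq_len(n_genera)),
             family = assign,
             stringsAsFactors = FALSE)
}
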