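#' Write a detection dataset as plain-text tables
#'
#' Writes the long-format observation table (`observations.csv`:
#' site_id, year, visit_id, replicate_id, taxon_id, value and, when
#' present, primer), the site-visit covariate table (`covariates.csv`),
#' the taxonomy map (`taxonomy.tsv`) and a JSON sidecar
#' (`generation.json`) echoing the dataset mode and dimensions.  Masked
#' replicates are simply absent from the observation table.
#'
#' @param data A `detection_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_detection_dataset <- function(data, dir) {
  stopifnot(inherits(data, "detection_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_v <- dim(data$y)[1]; n_r <- dim(data$y)[2]; K <- dim(data$y)[3]
  rows <- list()
  for (j in seq_len(n_r)) {
    sampled <- !is.na(data$y[, j, 1])
    if (!any(sampled)) next
    df <- expand.grid(visit = which(sampled), taxon = seq_len(K))
    rows[[j]] <- data.frame(
      site_id = data$visits$site_id[df$visit],
      year = data$visits$year[df$visit],
      visit_id = data$visits$visit_id[df$visit],
      replicate_id = j,
      taxon_id = data$taxa[df$taxon],
      value = data$y[cbind(df$visit, j, df$taxon)],
      stringsAsFactors = FALSE)
    if (!is.null(data$primer))
      rows[[j]]$primer <- data$primer[df$visit, j]
  }
  obs <- do.call(rbind, rows)
  obs_path <- file.path(dir, "observations.csv")
  write.csv(obs, obs_path, row.names = FALSE)
  cov <- cbind(data$visits, as.data.frame(data$occ_covariates))
  cov_path <- file.path(dir, "covariates.csv")
  write.csv(cov, cov_path, row.names = FALSE)
  tax_path <- file.path(dir, "taxonomy.tsv")
  write.table(data$taxonomy, tax_path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  side_path <- file.path(dir, "generation.json")
  jsonlite::write_json(list(mode = data$mode, n_visits = n_v,
                            max_replicates = n_r, n_taxa = K),
                       side_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(obs_path, cov_path, tax_path, side_path))
}

#' Read a long-format detection table
#'
#' Reads the CSV schema written by [write_detection_dataset()]:
#' required columns `site_id`, `year`, `visit_id`, `replicate_id`,
#' `taxon_id`, `value`, optional `primer`.  Duplicate
#' (visit, replicate, taxon) rows are rejected; values are validated
#' against the declared mode.  Visit-level covariates and a taxonomy can
#' be supplied from companion files.
#'
#' @param path Path to the observation CSV.
#' @param mode `"presence_absence"` or `"count"`.
#' @param covariates_path Optional covariates CSV (columns `visit_id`
#'   plus numeric covariates).
#' @param taxonomy_path Optional taxonomy TSV (see [read_taxonomy()]).
#' @return A `detection_dataset`.
#' @export
read_detection_table <- function(path,
                                 mode = c("presence_absence", "count"),
                                 covariates_path = NULL,
                                 taxonomy_path = NULL) {
  mode <- match.arg(mode)
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("site_id", "year", "visit_id", "replicate_id", "taxon_id",
           "value")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df[c("visit_id", "replicate_id", "taxon_id")]))
    stop("duplicate (visit, replicate, taxon) rows", call. = FALSE)
  if (mode == "presence_absence" && any(!df$value %in% c(0, 1)))
    stop("non-binary values in presence_absence mode", call. = FALSE)
  if (mode == "count" &&
      (any(df$value < 0) || any(df$value != round(df$value))))
    stop("counts must be nonnegative integers", call. = FALSE)
  visits <- unique(df[c("site_id", "year", "visit_id")])
  visits <- visits[order(match(visits$visit_id, df$visit_id)), ]
  rownames(visits) <- NULL
  taxa <- sort(unique(df$taxon_id))
  reps <- sort(unique(df$replicate_id))
  y <- array(NA_real_, dim = c(nrow(visits), max(reps), length(taxa)),
             dimnames = list(NULL, NULL, taxa))
  vi <- match(df$visit_id, visits$visit_id)
  ti <- match(df$taxon_id, taxa)
  y[cbind(vi, df$replicate_id, ti)] <- df$value
  ## a sampled (visit, replicate) must cover every taxon
  for (j in reps) {
    partial <- apply(y[, j, , drop = FALSE], 1, function(v)
      any(is.na(v)) && !all(is.na(v)))
    if (any(partial))
      stop("replicate ", j, " has rows for some taxa but not others",
           call. = FALSE)
  }
  primer <- NULL
  if ("primer" %in% names(df)) {
    primer <- matrix(NA_character_, nrow(visits), max(reps))
    primer[cbind(vi, df$replicate_id)] <- df$primer
  }
  occ <- NULL
  if (!is.null(covariates_path)) {
    cv <- read.csv(covariates_path, stringsAsFactors = FALSE)
    stopifnot("visit_id" %in% names(cv))
    cv <- cv[match(visits$visit_id, cv$visit_id), , drop = FALSE]
    num <- vapply(cv, is.numeric, logical(1)) &
      !names(cv) %in% c("year", "replicate_id")
    occ <- as.matrix(cv[, num, drop = FALSE])
  }
  taxonomy <- if (!is.null(taxonomy_path)) read_taxonomy(taxonomy_path)
  detection_dataset(y, visits, occ_covariates = occ, taxonomy = taxonomy,
                    mode = mode, primer = primer)
}

#' Read a taxonomy map
#'
#' TSV with columns `taxon_id`, `genus`, `family`.  Duplicate taxon ids
#' and genera assigned to more than one family are rejected.
#'
#' @param path Path to the TSV.
#' @return Data.frame taxonomy map.
#' @export
read_taxonomy <- function(path) {
  tx <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("taxon_id", "genus", "family")
  miss <- setdiff(req, names(tx))
  if (length(miss))
    stop("taxonomy missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(tx$taxon_id))
    stop("duplicated taxon_id in taxonomy", call. = FALSE)
  gf <- unique(tx[c("genus", "family")])
  if (anyDuplicated(gf$genus))
    stop("genus mapped to more than one family", call. = FALSE)
  tx
}

## ---- config-driven pipeline stages ---------------------------------

read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopifnot(is.list(cfg))
  cfg
}

write_manifest <- function(dir, cfg, seed, stage) {
  manifest <- list(stage = stage, seed = seed,
                   config = cfg,
                   package_version =
                     as.character(utils::packageVersion("msompower")),
                   r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(NULL)
}

#' Run the simulate stage from a config
#'
#' Config keys (all optional, with survey-design defaults): `design`
#' (fields of [survey_design()]), `hyperparams` (fields of
#' [community_hyperparams()]), `mode`.
#'
#' @param config Path to a YAML config or a config list.
#' @param out Output directory.
#' @param seed Integer seed.
#' @return Invisibly, the simulated `detection_dataset`.
#' @export
run_simulate <- function(config, out, seed = 1L) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  design <- do.call(survey_design, cfg$design %||% list(n_sites = 30L))
  hp <- do.call(community_hyperparams, cfg$hyperparams %||% list())
  seeds <- derive_seeds(seed, 2)
  params <- draw_community_params(hp, design$n_taxa_true,
                                  design$n_occ_covariates,
                                  design$n_det_total,
                                  seed = seeds[[1]])
  data <- if (identical(cfg$mode, "count"))
    simulate_count_dataset(params, design, seed = seeds[[2]])
  else simulate_dataset(params, design, seed = seeds[[2]])
  write_detection_dataset(data, out)
  write_manifest(out, cfg, seed, "simulate")
  invisible(data)
}

#' Run the fit stage from a config
#'
#' Config keys: `observations`, `covariates`, `taxonomy` (paths),
#' `model` (`"occupancy_pa"` or `"nmixture_count"`), `mcmc` (fields of
#' [mcmc_control()]), `prior` (fields of [prior_spec()]).
#'
#' @inheritParams run_simulate
#' @return Invisibly, the fit object; posterior draws go to
#'   `posterior.csv` (long format) and diagnostics to
#'   `diagnostics.json` in `out`.
#' @export
run_fit <- function(config, out, seed = 1L) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  model <- cfg$model %||% "occupancy_pa"
  mode <- if (model == "nmixture_count") "count" else "presence_absence"
  data <- read_detection_table(cfg$observations, mode = mode,
                               covariates_path = cfg$covariates,
                               taxonomy_path = cfg$taxonomy)
  control <- do.call(mcmc_control, cfg$mcmc %||% list())
  prior <- do.call(prior_spec, cfg$prior %||% list())
  fit <- if (model == "nmixture_count")
    fit_nmixture(data, control, prior, seed = seed)
  else fit_msom(data, control, prior, seed = seed)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  long <- do.call(rbind, lapply(seq_along(fit$draws), function(ch) {
    d <- fit$draws[[ch]]
    data.frame(chain = ch, iteration = seq_len(nrow(d)),
               parameter = rep(colnames(d), each = nrow(d)),
               value = as.vector(d))
  }))
  write.csv(long, file.path(out, "posterior.csv"), row.names = FALSE)
  sm <- summary(fit)
  diag <- list(
    rhat = setNames(as.list(sm$rhat), sm$parameter),
    n_flagged = sum(!sm$converged, na.rm = TRUE),
    acceptance = fit$accept,
    inclusion = fit$inclusion,
    gamma = estimate_gamma(fit)[c("mean", "ci", "observed")])
  jsonlite::write_json(diag, file.path(out, "diagnostics.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(out, cfg, seed, "fit")
  invisible(fit)
}

#' Run the diversity stage from a config
#'
#' Reads observations, computes the observed community matrix, pairwise
#' dissimilarities at genus and family rank, and summary richness; writes
#' them as CSV/JSON.
#'
#' @inheritParams run_simulate
#' @return Invisibly, a list of the computed tables.
#' @export
run_diversity <- function(config, out, seed = 1L) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  data <- read_detection_table(cfg$observations,
                               taxonomy_path = cfg$taxonomy)
  m <- observed_matrix(data)
  metric <- cfg$metric %||% "jaccard"
  d_genus <- pairwise_dissimilarity(m, metric)
  fam <- aggregate_taxa(m, data$taxonomy, "family")
  d_family <- pairwise_dissimilarity(fam, metric)
  contrast <- resolution_dissimilarity_contrast(m, fam, metric)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write.csv(as.data.frame(m), file.path(out, "observed_matrix.csv"))
  write.csv(d_genus, file.path(out, "dissimilarity_genus.csv"))
  write.csv(d_family, file.path(out, "dissimilarity_family.csv"))
  jsonlite::write_json(
    list(observed_richness = observed_richness(data),
         mean_dissimilarity_genus = mean(d_genus[lower.tri(d_genus)]),
         mean_dissimilarity_family = mean(d_family[lower.tri(d_family)]),
         resolution_contrast = contrast[c("percent", "points")]),
    file.path(out, "diversity.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  write_manifest(out, cfg, seed, "diversity")
  invisible(list(matrix = m, genus = d_genus, family = d_family))
}

#' Run the power stage from a config
#'
#' Config keys: `gamma`, `n_families`, `occupancy` (`mu`, `sigma`),
#' `design` (lists `n_sites`, `replicates`, `approach` crossed into a
#' grid), `severities`, `n_sim`, `alpha`, `n_resamples`.
#'
#' @inheritParams run_simulate
#' @return Invisibly, the `power_result`; the tidy power table goes to
#'   `power.csv` and minimum detectable severities to
#'   `minimum_detectable.json`.
#' @export
run_power <- function(config, out, seed = 1L) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  gamma <- cfg$gamma %||% 120L
  seeds <- derive_seeds(seed, 3)
  taxonomy <- make_taxonomy(gamma, cfg$n_families %||% max(1L, gamma %/% 3L),
                            seed = seeds[[1]])
  occ <- cfg$occupancy %||% list(mu = -1.5, sigma = 1.2)
  set_seed_if(seeds[[2]])
  psi <- plogis(rnorm(gamma, occ$mu, occ$sigma))
  dg <- expand.grid(n_sites = cfg$design$n_sites %||% c(4L, 12L),
                    replicates = cfg$design$replicates %||% c(1L, 3L),
                    approach = cfg$design$approach %||%
                      c("CABIN_family", "DNA_family", "DNA_genus"),
                    stringsAsFactors = FALSE)
  res <- power_curve(psi, dg,
                     severities = cfg$severities %||% c(0, 0.2, 0.4, 0.7),
                     taxonomy = taxonomy,
                     n_sim = cfg$n_sim %||% 100L,
                     alpha = cfg$alpha %||% 0.05,
                     n_resamples = cfg$n_resamples %||% 499L,
                     seed = seeds[[3]])
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write.csv(res$power, file.path(out, "power.csv"), row.names = FALSE)
  jsonlite::write_json(res$minimum_detectable,
                       file.path(out, "minimum_detectable.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(out, cfg, seed, "power")
  invisible(res)
}

#' Command-line entry point
#'
#' Dispatches `simulate`, `fit`, `diversity` or `power` with flags
#' `--config`, `--seed`, `--out`; used by the `msompower` script in
#' `inst/scripts/`.
#'
#' @param args Character vector of arguments (defaults to the command
#'   line).
#' @return Exit code, invisibly (0 on success).
#' @export
msompower_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: msompower <simulate|fit|diversity|power>",
                 "--config FILE --out DIR [--seed N]")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  sub <- args[1]
  get_flag <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i[1] < length(args)) args[i[1] + 1] else default
  }
  cfgf <- get_flag("--config")
  out <- get_flag("--out", "msompower_out")
  seed <- as.integer(get_flag("--seed", "1"))
  runner <- switch(sub, simulate = run_simulate, fit = run_fit,
                   diversity = run_diversity, power = run_power, NULL)
  if (is.null(runner) || is.null(cfgf)) {
    message(usage)
    return(invisible(1L))
  }
  tryCatch({
    runner(cfgf, out, seed)
    invisible(0L)
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    invisible(1L)
  })
}
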