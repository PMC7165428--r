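---
title: "Community occupancy models, detection-corrected diversity, and monitoring power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community occupancy models, detection-corrected diversity, and monitoring power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`msompower` is built around a single question that dominates
biomonitoring of diverse, hard-to-sample communities such as wetland
macroinvertebrates: *what does a survey miss, and what does that imply
for richness estimates and for our power to notice change?*  This
vignette lays out the models the package fits, the choices behind their
implementation, and what the synthetic-data experiments in the test
suite do and do not demonstrate.

## The hierarchical multispecies occupancy model

The data are replicated detections: `y[i, j, k] = 1` when taxon `k` was
detected in replicate sample `j` of site visit `i`.  Replicates are
simultaneous independent samples, which is what lets the model separate
*occupancy* (is the taxon there?) from *detectability* (do we see it
when it is there?).  The hierarchy, from the bottom up:

1. **Data augmentation.** The taxon list is padded to a superpopulation
   of `M` taxa; each carries a membership indicator
   `w_k ~ Bernoulli(Omega)`.  Taxa detected at least once have
   `w_k = 1`; the all-zero rows estimate how many taxa the survey never
   saw.  Regional richness (gamma diversity) is `sum(w_k)` per
   posterior draw.
2. **State process.** `z[i, k] ~ Bernoulli(w_k * psi[i, k])` with
   `logit(psi) = lpsi_k + betalpsi_k · x_i` (site-visit covariates such
   as flood frequency or water temperature).
3. **Observation process.**
   `y[i, j, k] | z ~ Bernoulli(z[i, k] * p[i, j, k])` with
   `logit(p) = lp_k + betalp_k · v_ij` (sample covariates such as
   sequencing depth, individuals counted, and primer pair as a
   categorical contrast).
4. **Taxon heterogeneity.** All taxon-level intercepts and slopes are
   random effects from community normal distributions, e.g.
   `lpsi_k ~ Normal(mu_lpsi, sigma_lpsi^2)`.  These hyperparameters are
   what augmentation leans on to say anything about unseen taxa.

The count-data variant (`fit_nmixture()`) replaces (2)–(3) with latent
abundance `N[i, k] ~ Poisson(w_k * lambda[i, k])`,
`y[i, j, k] | N ~ Binomial(N[i, k], p[i, j, k])`, with log-normal
abundance heterogeneity across taxa (`log lambda` takes the role of the
logit-scale occupancy predictor).

## Sampler design

The models are fitted by a purpose-built Metropolis-within-Gibbs
sampler rather than a generic probabilistic-programming backend,
because indicator-variable selection and data augmentation interleave
naturally with exact conditional draws:

* `z`, `w`, `Omega`, and (for counts) `N` are drawn from their exact
  full conditionals.  The latent-abundance conditional is evaluated by
  truncated enumeration with a Poisson-tail bound keeping the neglected
  mass below `1e-10`; this is exact for any number of replicates and
  vectorizes across all site-by-taxon cells, which is why it is used
  instead of a discrete random-walk proposal.
* Taxon-level intercepts and slopes use adaptive random-walk
  Metropolis, vectorized across taxa.  Proposal scales adapt by a
  Robbins–Monro rule toward 0.35 acceptance during burn-in only and are
  frozen afterwards, so the retained chain is a fixed-kernel Markov
  chain.
* Hyper-means have conjugate normal updates; hyper-SDs use a
  random-walk on the log scale.  Members with no data weight (taxa with
  `w = 0`, or covariates switched off) are redrawn directly from their
  priors — an exact Gibbs step that keeps augmented taxa mixing fast.
* Covariate selection follows the Kuo–Mallick construction: one shared
  inclusion indicator `V_x ~ Bernoulli(0.5)` per covariate multiplies
  that covariate's contribution for every taxon, and its full
  conditional compares the model likelihood with the covariate on
  versus off.  Posterior inclusion frequencies are reported per
  covariate.  Indicator chains are known to mix slowly in complex
  models; the per-draw indicator values are stored so users can judge
  mixing directly.

**Priors.** Hyper-means are Normal(0, 1.5²) on the logit scale,
hyper-SDs Uniform(0, 5), `Omega ~ Beta(1, 1)` — weakly informative
defaults standard for community occupancy models, all adjustable via
`prior_spec()`, which can also hold any hyperparameter fixed (used by
the exact small-instance checks).

**Defaults.** 3 chains, 20 000 iterations, 10 000 burn-in, thin 10,
`M` twice the number of data taxa.  Convergence reporting is advisory:
`summary()` attaches the classic Gelman–Rubin between/within statistic
per parameter and flags values at or above 1.1, but no chain is ever
silently discarded.  Dunn–Smyth (randomized-quantile) residuals provide
the goodness-of-fit view that raw residuals cannot for binary data; a
deterministic midpoint mode exists purely for testing.

## Verification strategy

Because the sampler is hand-built, the test suite leans on independent
oracles rather than reference posteriors:

* On instances small enough to enumerate (2 visits × 2 replicates × 1
  taxon, hyperparameters fixed), the MCMC posterior of `(psi, p)` is
  compared to dense-grid quadrature — total variation below 0.05 at
  50 000 draws.
* Conditional updates (`z`, `w`, `Omega`, `N`) are checked against
  hand-enumerated probabilities and brute-force normalization.
* Coverage: across 20 replicate surveys of 50 taxa × 60 visits × 3
  replicates generated at `mu_lpsi = -0.5`, `sigma_lpsi = 1`,
  `mu_lp = 0`, `sigma_lp = 1`, the 95% credible intervals for all four
  hyperparameters cover the truth in at least 17 of 20 fits (single
  chains of 3 000 iterations — chosen to keep the full study near ten
  minutes; the same code scales to the package defaults).
* Augmentation: communities of 120 genera simulated under a rare-biased
  regime (`mu_lpsi = -2`, `sigma_lpsi = 1.3`, `mu_lp = -1`,
  `sigma_lp = 1`; 30 sites × 3 replicates) leave roughly a quarter of
  taxa undetected; the posterior 95% interval for gamma recovers 120
  with the same 17/20 criterion.

## The synthetic-data generator

`simulate_dataset()` generates data from exactly the model the sampler
fits, which is the point: every downstream stage is testable without
any field data.  Covariates are standardized normal by default (the
model consumes them as generated), the primer pair is a categorical
covariate expanded to contrasts so each taxon gets per-primer
detectability, and missing replicates are masked rather than
zero-filled because the likelihood accommodates ragged designs
directly.  The `delta_wetland_design()` preset mirrors a boreal-delta
monitoring program: ~30 sites over 6 years, triplicate samples, 360
genera in 130 families with 1–8 genera per family.

What passing tests on such data show is that the *inference machinery*
is correct and well calibrated **when the model is true**.  They cannot
show robustness to what real surveys add: nonrandom aggregation of
individuals (the reason count models tend to be misspecified — see
`expected_richness_under_count_model()`, which quantifies the gap
between predicted and observed richness under random sampling of
individuals), taxonomic misassignment, spatial autocorrelation, or
covariates missing from the model.

## The metacommunity simulation and power engine

The power analysis asks how severe a community-occupancy decline must
be before a monitoring design notices it:

1. **Baseline.** A site × genus presence-absence matrix drawn from a
   fitted or parametric occupancy distribution.
2. **Turnover.** Year-to-year compositional change is simulated by
   curveball trades — fixed-margin permutation that holds each taxon's
   occupancy and each site's richness constant, i.e. random assembly.
   The trade count can be calibrated to a target within-site turnover
   (`calibrate_turnover()`); replicating strong observed turnover
   requires full redistribution, so the engine defaults to complete
   reshuffling between years.
3. **Stressor.** `apply_stressor()` removes an exact
   `round(severity × occurrences)` presences, allocated with
   probability proportional to `1 - tolerance_k`, where tolerances are
   Gaussian-copula draws rank-correlated with occupancy
   (`make_tolerances()`).  Severity is therefore the *fraction of all
   occurrences removed* — the only scale-free reading of "reduction to
   community occupancy".
4. **Observation.** Each replicate detects present taxa with per-taxon
   probabilities drawn from a logit-normal preset per sampling
   approach.  The presets encode the empirical ordering — morphology
   (`CABIN_family`, mean logit −1.5) well below metabarcoding at family
   rank (`DNA_family`, +0.8), genus rank slightly below family
   (`DNA_genus`, +0.2) because subtaxa are less prevalent and less
   abundant than their parents.  Family-rank approaches aggregate the
   genus-level truth by OR before sampling.
5. **Test.** Each post-impact year is compared to the pooled baseline
   years with a summed binomial likelihood-ratio statistic over taxa
   and a site-label permutation null (499 resamples by default) — a
   re-implementation of the `mvabund`-style community test.  A design
   "detects" an impact when at least one of two post-impact years
   rejects at `alpha = 0.05`; the minimum detectable severity is where
   the power curve crosses 0.5.

Two deliberate interpretations: "detected within 2 years at least 50%
of the time" is implemented as rejection in ≥1 of 2 consecutive
post-impact years (a both-years rule is available via `rule =
"both"`), and "95% confidence" is read as the per-test level 0.05.

A property worth knowing: with margin-preserving turnover the
site-label permutation null also resamples between-site richness
variation, so the test runs *conservative* at zero severity (rejection
below `alpha`).  This is inherent to comparing a fixed-margin null
against site resampling, not an implementation artifact, and it means
reported powers are if anything understated.

Replicated presence-absence data enter the comparison collapsed to
site-level any-replicate detection; replicate count therefore acts
through the effective detection probability `1 - (1 - p)^J`.

The test-suite power study uses a scaled-down metacommunity (120 genera
in 40 families, 2 baseline years, grids of 4–12 sites × 1 or 3
replicates, 100 simulations per cell) so the full sweep runs in
minutes; the engine itself is indifferent to scale.

## Diversity accounting

`observed_matrix()` collapses replicates by any-detection;
`corrected_matrices()` returns the latent `z` draws, whose row sums are
detection-corrected alpha diversity (never below observed alpha, since
detections force `z = 1`).  Pairwise dissimilarity uses Jaccard by
default — all headline comparisons are presence-absence — with Sørensen
available for sensitivity; both ignore shared absences, and the
dissimilarity index behind published turnover figures is usually
unstated, so neither is asserted as canonical.  Aggregation to family
rank is a logical OR (sum for counts), which makes family prevalence at
least that of any member genus and drives the expected sign of the
genus-versus-family dissimilarity contrast
(`resolution_dissimilarity_contrast()` reports both the ratio and the
percentage-point difference; the ratio is undefined when the
family-rank mean is zero).

## Numerical notes and degenerate inputs

* Bernoulli log-likelihoods zero out `0 · log 0` explicitly; fitted
  probabilities of exactly 0/1 that contradict an observation yield
  infinite residuals and a warning rather than `NaN`.
* `gelman_rubin()` is the classic (non-split) statistic; two constant,
  equal chains make it undefined and it returns `NA` with an
  `undefined` attribute.
* A visit whose replicates are all masked cannot enter a fit (error);
  an empty site is maximally dissimilar to non-empty sites and flagged.
* All randomness flows from one seed per entry point; chain seeds are
  derived sub-seeds, and identical seeds give bit-identical output.

## Known limitations

No spatial structure (the simulation is not spatially explicit), no
autologistic or phylogenetic terms, no count overdispersion beyond
Poisson (the misspecification check is the intended diagnostic), and no
sequence-level processes — detection bias is modeled strictly at the
probability level.
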