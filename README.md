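# msompower

Hierarchical multispecies occupancy models (MSOM), detection-corrected
diversity estimation, and monitoring power analysis for replicated
biomonitoring surveys — the setting where bulk community samples
(morphological sorting or DNA metabarcoding of wetland
macroinvertebrates, say) yield presence–absence or count records per
taxon, and *imperfect detection* systematically hides part of the
community.

It is written for ecologists and biomonitoring programs who need to

* estimate how many taxa a survey missed (gamma diversity via data
  augmentation) and correct alpha/beta diversity for detection error,
* compare the detectability of sampling protocols, primers, or
  taxonomic ranks on a common model scale, and
* ask how severe a community decline must be before a given monitoring
  design would notice it.

## The models

For detections `y[i,j,k]` of taxon `k` in replicate sample `j` of site
visit `i`, the occupancy model is the four-level hierarchy

```
w_k      ~ Bernoulli(Omega)                     # membership (augmentation)
z[i,k]   ~ Bernoulli(w_k * psi[i,k])            # occupancy state
y[i,j,k] ~ Bernoulli(z[i,k] * p[i,j,k])         # detection
logit(psi[i,k]) = lpsi_k + betalpsi_k · x_i     # taxon-level random effects
logit(p[i,j,k]) = lp_k   + betalp_k   · v_ij    #   from community Normals
lpsi_k ~ N(mu_lpsi, sigma_lpsi²),  lp_k ~ N(mu_lp, sigma_lp²), ...
```

with regional richness `gamma = sum(w_k)` per posterior draw.  The
count-data variant replaces the middle layers with
`N[i,k] ~ Poisson(w_k · lambda[i,k])`,
`y[i,j,k] ~ Binomial(N[i,k], p[i,j,k])`.  Covariate selection uses
Kuo–Mallick indicators `V_x ~ Bernoulli(0.5)` shared across taxa.
Everything is fitted by a purpose-built Metropolis-within-Gibbs sampler
(exact conditionals for all latent states, adaptive random walks for
taxon effects) with Gelman–Rubin and Dunn–Smyth diagnostics.

The power engine simulates a turnover-rich metacommunity (fixed-margin
"curveball" permutation: taxon occupancy and site richness held
constant), removes a fraction of occurrences weighted by
tolerance–occupancy correlation, samples imperfect detections per
design, and tests composition shifts with a summed likelihood-ratio
statistic against a site-permutation null (an `mvabund`-style test,
re-implemented).

## Worked example

Simulate a survey from known community parameters, fit the augmented
MSOM, and read off detection-corrected richness:

```r
library(msompower)

hp     <- community_hyperparams(mu_lpsi = -1, sigma_lpsi = 1.2,
                                mu_lp = 0, sigma_lp = 1)
design <- survey_design(n_sites = 40, replicates_per_visit = 3,
                        n_taxa_true = 80)
params <- draw_community_params(hp, 80, seed = 11)
survey <- simulate_dataset(params, design, seed = 12)
survey
#> Detection dataset (presence_absence): 40 site visits x 3 replicate slots x 80 taxa
#>   120 sampled visit-replicates; 0 occupancy / 0 detection covariate(s)
#>   observed richness: 79 taxa detected

fit <- fit_msom(survey, mcmc_control(n_chains = 2, n_iter = 4000,
                                     n_burnin = 1500, thin = 5), seed = 13)
fit
#> Community occupancy fit: 2 chain(s) x 500 kept draws; 80 data taxa; M = 160
#>   observed richness 79; posterior gamma 86.6 [80, 97]

g <- estimate_gamma(fit)
percent_increase(g$mean, g$observed)
#> [1] 10

subset(summary(fit), parameter %in% c("mu_lpsi", "sigma_lpsi", "gamma"))
#>   parameter    mean     sd  lower  upper  rhat converged
#>     mu_lpsi -1.2696 0.2156 -1.738 -0.894 0.999      TRUE
#>  sigma_lpsi  1.4251 0.2096  1.070  1.873 1.000      TRUE
#>       gamma 86.5750 4.2523 80.000 97.000 1.000      TRUE
```

The survey observed 79 of 80 taxa, and the model's posterior for gamma
(mean 86.6, 95% interval [80, 97]) correctly brackets the truth while
estimating that detection error hid about 10% of the community — the
same arithmetic that turns an observed richness of 74 families into a
corrected estimate of 95 (`percent_increase(95, 74)` → 28%).

A monitoring power curve for a genus-level metabarcoding design:

```r
tax <- make_taxonomy(120, 40, seed = 1)
psi <- plogis(rnorm(120, -1.5, 1.2))
res <- power_curve(psi,
                   data.frame(n_sites = 12, replicates = 3,
                              approach = "DNA_genus"),
                   severities = c(0, 0.2, 0.4, 0.7),
                   taxonomy = tax, n_sim = 100, seed = 99)
res$minimum_detectable   # severity where power crosses 0.5
```

`run_simulate()` / `run_fit()` / `run_diversity()` / `run_power()` (and
the thin `inst/scripts/msompower` wrapper) drive the same stages from
YAML configs, writing CSV/JSON outputs plus a reproducibility manifest.

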