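# wingcontrast

Tools for asking whether conspicuously contrasting **ventral wing patterns**
in birds track ecological traits that raise the risk of in-flight collisions
— large body mass, colonial breeding, big flocks — while properly accounting
for shared ancestry. The package is aimed at comparative biologists who need
the full chain: scoring wing images, aggregating human scorer panels,
assembling trait tables, and fitting Bayesian phylogenetic mixed models over
a set of candidate trees.

## What it computes

**Contrast of a wing image** is the RMS contrast — the sample standard
deviation of the grey values of the wing's pixels after background removal
(alpha mask or chroma key) and greyscale conversion:

    RMS = [ 1/(n-1) * sum_i (x_i - mean(x))^2 ]^(1/2)

**Manual contrast scores** come from a panel of S scorers (30 in the
standard protocol), each classifying every image as contrasting or not; an
image's score is its count of contrasting votes (0..S), and a species' score
is the mean over its images.

**The comparative model** is a phylogenetic Gaussian mixed model

    y = X beta + u + e,   u ~ N(0, s2_p * V),   e ~ N(0, s2_e * I)

with V the (unit-height-scaled) phylogenetic covariance matrix, fitted by a
parameter-expanded Gibbs sampler with the standard weakly informative priors
(residual: V = 1, nu = 0.002; phylogenetic: V = 1, nu = 1, alpha prior
N(0, 1000)) and a 75 000-iteration / 7500 burn-in / thin-40 default chain.
Phylogenetic signal is reported as the posterior mean of
`lambda = s2_p / (s2_p + s2_e)`; phylogenetic uncertainty is absorbed by
fitting the identical model on k trees and averaging posterior summaries.
A profiled-GLS maximum-likelihood fit is included as an independent
cross-check of the sampler.

A synthetic-data generator produces every input — Yule trees (plus
age-jittered variants standing in for a posterior tree set), traits evolved
on the tree, Gaussian responses with chosen coefficients and signal,
patchwork wing images with truth labels, and scorer panels — so the whole
pipeline is testable with known ground truth. The methods vignette
(`vignettes/wingcontrast-methods.Rmd`) documents the model, priors,
conventions and limitations.

## Worked example

```r
library(wingcontrast)

# a 300-species dataset with known ground truth
spec <- simulation_spec(n_species = 300, n_missing = 30, n_museum = 100,
                        n_museum_missing = 5, n_trees = 4,
                        lambda_true = 0.77, s2_total = 25)
ds <- simulate_dataset(spec, seed = 42, images = FALSE)

flt <- filter_missing(ds$traits)
des <- build_design(flt$table, response = "manual")
trees <- lapply(ds$trees, match_tree_species,
                species_id = des$species_id, prune = TRUE)
avg <- fit_tree_set(des$y, des$X, trees, k = 3,
                    schedule = mcmc_schedule(15000, 1500, 10, seed = 42),
                    seed = 42, species_id = des$species_id)
print(avg)
```

```
Model averaging over 3 trees
                 coef post_mean     se    pMCMC     ess
1         (Intercept)    9.0305 1.9481 0.001481   57.79
2           nocturnal   -7.1925 0.8611 0.001481 1314.73
3            colonial    1.0024 0.5021 0.050370 1350.00
4          log_mass_c    1.0560 0.3151 0.002469  962.09
5         log_flock_c   -0.1220 0.1938 0.520988 1319.00
6         sqrt_pred_c   -0.1113 0.4401 0.790617 1283.83
7 colonial:log_mass_c    0.5951 0.3679 0.102222 1151.72
mean lambda = 0.764
```

The simulation truth was intercept 10.276, nocturnal -7.241, colonial 0.789,
log mass 0.700, log flock 0.107, sqrt predators 0.138, interaction 0.973,
with phylogenetic signal 0.77. At 270 retained species every posterior mean
sits near its truth, the strong effects (nocturnal, mass) come out with
small pMCMC, and the recovered signal (0.764) is close to the generating
0.77. `ess` is the effective sample size of each coefficient's chain (the
intercept mixes slowest because it competes with the phylogenetic random
effect); `se` is the mean per-model posterior standard deviation.

## The analysis workflow

`analysis/` holds numbered drivers that rerun the whole study on a
full-scale synthetic dataset (1980 species, 682 museum images, 30 scorers,
10 candidate trees): `01_simulate_data.R`, `02_score_images.R`,
`03_prepare_traits.R`, `04_fit_models.R`, `05_validation_regression.R`.
Each writes its tables under `results/` (bulky intermediates go to
`scratch/`). Run them in order with `Rscript`.

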