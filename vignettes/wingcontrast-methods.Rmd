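---
title: "Methods: ventral wing contrast and its ecological correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ventral wing contrast and its ecological correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingcontrast)
```

## The problem

Many birds display strongly contrasting colour patterns on the underside of
their wings — patterns visible mainly in flight, against the sky. One
functional hypothesis is collision avoidance: large-bodied and
colonial-breeding species, which face the greatest risk of in-flight
collisions, should benefit most from being conspicuous to birds flying
nearby. Testing this requires (i) a defensible species-level measure of
ventral wing contrast and (ii) a comparative model that respects the
non-independence of related species.

`wingcontrast` implements both measurement routes and the comparative model,
together with a synthetic-data generator that produces every input with
known ground truth, so the entire pipeline can be verified end to end
without museum images or published trees.

## Measuring contrast

**RMS contrast.** For a wing image, the background is removed (alpha channel
when present, otherwise chroma keying with Euclidean RGB distance, default
tolerance 10 on the 0–255 scale), the image is converted to greyscale, and
the contrast is the sample standard deviation of the wing pixels' grey
values,

$$\mathrm{RMS} = \left[\frac{1}{n-1}\sum_{i=1}^n (x_i - \bar x)^2\right]^{1/2}.$$

Three conventions are fixed because the statistic is scale-dependent:

* greyscale uses ITU-R BT.601 luma weights (0.299, 0.587, 0.114), carried as
  real values without re-quantization; the weights are a declared,
  configurable convention — any fixed luma choice works, but it must be
  stated;
* grey values live on 0–255, so RMS is in grey-value units on that scale;
* a perfectly uniform wing has RMS 0; its log-scale value is
  `log(rms + 1e-6)` with a warning, keeping such species in log-scale models
  rather than silently dropping them.

When a species has several images, per-image RMS values are averaged
*before* the log transform, mirroring how manual scores are averaged at the
species level.

**Manual scores.** A panel of S scorers (30 in the standard protocol) each
classifies every image as contrasting or not. The image score is the *count*
of contrasting votes (0..S) — means and ranges reported for such panels are
on the count scale — with a proportion accessor for convenience. Species
scores are arithmetic means over the species' images. Ragged panels are
rejected rather than imputed: the protocol is a complete design, and silent
imputation would change the score's meaning.

## The trait table

Five ecological predictors enter the model: body mass (g), flock size,
coloniality (0/1, baseline non-colonial), number of sympatric avian
predators, and activity time (0/1, baseline diurnal). Species with any
missing trait (or a missing response) are removed before modelling. Mass and
flock size are log-transformed, the predator count square-root-transformed;
all continuous predictors are centred *after* filtering (the centring
offsets are recorded so raw values can be reconstructed), and the model
includes a coloniality × log-mass interaction.

Logs are natural logarithms — the base is not a mathematical necessity, but
slope magnitudes are only interpretable once it is fixed, so it is recorded
in the design metadata. Variance inflation factors are computed on the main
effects only: an interaction built from centred components inflates VIF
mechanically without indicating genuine collinearity.

## The phylogenetic mixed model

The response for species $i$ is modelled as

$$y = X\beta + u + e, \qquad u \sim N(0,\, \sigma^2_p V), \qquad
  e \sim N(0,\, \sigma^2_e I),$$

where $V$ is the phylogenetic covariance matrix: $V_{ij}$ is the shared
root-to-tip path length of species $i$ and $j$, scaled to unit diagonal
(trees are normalised to unit height so variance components are comparable
across trees of different depths; polytomies are accepted).

**Priors.** Residual variance: inverse-Wishart with $V = 1$, $\nu = 0.002$
(weakly informative). Phylogenetic variance: parameter-expanded — the random
effect is written $u = \alpha g$ with $g \sim N(0, \sigma^2_g V)$ and a
working scale $\alpha \sim N(0, 1000)$, with $V = 1$, $\nu = 1$ on
$\sigma^2_g$. The expansion keeps the chain mixing when the variance
component is near zero, where a plain inverse-gamma sampler sticks.

**Sampler.** All full conditionals are conjugate, so the model is fitted by
Gibbs sampling with no tuning parameters: the fixed effects and $\alpha$
have Gaussian conditionals, the variance components inverse-gamma
conditionals, and the phylogenetic effects are updated in the eigenbasis of
$V$, where their joint conditional has a *diagonal* precision
$\alpha^2/\sigma^2_e + 1/(\lambda_i \sigma^2_g)$ — one eigendecomposition
per fit, no per-iteration factorization. Eigenvalues are floored at 1e-10,
which also accommodates the zero eigenvalues polytomies and star trees
produce. The default schedule is 75 000 iterations, 7500 burn-in, thinning
40 (1687 retained draws); chains are bit-reproducible under a seed.

**Reported quantities.** Per coefficient: posterior mean, 95% highest
posterior density interval (a quantile-interval flag exists; HPD is the
default because variance-adjacent quantities are skewed), posterior sd,
pMCMC ($2\min(\Pr(\beta>0), \Pr(\beta<0))$, floored at $1/n$ per tail,
capped at 1), and effective sample size
($n / (1 + 2\sum_k \hat\rho_k)$ with initial-positive-sequence truncation:
autocorrelations are summed in consecutive pairs until a pair sum goes
negative).

**Phylogenetic signal.** Pagel's λ is reported as the phylogenetic
variance fraction $\sigma^2_p / (\sigma^2_p + \sigma^2_e)$ computed per
retained draw and averaged — the heritability-style quantity animal-model
users report as λ. A profiled-GLS maximum-likelihood estimate over a λ grid
(`fit_gls`, error covariance $\lambda V + (1-\lambda) I$) is exposed as an
independent cross-check; the two agree closely on simulated data and the
GLS route doubles as the oracle in the test suite.

**Tree averaging.** Phylogenetic uncertainty is absorbed by fitting the
identical model on k trees sampled without replacement from a candidate set
and averaging posterior means, pMCMC and λ arithmetically. The reported
"s.e." is the mean of per-model posterior standard deviations — a
definition recorded in metadata because averaged summaries do not have a
unique standard error. Per-tree seeds derive deterministically from the
master seed, so a tree-set fit is reproducible end to end.

**Validation regression.** The manual score is regressed on the
standardized log RMS score with the same phylogenetic random effect. The
reported fit quality is a Bayesian marginal R²: per retained draw,
$\mathrm{Var}(X\beta) / (\mathrm{Var}(X\beta) + \sigma^2_p + \sigma^2_e)$,
averaged over draws — the variance explained by the fixed effect against
all model variance, which is the quantity a simple-regression R² estimates
when the random effect is negligible.

## What the synthetic generator emulates

The generator produces, from a single master seed: a candidate tree set —
one base Yule (pure-birth) tree plus variants with lognormally jittered
node ages (topology and ultrametricity preserved), because a posterior tree
sample consists of correlated estimates of one phylogeny, and a set of
*unrelated* random trees would destroy the signal any single-tree response
carries; traits (log mass evolves by Brownian motion on the tree
by default, so predictors themselves carry phylogenetic signal — the
confounding real comparative data face; an iid mode exists for clean unit
tests); coloniality optionally mass-dependent on the logit scale (default
slope 0, keeping recovery tests unconfounded); a Gaussian response drawn
from exactly the model above with chosen $\beta$, λ and total variance;
elliptical patchwork wing images on a key-colour background whose truth
label follows the "two or more colours, each above 5% of patches" rule; and
a scorer panel whose votes flip the truth independently with a set error
rate.

Default counts mirror the study scale — 1980 species, 200 with missing
traits, 682 with museum images of which 17 incomplete (665 retained), 30
scorers — and every count is a parameter so tests can shrink. Default
response parameters are the study-scale values (total variance 25,
phylogenetic fraction 0.77, Table-style coefficients); trait distributions
(geometric-mean mass 100 g with log-sd 1.5, log-normal flock sizes, Poisson
predator counts with mean 30, 5% nocturnal, 25% colonial) are chosen once
as realistic for a broad bird assemblage.

What it does **not** emulate: real wing shapes or taxonomic structure, the
empirical score distribution, eBird-derived flock sizes, or observation
error in the traits. Passing recovery tests therefore demonstrates that the
pipeline estimates what it claims under its own assumptions — not that
those assumptions hold for any particular real dataset.

## Numerical and test-design choices

* Yule trees come from a constant-rate simulator conditioned on the tip
  count; tests assert determinism, exact tip counts, ultrametricity and the
  scaled-covariance range rather than a closed-form root-depth law, which
  differs under tip-count conditioning.
* Monte-Carlo test sizing: the end-to-end recovery check pools interval
  coverage over runs × coefficients (threshold 0.90, with a 0.80
  per-coefficient floor). At 50 replicates a per-coefficient 0.90 threshold
  sits inside the binomial noise of the true ≈0.94 coverage and would fail
  sporadically with correct code; pooling makes the check sharp without
  loosening it.
* Replicate simulations must not share RNG streams: each dataset is drawn
  from one seeded stream rather than from consecutive per-stage seeds,
  which would make "independent" replicates overlap.
* Degenerate inputs: all-background images, sub-2-pixel masks, ragged vote
  panels, non-positive masses under the log, single-species designs,
  perfectly collinear predictors and constant chains all raise explicit
  errors or warnings rather than propagating silently.

## Limitations

Gaussian response only (scores are treated as continuous); single
phylogenetic random effect; no inter-rater reliability statistics; no
avian-vision (tetrachromatic) colour modelling; no automatic wing
segmentation for cluttered field photographs — field images are the manual
panel's job. Problem sizes in the shipped tests (80–682 tips, chains of
2500–15 000 iterations) are the package's chosen verification scale;
study-scale runs use the 75 000-iteration default schedule.
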