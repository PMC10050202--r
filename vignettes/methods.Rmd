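---
title: "Methods: functional spectra of life-history strategies and their erosion under extinction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional spectra of life-history strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The question

Turtles, tortoises and crocodilians are among the most threatened vertebrate
clades. Their life-history strategies — the trade-offs between survival,
development and reproduction — can be summarised in a low-dimensional
"functional space", and the extent of that space occupied by extant species is
a measure of functional diversity. `funspectra` asks: how much of that
occupied space would disappear if the threatened species actually went
extinct, and is that loss larger than expected if extinction struck species at
random?

The pipeline has six stages, each usable on its own:

1. **Phylogenetic comparative tools** — Brownian covariance `C` from a tree,
   Pagel's λ by profile maximum likelihood, PGLS residuals, and a
   Kruskal–Wallis test of whether missingness tracks threat status.
2. **Imputation** — chained-equations predictive mean matching (PMM) with
   phylogenetic eigenvector covariates; 40 independently seeded completed
   datasets.
3. **Ordination** — phylogenetic PCA (pPCA) of six log/logit-transformed,
   body-mass-corrected traits, with Kaiser/varimax retention and pooling of
   scores and loadings across the 40 imputations.
4. **Trait probability density (TPD)** — per-species Gaussian kernels with an
   unconstrained plug-in bandwidth on a fixed 200×200 grid, thresholded to the
   99% highest-density region (HDR).
5. **Extinction scenarios** — cumulative IUCN removals (−CR, −EN, −VU, −NT)
   and per-threat removals, each against a 999-iteration random-removal null
   envelope.
6. **Risk surfaces** — binomial GAM smooths of P(high-risk) or P(affected by
   a threat) over the two ordination axes.

# Models and assumptions

## Trait evolution and Pagel's λ

A trait `y` (log scale; logit for yearly survival probabilities) is modelled
as multivariate normal with mean `μ1` and covariance `σ² C(λ)`, where
`C[i,j]` is the depth of the most recent common ancestor of tips `i` and `j`
and `C(λ)` multiplies the off-diagonal entries by `λ ∈ [0, 1]`. `fit_lambda()`
profiles `μ` and `σ²` analytically and maximises over `λ` with Brent search
(tolerance 1e-6); the SE comes from the numerical curvature of the profile
log-likelihood. Non-ultrametric trees are accepted — nothing in the algebra
requires equal root-to-tip distances. Near-singular covariances (effectively
duplicated tips) receive a relative jitter of 1e-10 on the diagonal, with a
message.

With a single trait and ~300 tips, the sampling SD of `λ̂` at intermediate
true values is about 0.09; boundary values (0 and 1) are recovered almost
exactly. Tests of recovery rates are designed around that precision.

## Imputation model

Each incomplete variable is regressed, on its modelling scale, on all other
traits plus `k = min(15, n/10)` eigenvectors of the double-centred Brownian
covariance; closely related species share eigenvector loadings, which is how
phylogeny informs the fill-ins. Parameters are drawn from their Bayesian
posterior each sweep (a small relative ridge stabilises collinear designs),
and each missing cell takes the *observed* value of one of 5 donors nearest
in predicted-mean space — so imputed values are always actually observed
values and ranges are preserved by construction. The chain runs 15 sweeps,
visiting variables in order of increasing missingness. Forty independently
seeded single-imputation chains (seeds `master + 1 … master + 40`) quantify
imputation uncertainty by between-dataset variation; with no gaps the chains
are identical and the pooling SE is zero.

Two diagnostics are provided: the overlap coefficient between observed-value
and imputed-value kernel densities per trait, and a symmetric Procrustes
statistic between the ordination of the fully imputed data and that of a
low-imputation subset.

## Ordination

`preprocess_traits()` maps each focal trait to its modelling scale, estimates
that trait's λ, takes PGLS residuals against log body mass with error
covariance `C(λ̂)` (removing allometry so the axes express strategy, not
size), and z-transforms. `ppca_fit()` then estimates a joint λ for the whole
trait matrix by matrix-normal profile likelihood, computes the evolutionary
covariance around the GLS phylogenetic mean, converts it to a correlation
matrix, and eigendecomposes. On a star phylogeny this reduces exactly to
ordinary correlation PCA — a property the test suite checks at 1e-8.

Axis signs are arbitrary in any PCA; we fix them so maximum lifespan loads
positively on PC1 (the fast–slow continuum points toward long-lived species)
and clutch size loads positively on PC2 (the reproductive-strategy axis
points toward large clutches). Components with eigenvalue > 1 (Kaiser, on the
correlation scale) are varimax-rotated and reported, but the TPD space always
uses the two *unrotated* leading components: the variance fractions quoted
for the two axes refer to principal axes, and a two-dimensional spectrum is
what the downstream extinction machinery assumes. Pooling across the 40 fits
aligns axes by maximal absolute loading correlation (sign-flipping as
needed; ties broken by original order) and averages element-wise, with
SD/√40 as the pooling uncertainty.

A pattern worth knowing: per-trait λ estimated on observed cells is high
(≈0.75–0.9 in the default synthetic world), while the pooled joint λ of the
ordination is lower (≈0.67). Imputation noise attenuates cross-species
resemblance, and pooling inherits that attenuation; the same raw-versus-
pooled gap appears in real analyses of this kind.

## TPD functional space

Every species contributes a bivariate normal kernel centred on its (PC1, PC2)
position, all sharing one bandwidth matrix `H`. `select_bandwidth()` is an
unconstrained plug-in selector: the data are pre-sphered, the five
fourth-order integrated density-derivative functionals are estimated with an
isotropic normal-scale pilot (`g = n^{-1/8}` on the sphered scale), the
asymptotic MISE of a full Gaussian `H` is minimised numerically, and the
result is conjugated back. For a standard normal sample this lands on the
`n^{-1/3}` reference scaling; it is exactly scale-equivariant and
rotation-equivariant up to optimiser tolerance. The single-stage pilot is
conservative on strongly multimodal clouds (it oversmooths relative to
per-cluster scale); life-history spaces are single dense clouds, where it is
well behaved. Collinear point sets fall back to a diagonal normal-reference
rule with a warning.

The grid spans the data range padded by `3·sqrt(max eigenvalue of H)` per
side, with 200 equal cells per dimension (40,000 cells). Kernels are
evaluated at cell centres (midpoint rule) and the summed density is
renormalised to integrate to exactly 1, absorbing both quadrature error and
tail truncation. The 99% HDR threshold keeps the smallest set of
highest-density cells reaching 99% of mass (ties broken by cell index),
zeroes the rest, and renormalises; quantile contours at 50–99% are nested by
construction. Functional richness is occupied-cell count × cell area.

Critically, **bandwidth and grid are computed once from the full species set
and reused for every scenario subset**. "Cells becoming empty" is only
well-defined cell-by-cell on a shared grid; per-subset re-selection is
possible via the exposed arguments but is not the default.

## Extinction scenarios and the null model

IUCN scenarios are cumulative (−CR ⊆ −EN ⊆ −VU ⊆ −NT); Data Deficient and
unassessed species are never removed. Threat scenarios remove all flagged
species (`_all`) or only flagged CR/EN/VU species (`_threatened`). IUCN
scenarios run on the pool of IUCN-assessed species; threat scenarios on the
pool with known threat flags. Loss is the percentage of baseline-occupied
cells (after the 99% threshold) that are unoccupied in the reduced TPD —
an occupancy-mask difference, not an integrated density difference. The null
model removes the same number of species uniformly at random, 999 times, and
reports the 5th/50th/95th percentiles (linear interpolation). The
randomisations are computed as chunked indicator-matrix products against a
precomputed species × cell kernel matrix, which keeps a full 16-scenario run
with 999 nulls each to roughly a minute at 259 species.

## Risk surfaces

`fit_risk_surface()` wraps a binomial GAM with a 2-D thin-plate penalized
spline over (PC1, PC2). The smoothing parameter is chosen by REML — we
prefer it to GCV because REML-selected smooths give better-calibrated
smooth-term p-values, and the test suite checks that null-label p-values are
approximately uniform. The smooth-term test is the Wald-type test reported
by the GAM machinery (chi-square scale, reference df from the smooth).
Published χ² values for comparable models are displayed for context in the
README but are never used as test expectations: they depend on the specific
smoothing-parameter path and p-value approximation of the original software
configuration. Confidence bands are computed on the link scale and mapped
through the inverse logit, so they always bracket the estimate and stay
inside (0, 1); prediction cells outside the convex hull of the data are
flagged as extrapolated.

# The synthetic study system

`sim_config()` defaults define a world with the statistical structure of the
real chelonian/crocodilian dataset:

* **Phylogeny:** birth–death tree conditioned on 259 extant tips (birth 1,
  death 0.3), rescaled to unit height so Brownian rates read as tip-level
  variances.
* **Traits:** each of nine traits (six focal + mass, size, incubation) is
  Brownian with λ = 0.85 — "strong signal", matching per-trait estimates
  above 0.8 on real data. Body mass is generated first; other traits add an
  allometric term on centred log mass (e.g. clutch size slope 0.45, maturity
  0.25). Beyond allometry, two latent Brownian factors induce the two axes
  life-history theory expects: a *pace* factor loading on survival, lifespan
  and maturity, and a *clutch-frequency vs clutch-size trade-off* factor.
  Loadings are normalised so every trait's marginal covariance is exactly
  `σ² C(λ)` — the factor structure changes correlations, not marginals. With
  these defaults the complete-data ordination shows PC1 ≈ 39%, PC2 ≈ 21%,
  between-world spread of several points.
* **Status and threats:** species are ranked by a latent logistic risk score
  (intercept 0, +0.8·PC1, −0.4·PC2, plus standard logistic noise) and IUCN
  categories are filled by quota — 46 CR, 36 EN, 49 VU, 25 NT, 51 LC, 7 DD,
  45 unassessed, scaled proportionally for other world sizes. This is an
  ordinal logistic model calibrated to fixed margins: the published category
  *counts* are treated as study conditions, while *which* species fall in
  each category follows the trait–risk association. Six threat flags are
  independent Bernoulli draws; only local consumption, invasive/disease and
  pollution depend on trait-space position, matching the reported pattern
  that the other three threats strike independently of strategy. Eight
  species get unknown flags; continents are filled by quota with fixed
  per-continent sizes and threatened fractions (Asia 66 species, 83%
  threatened, etc.), with 14 species of unknown continent.
* **Missingness:** each maskable cell (everything except mass and size) is
  masked with probability `logistic(logit(0.38) + 0.3·threatened)` — 38%
  baseline with a mild extra risk for threatened species, reproducing the
  reported borderline association between gaps and threat status. This is
  missing-at-random given threat status; the mechanism of the real data is
  uncharacterised beyond that association, so recovery results here certify
  the machinery under MAR, not the real-world mechanism.

What the generator does **not** emulate: measurement error within species,
the geography of ranges (continent is a label, not a range), threat
interactions, and the particular geometry of the real species cloud. That
last point matters for interpretation: quantities that depend on the exact
cloud and threat placement — hotspot concentration, per-scenario loss
percentages — vary by several points from world to world and are *not*
expected to match published values from the real dataset; the tests that
compare them document this. Quantities anchored by the generator's
conditions (category counts, pool sizes, continent composition, two-axis
structure, strong λ) do match.

# Numerical choices and edge cases

* Cholesky solves everywhere, with a 1e-10 relative jitter fallback.
* The pPCA profile likelihood clamps eigenvalues of the plug-in covariance
  at 1e-12 of the largest, so duplicated traits do not break the λ search;
  a genuinely constant trait column is an error.
* HDR ties are broken by row-major cell index; `q = 1` keeps every
  positive-density cell.
* PMM with a variable that has no observed values errors naming the
  variable; a fully observed table passes through unchanged.
* All stage seeds derive from one master seed by fixed offsets (generator
  stages `+0…+3`, imputation `+1000 + chain`, scenarios `+2000 + index`), so
  a rerun reproduces every artifact bit-for-bit.
* Default problem sizes for the full analysis (259 species, 40 imputations,
  200×200 grid, 999 nulls) complete in about two minutes on one CPU; unit
  tests use smaller worlds (40–120 species, 40–60 cells per dimension,
  29–199 nulls) chosen to keep each property check sharp but cheap.

# Known limitations

* λ > 1, Ornstein–Uhlenbeck or early-burst models are out of scope; so are
  ancestral-state reconstruction and >2-D TPD spaces.
* The risk-surface χ²/p values are approximation-dependent; only their
  calibration (uniform under null) and power (small under strong signal) are
  guaranteed, not agreement with any particular published statistic.
* The loss metric counts emptied cells of the thresholded baseline; an
  integrated-density alternative would weight cells by mass and generally
  give smaller losses. The thresholded-occupancy version is the default
  because "cells become empty" is the published definition of the quantity.
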