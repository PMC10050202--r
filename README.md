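# funspectra

Functional spectra of life-history strategies — and how extinctions of
threatened species erode them.

`funspectra` is an R package for conservation-oriented comparative
demography, built around turtles, tortoises and crocodilians (Testudines and
Crocodilia) but applicable to any clade with a phylogeny, a species × trait
table, and IUCN-style metadata. It answers two questions:

1. **What does the functional space of a clade look like?** Six life-history
   traits — adult survival *Sa*, juvenile survival *Sj*, maximum lifespan
   *ML*, age at sexual maturity *Lα*, clutches per year *CN*, clutch size
   *CS* — are log/logit-transformed, corrected for body-mass allometry with
   phylogenetic regression, and ordinated with a phylogenetically informed
   PCA (pPCA). PC1 is the *fast–slow continuum*; PC2 the *reproductive
   strategy* (clutch frequency vs clutch size) axis. A trait probability
   density (TPD) — the normalised sum of per-species Gaussian kernels

   *TPD(x) = (1/S) Σₛ N(x; μₛ, H)*,

   with an unconstrained plug-in bandwidth **H** on a fixed 200 × 200 grid,
   thresholded to its 99% highest-density region — describes the occupied
   spectrum, and the area of the occupied region measures functional
   richness.

2. **How much of that space do we lose under extinction scenarios?**
   Cumulative IUCN removals (−CR, −EN, −VU, −NT) and per-threat removals are
   replayed on the shared grid; the loss is the percentage of
   baseline-occupied cells left empty. Each scenario is compared against a
   999-iteration null in which the same number of species is removed at
   random: losses beyond the null's 95th percentile mean the removed species
   carried *unique* strategies, losses inside it mean their strategies were
   redundant.

Because real trait tables are gappy (~38% missing in this clade), the
pipeline includes phylogenetically informed multiple imputation:
chained-equations predictive mean matching with phylogenetic eigenvector
covariates, 40 independently seeded completed datasets, and pooling of the
ordination across them. Pagel's λ — the off-diagonal multiplier of the
Brownian covariance, 0 = no phylogenetic signal, 1 = full Brownian
expectation — is estimated per trait and jointly in the pPCA. Binomial GAM
surfaces map P(high-risk) and P(affected by each threat) over the two axes.

A first-class synthetic-data generator (`sim_config()`,
`simulate_dataset()`) reproduces the statistical structure of the real study
system — 259 species, birth–death phylogeny, traits with strong signal
(λ = 0.85), a pace factor and a clutch trade-off factor, published IUCN
category counts (46 CR / 36 EN / 49 VU / 25 NT / 51 LC / 7 DD / 45
unassessed), threat flags, continents, and biased missingness — so every
stage is testable without the original data files.

## Worked example

```r
library(funspectra)

res <- run_pipeline(config = sim_config(seed = 1), n_iter = 999)
print(res)
```

```
<fs_pipeline> 259 species; 40 imputations
  PC1 38.3% PC2 25.1% ; pooled lambda 0.672 
  hotspot: 56.4 % of species in 18.4 % of spectrum
  -CR: loss 6.6% (null 5.1 [1.1, 10.5])
  -EN: loss 12.3% (null 9.3 [3.9, 16.1])
  -VU: loss 20.5% (null 17.0 [9.5, 25.5])
  -NT: loss 30.2% (null 23.0 [14.3, 32.4])
```

Reading this output: the two leading axes carry 38.3% and 25.1% of trait
variance — the two-axis structure life-history theory predicts — with a
pooled phylogenetic signal of 0.672. Over half the species crowd into a
hotspot covering 18% of the occupied spectrum (high functional redundancy).
Losing all Critically Endangered species (−CR, 46 species) would erase 6.6%
of the spectrum, within the random-removal envelope for this simulated
world; the cumulative scenarios erode up to 30% of the spectrum by −NT. In
the real clade the observed losses sit *above* the envelope because
threatened species there hold unusually distinct strategies — exactly the
comparison the null model is built to expose.

Each piece is available on its own and returns a tibble or a tidy-able
object:

```r
sim   <- simulate_dataset(sim_config(n_species = 100, seed = 7))
lam   <- trait_lambda(sim$traits, sim$tree)          # per-trait Pagel's lambda
iset  <- impute_traits(sim$traits, sim$tree)          # 40 completed datasets
ord   <- run_ppca(iset, sim$tree)                     # pooled pPCA
glance(ord)                                           # lambda, variance, axes
bw    <- select_bandwidth(ord$space)
grid  <- build_grid(ord$space, 200, 3, bw)
tpd   <- hdr_threshold(tpd_density(ord$space, bw, grid), 0.99)
autoplot(tpd)                                         # spectrum + contours
scen  <- run_scenarios(ord$space, sim$meta, n_iter = 999, seed = 1)
autoplot(scen)                                        # losses vs null envelopes
surf  <- fit_risk_surface(ord$space,
                          sim$meta$iucn %in% c("CR", "EN"))
smooth_term_test(surf)                                # chi2, edf, p
autoplot(surf)                                        # risk map over the axes
```

For comparison, published analysis of the real 259-species
chelonian/crocodilian dataset reports: PC1 = 39.1%, PC2 = 23.1%, pooled λ = 0.674 ± 0.030,
a hotspot holding 50% of species in 13.2% of the spectrum, a −VU loss of
26.8%, and a −CR loss of 12.67% against a null median of 3.82% — and GAM χ²
statistics of 28.59 (extinction risk), 27.36, 25.92 and 19.22 (threat
models). Quantities pinned by the generator's design (counts, pools,
continent composition, axis structure, λ) are reproduced by the synthetic
world; quantities that depend on the exact geometry of the real species
cloud (hotspot concentration, per-scenario loss magnitudes, χ² values) are
not, and the methods vignette explains why.

## Package layout

| | |
|---|---|
| `R/synthetic.R` | synthetic world: tree, traits, missingness, status/threats |
| `R/phylo.R` | Brownian covariance, Pagel's λ, PGLS, missingness test |
| `R/impute.R` | phylogenetic eigenvectors, PMM chains, diagnostics |
| `R/ppca.R` | preprocessing, pPCA, Kaiser/varimax, pooling |
| `R/tpd.R` | bandwidth, grid, TPD, HDR threshold, contours, hotspot |
| `R/extinction.R` | scenarios, losses, null envelopes, continent table |
| `R/surface.R` | binomial GAM risk surfaces |
| `R/pipeline.R` | `run_pipeline()` orchestration and artifact export |
| `vignettes/methods.Rmd` | the model, assumptions, tuning parameters, limits |
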