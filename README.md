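# phylospread

Post-processing, simulation and hypothesis testing for **continuous
phylogeographic** reconstructions. Bayesian continuous phylogeography (as run
in BEAST with relaxed-random-walk diffusion models) produces posterior
samples of time-scaled trees whose every node carries geographic
coordinates. `phylospread` takes those trees and answers the questions
molecular epidemiologists ask next: how fast and how far did lineages
disperse, how uncertain are the reconstructed locations, and did
environmental factors shape the spread?

The package is organised around one intermediate object: every posterior
tree is decomposed into an **extraction table** in which each row summarises
one phylogenetic branch as a movement vector — start/end calendar times,
start/end locations, duration and great-circle displacement. All analyses
consume these tables.

## What it computes

**Lineage dispersal statistics** (per posterior tree, summarised as median +
HPD across trees):

- weighted lineage dispersal velocity
  `v = Σᵢ dᵢ / Σᵢ tᵢ` (km/yr), where `dᵢ` and `tᵢ` are the displacement and
  duration of branch `i`;
- weighted diffusion coefficient
  `WDC = Σᵢ dᵢ² / (4 Σᵢ tᵢ)` (km²/yr), the duration-weighted version of the
  per-branch 2-D diffusion estimator `Dᵢ = dᵢ²/(4tᵢ)` — unlike the velocity,
  the WDC is robust to sampling intensity;
- the coefficient of variation of `Dᵢ` across branches (diffusion
  heterogeneity), isolation-by-distance correlations (geographic vs
  patristic distance over tip pairs), and the maximal wavefront distance
  from the epidemic origin through time.

**Uncertainty visualisation layers**: kernel-density HPD polygons per MCC
internal node (TreeAnnotator-style annotations) or per time slice pooled
across posterior trees, exported as GeoJSON.

**Spatially explicit simulators**: Brownian (BRW) and relaxed (RRW) random
walks along fixed trees or birth–death trees, optionally with barriers
(masked raster cells) or with dispersal velocity modulated by an
environmental raster. A branch of duration `t` draws an isotropic bivariate
normal displacement with per-axis variance `σ₀² t ψ` (`ψ` a mean-1 gamma
scaler under RRW), so `E[d²/(4t)] = σ₀²/2`.

**Landscape hypothesis tests** built on tree-branch randomisation nulls:
branch durations are regressed on environmental path distances (straight
line, least cost, or circuit-style commute time on the raster lattice) under
a rescaling ladder `1 + k·v/vmax`, giving the statistic
`Q = R²_env − R²_null`; support is summarised as
`BF = p/(1−p)` where `p` is the fraction of posterior trees whose observed
`Q` beats the matched randomised tree. Dispersal-location (attraction/
repulsion) and isolation-by-resistance tests follow the same scheme, and an
environmental-distance MDS transformation supports prior-informed
reanalysis in deformed space.

## Worked example

The package ships a seeded fixture generator, so the full pipeline runs
without external data:

```r
library(phylospread)

# 1. synthetic posterior (10 trees, 20 tips, known diffusivity 100 km2/yr)
fx <- file.path(tempdir(), "fixtures")
generateFixtureSuite(fx, seed = 7, scale = "small")

# 2. parse the annotated posterior and decompose into movement vectors
trees <- parseAnnotatedTrees(file.path(fx, "posterior.trees"),
                             mostRecentSamplingDate = 2020,
                             burnInFraction = 0, nToSample = 10, seed = 1)
tables <- lapply(trees, extractBranchTable)
tables[[1]]
#> ExtractionTable: 38 branches
#>   time span: 2017.1702 .. 2020.0000
#>   total lineage length: 437.37 km over 17.05 yr

# 3. dispersal statistics across the posterior
dispersalStatistics(tables, trees, mass = 0.95)
#> DispersalStatsSummary over 10 posterior trees (mass 0.95)
#>    statistic     median     hpdLow     hpdHigh
#>     velocity 24.5456848 17.9343291  28.7797778
#>          wdc 96.4454766 69.0307736 123.4013127
#>          cvD  0.9197347  0.8205061   1.1012905
#>   ibdPearson  0.4891437  0.1555179   0.6595019
#>  ibdSpearman  0.3880379  0.1155835   0.6773443

# 4. landscape test: does the west-east gradient structure diffusion?
grad <- readEnvRaster(file.path(fx, "gradient.asc"))
nulls <- lapply(seq_along(tables), function(i)
  randomizeTable(tables[[i]], grad, seed = 100 + i))
diffusionTest(tables, nulls, grad, kLadder = c(10, 100), model = "straight")[[1]]
#> QStatResult: raster 'gradient', k = 10, model = straight
#>   mean Q = 0.0013, p = 0.300, BF = 0.429
```

The recovered `wdc` median of ~96 km²/yr matches the generator's true
diffusion coefficient of 100 km²/yr (`σ₀² = 200` km²/yr per axis, `D =
σ₀²/2`). The gradient raster had no role in generating the data, and the
test finds no support (`p = 0.30`, `BF < 1`).

## Documentation

The methods vignette (`vignettes/phylospread-methods.Rmd`) describes the
models, the randomisation nulls, the numerical conventions (Earth radius,
duration clamping, commute-time scaling) and the design choices, with the
study conditions used by every simulation-based check.
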