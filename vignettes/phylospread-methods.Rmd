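---
title: "Models and methods behind phylospread"
author: "phylospread authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phylospread}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. From posterior trees to movement vectors

Continuous phylogeographic inference yields a posterior sample of rooted,
binary, time-scaled trees whose nodes carry 2-D coordinates. `phylospread`
reads the BEAST dialect of annotated NEXUS: node comments either hold a
bivariate `location={lat, lon}` annotation (BEAST stores latitude first) or
a split `location1`/`location2` pair. The parser swaps into the package's
canonical (lon, lat) order; a tree mixing both conventions is rejected
rather than guessed at. Node ages are anchored so the most recent tip sits
at the user-supplied sampling date, in decimal years.

Each tree is decomposed into an *extraction table*: one row per non-root
node, describing the branch from its parent as a movement vector. A binary
rooted tree with $n$ tips yields exactly $2n-2$ rows; the root is not given
a virtual row (there is no movement leading into it — the alternative of a
zero-length root row would only add a degenerate branch to every
statistic). Durations below $10^{-8}$ yr are clamped to $10^{-8}$ and
flagged, so velocity and diffusion ratios stay finite while the branch is
preserved.

Burn-in removal and posterior subsampling are uniform without replacement
over the post-burn-in tree indices, under a user seed, so any analysis is
reproducible from the tree file alone.

## 2. Dispersal statistics

For branch $i$ with displacement $d_i$ (great-circle km, Earth radius 6371
km; Euclidean km for projected input) and duration $t_i$:

* weighted lineage dispersal velocity $v = \sum d_i / \sum t_i$;
* per-branch diffusion coefficient $D_i = d_i^2/(4 t_i)$ and weighted
  diffusion coefficient $\mathrm{WDC} = \sum d_i^2 / (4\sum t_i)$.

The $1/4$ is the 2-D Brownian convention: a walk with per-axis variance
rate $\sigma_0^2$ has $E[d^2] = 2\sigma_0^2 t$, so $E[D_i] = \sigma_0^2/2$
— the package pins $D = \sigma_0^2/2$ and the test suite checks the mapping
numerically against the simulators. The velocity is *not* robust to
sampling intensity: denser sampling splits lineages into shorter branches
and, because $E|d| \propto \sqrt{t}$ under diffusion, summed displacement
grows. The WDC is approximately invariant because collapsing an unobserved
path into its net displacement preserves $E[d^2]/t$. The suite demonstrates
the contrast by simulating 200-tip Brownian trees and pruning each to a
random 50-tip subsample (`subsampleTips()`), the matched design for a
sampling-intensity comparison — independent trees of different sizes would
confound tree shape with sampling.

The *wavefront* series reports, on a time grid, the maximal distance from
the origin reached by any lineage up to each time: all realised branch
endpoints plus the linearly interpolated (in lon/lat) positions of branches
straddling the grid point, which keeps the front smooth between node
events. The origin defaults to each tree's own root location rather than a
pooled estimate, so posterior uncertainty in the origin propagates into the
band. The isolation-by-distance signal is the Pearson (and Spearman)
correlation between great-circle tip-pair distance and patristic duration;
distances are untransformed by default with a log–log option, since the
metric is used comparatively and the transform choice is not settled in the
literature.

Posterior summaries use one value per sampled tree — never branches pooled
across trees, which would understate between-tree uncertainty. The HPD
interval is the shortest contiguous window of the sorted per-tree values
containing $\lceil m n \rceil$ of them; the default summary mass is 0.95,
while node/slice *polygons* default to the conventional 0.80.

## 3. Credible-region polygons

`kdeHpdRegion()` estimates a Gaussian kernel density on a regular grid
(default $200\times200$) with the normal-reference (Silverman-type)
diagonal bandwidth — deterministic given the data, no tuning parameter.
The region is the smallest set of grid cells whose summed (renormalised)
density mass reaches the target: cells are sorted by density and
accumulated, which makes regions of increasing mass nested by construction.
Membership queries use the same cell set, so reported coverage is exact
with respect to the region definition; contour rings at the threshold
density are attached for export. Degenerate input (all points identical)
returns a flagged single-cell square rather than an error, since MCC trees
can carry point-mass nodes. Time-slice polygons pool internal-node end
locations only — tip locations are sampling locations, not inferences — with
a flag to include tips; slices are right-closed, cumulative by default
(successive snapshot layers), and slices with fewer than 10 pooled points
are omitted with a warning rather than producing a meaningless kernel fit.
Layers export as GeoJSON at full coordinate precision; GeoJSON was chosen
as the vector format because it round-trips losslessly through a text file.

## 4. Environmental distances

Three path models turn a raster into pairwise "environmental distances".
Rasters are first rescaled as $1 + k\,v/v_{\max}$ (resistance) or
$1 + k(1 - v/v_{\max})$ (conductance) with a default ladder
$k \in \{10, 100, 1000\}$: the ladder spans weak to strong effects and the
uniform raster of ones ($k=0$) nests the null inside the family. Each $k$
is reported separately without multiple-testing correction, mirroring the
exploratory character of raster screening; this is documented rather than
hidden.

* **straight**: exact line integral of cell values along the segment (cell
  crossings are computed analytically, lengths converted to km by
  great-circle scaling);
* **leastcost**: shortest path on the 8-connected lattice of non-masked
  cells, an edge costing the *mean* of its two cell values times the
  distance between cell centres (diagonals are naturally $\sqrt2$ longer).
  The mean rather than the sum keeps the uniform raster's cost equal to
  path length; the octile metric overestimates straight-line distance by at
  most ~8%, which the suite checks;
* **resistance**: commute-time distance on the same lattice as a resistor
  network with edge conductance $1/\text{mean resistance}$, scaled as
  $2\,|E|\,R_{\text{eff}}$ with $|E|$ the lattice edge count. On a 1-D
  chain of $m$ uniform cells this equals $2(m-1)^2\rho$, the closed form
  the tests pin. Effective resistances are computed by sparse Cholesky
  solves of the grounded graph Laplacian — no external circuit solver.

Points on masked cells are errors; pairs separated by a masking barrier get
an `Inf` sentinel, reported rather than thrown, so one disconnected pair
does not abort a posterior-wide analysis. Cell registration is half-open
floor indexing from the lower-left corner, and the value applies to the
whole cell. No reprojection is attempted: all inputs must share a CRS, and
projected (planar km) input is flagged end-to-end, switching every distance
and bearing computation to Euclidean geometry.

## 5. Simulators

All three simulators share one diffusion engine. Displacements are drawn in
km on the local tangent plane and converted to degrees — valid at the
regional extents of outbreak analyses, a documented limitation near the
poles. Per-branch variance is $\sigma_0^2\, t_i\, \psi_i\, m(x_p)$:

* $\psi_i = 1$ (BRW) or a mean-1 gamma draw with shape $\nu$ (RRW;
  variance $1/\nu$, $\nu \to \infty$ recovers BRW — the suite checks that
  branch-coefficient heterogeneity decreases monotonically in $\nu$). The
  gamma family was chosen for closed-form moments; a mean-1 lognormal is
  exposed as an option.
* $m(x_p)$ is an optional local multiplier read from a raster at the
  *parent* node position: $1/(1 + k_{\text{sim}} v/v_{\max})$ for
  resistance-type rasters, $1 + k_{\text{sim}} v/v_{\max}$ for
  conductance. Sampling the environment once per branch (not
  path-integrated) matches the branch-level variance scaling and keeps
  rejection sampling simple; with $k_{\text{sim}}=0$ the output is
  bit-identical to the unmodulated engine.

Masked cells act as barriers via rejection resampling (cap 1000 per branch,
then an error advising a smaller $\sigma_0^2$ or wider corridor). Each
branch draws from its own RNG stream derived by stable string hashing of
the node id from the root seed, so runs are reproducible regardless of
traversal order and nested configurations reuse identical draws. A
`conserveDistances` variant resamples directions only, keeping each
branch's observed displacement magnitude.

The birth–death simulator grows lineages at per-capita rates
$\lambda$ (split) and $\mu$ (death) until either $N$ extant lineages exist
or time $T$ is reached. When stopping on $N$, sampling occurs at a point
drawn strictly between the $N$-th birth and the next would-be event, so the
youngest cherry does not sit on zero-length branches. Extinct lineages are
pruned by default (flag to keep), collapsing pass-through nodes; total
extinction triggers a retry (up to 100). The Yule expectation — time from
$k$ to $k+1$ lineages $\sim 1/(k\lambda)$ — is verified by the suite.

## 6. Randomisation nulls and landscape tests

The null dispersal model preserves what the data fix — tree topology,
branch durations, branch lengths — and randomises what the environment
could have shaped, the geometry:

* **rotation** (default): traverse root-to-tips, keep each branch anchored
  at its parent's randomised end, draw a uniform bearing (spherical
  destination-point formula, consistent with the haversine distance).
  Preserves connectivity and all branch lengths to numerical precision;
* **translation**: each branch rigidly moved (same bearing and length) to a
  uniform random start, destroying connectivity — a deliberately harsher
  null.

Candidates falling outside the extent or on masked cells are redrawn (cap
`maxTries = 100`); exhausted branches keep their observed bearing and are
flagged, and the run errors if more than 10% of branches fall back, since
that signals an undersized study extent. Environmental weighting accepts a
candidate endpoint with probability $(v/v_{\max})^s$ (attraction) or
$(1-v/v_{\max})^s$ (repulsion).

The diffusion test regresses branch durations on environmental distances
(ordinary least squares with intercept — the univariate $R^2$ equals the
squared Pearson correlation) on the rescaled and on the uniform raster,
giving $Q = R^2_{\text{env}} - R^2_{\text{null}}$ per tree; with $k=0$ both
regressors are bit-identical and $Q$ is exactly zero. Support compares each
posterior tree with its matched randomisation: $p$ is the winning fraction
and $\mathrm{BF} = p/(1-p)$, ties counted as losses and $p=1$ capped at
$(n-0.5)/0.5$. Two win rules are exposed because the field's usage is
ambiguous:

* the default **conjunction** rule ($Q_{\text{obs}} > 0$ *and*
  $Q_{\text{obs}} > Q_{\text{null}}$) buys specificity — a raster can never
  gain support while explaining less than plain geography;
* the **pairwise** rule ($Q_{\text{obs}} > Q_{\text{null}}$ only) is
  exchangeable by construction when observed tables are themselves
  randomisations, so its null expectation is exactly $p = 1/2$. The
  calibration checks in the suite use this rule; the conjunction rule is
  conservative under the same null (randomisation preserves the
  duration–length coupling of diffusive branches, so the environmentally
  perturbed regressor loses to plain distance more often than not).

The dispersal-location test compares mean raster values at branch end
nodes in both directions (attraction and repulsion); because half of the
end nodes are sampling locations, its outcome is entangled with sampling
effort and is reported with a degeneracy flag when observed and null
statistics tie everywhere. The isolation-by-resistance test replaces
geographic with environmental distances in the tip-pair correlation
against patristic durations, $Q_{\mathrm{IBR}} = r^2_{\text{env}} -
r^2_{\text{geo}}$. The MDS transformation double-centres the environmental
distance matrix and returns the two leading eigencoordinates (exact on
Euclidean input, a property the suite checks by Procrustes against an
independent implementation); re-running phylogeographic inference in the
transformed space is the user's step, outside this package. The
regularity comparison reports the coefficient of variation of per-branch
diffusion coefficients — lower is more Brownian.

## 7. What the synthetic data do and do not show

The fixture generator writes, under one seed (byte-identical on
regeneration): a posterior of BRW birth–death trees (10×20 tips at small
scale, 100×50 default) with per-axis variance 200 km²/yr (true diffusion
coefficient 100 km²/yr, a mid-range value for a regional outbreak, Yule
rate 1/yr, most recent tip 2020.0), an MCC-style tree with square 80% HPD
node annotations, and four 50×50 rasters of 0.2° cells (uniform, gradient,
half-plane barrier, seeded noise). It emulates the *format* and the
*diffusion geometry* of real reconstructions. It does not emulate:
posterior correlation between trees (fixture trees are independent draws,
real posterior samples are autocorrelated), phylogenetic signal in sampling
locations, location-inference uncertainty (fixture coordinates are exact),
or heterogeneous sampling effort. Passing tests therefore validate the
estimators and tests under their own model assumptions — not robustness to
the biases of real surveillance data.

Problem sizes used by the simulation-based checks were chosen to keep the
whole suite in the low minutes while leaving comfortable Monte-Carlo
margins: 200 replicates of 100-tip trees for estimator recovery, 50
replicates of 200-tip trees for the subsampling contrast, 50 replicate runs
of 10 trees for null calibration, and 20 trees of 150 tips for the power
check. The power check's study conditions — a binary habitat raster with a
21-fold diffusivity contrast ($k_{\text{sim}} = 20$) across a boundary
through the root, measured with a weak rescaling ($k = 1$) — reflect that a
variance multiplier $m$ moves displacements by $\sqrt{m}$, so the
measurement ladder that best matches a strong simulated effect sits well
below $k_{\text{sim}}$.

## 8. Known limitations

* Tangent-plane displacement conversion degrades near the poles and for
  continental-scale steps.
* Least-cost and commute-time distances are lattice metrics: they inherit
  grid resolution and 8-connectivity artefacts (octile overestimate up to
  ~8% on uniform ground).
* The commute-time scaling $2|E|R_{\text{eff}}$ follows the package's
  pinned chain closed form; it differs by a constant factor from the
  volume-weighted convention ($2\sum_e w_e R_{\text{eff}}$) on non-uniform
  rasters, which matters only if absolute commute times are compared across
  rasters — the tests use them only within-raster.
* GeoTIFF input relies on an ESRI world file or explicit extent arguments
  for georeferencing; ESRI ASCII grids are the self-contained text format.
* No CRS transformations, no polytomy resolution, no re-rooting, and no
  Bayesian inference: the package starts where the phylogeographic sampler
  stops.
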