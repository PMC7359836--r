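---
title: "Simulating genetic differentiation over dynamic glacial landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating genetic differentiation over dynamic glacial landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(paleodiverge)
```

## Why this model

Most landscape-genetic simulators put their complexity into demography and
genetics (individuals, alleles, mutation, coalescents) and treat the
landscape as a static backdrop. `paleodiverge` inverts that emphasis: the
landscape is fully dynamic — a centennial time series of habitat
suitability and landscape classes — and the genetics is reduced to the
minimum able to express *population differentiation*: a single symmetric
matrix `D` of accumulated divergence between occupied grid cells. The
model simulates genetic beta diversity only; there is no within-population
(alpha) diversity, no effective population size, no mutation rate. What it
buys with that parsimony is the ability to run a hemispheric-extent,
20,000-year scenario in seconds, making parameter sweeps over dispersal
and landscape-cost hypotheses trivial.

## The moving parts

**Connectivity.** Cells are nodes of an 8-connected graph (4-connectivity
available; 8 is the default because it reduces grid-axis artifacts in
least-cost paths). An edge's weight is the great-circle length between the
two cell centers (haversine, R = 6371 km — at continental extent planar
distances are badly wrong) times the arithmetic mean of the endpoint class
cost factors. The mean-of-endpoints rule is the standard symmetric choice
in cost-surface tooling; how per-cell costs become per-edge costs is
genuinely open, so both the rule and the neighborhood are configuration,
not dogma. Suitable habitat has factor 1 by definition; unsuitable land,
glacier and sea take factors ≥ 1 (defaults 1.25). Unsuitable terrain is
*costly, never impassable*: least-cost paths run over the full grid, so
raising a factor reroutes or lengthens paths but cannot disconnect the
graph. `least_cost_matrix()` uses exact Dijkstra shortest paths (via
igraph); the test suite holds it to a dense Floyd–Warshall oracle at
1e-9 relative error on hundreds of random classed grids.

**Dispersal.** Each occupied cell draws one dispersal distance (km/year)
from a Weibull kernel. We parameterize by median and shape — field
movement data are reported as medians and upper quantiles, never as
Weibull scales — and derive scale = median / (ln 2)^(1/shape), so the
kernel's median is exact by construction, and the 95% quantile is
median × (ln 20 / ln 2)^(1/shape). Shape 1 is exponential (frequent
long-distance dispersal, which in practice erases genetic structure);
shape 2.5 keeps draws near the median. The default median of 4.3 km/year
(95%: 7.7 km/year) sits in the range of observed caribou calving-ground
displacement rates, the motivating system for the scenario defaults. A
cell draws once, at initialization or colonization, and keeps its value
while occupied — dispersal as a stable local population trait; per-step
redrawing is available behind `redraw_each_step` for sensitivity checks.

**Per-step reach.** The kernel is in km/year but a landscape step spans
`step_years` (default 100) years. The connection and colonization
thresholds compare least-cost paths against
`d × dispersal_threshold_years`, default `= step_years`: a step represents
a century of movement opportunity. This reconciliation of units is a real
modeling choice, so it is exposed in the configuration rather than buried.

**Connection rule.** Cells *i* and *j* are connected when
`max(d_i, d_j)` × years *strictly* exceeds their least-cost path: gene
flow in either direction is enough to exchange migrants, and equality does
not connect. A `min` rule (both populations must reach each other) is one
switch away. Components of this connection graph — not just directly
connected pairs — define "together" for the divergence update, and
components are named by their lowest member cell index so runs are
reproducible down to labels.

**Divergence bookkeeping.** Per step, pairs in different components gain
`drift_multiplier × delta_flow` divergence units; pairs in the same
component lose `delta_flow`, floored at zero. Only the ratio is
meaningful; the default 3 (differentiation accumulates three times as fast
as gene flow erodes it) reflects the observation that during colonization
drift outpaces homogenization. `delta_flow` is a free unit and `D` is
unbounded above — there is no saturation, so absolute values of `D` are
comparable only within a run. Applying the gene-flow reduction
component-wide (rather than only along direct edges) is deliberate: it is
the only reading under which persistent clusters reach *exactly* zero
internal divergence — a pair isolated *a* steps then connected *b* steps
sits at exactly `max(0, 3a − b) × delta_flow`, which the tests verify
against simulation for random schedules.

**Step order.** Within a step: extinction, then colonization, then
connection and the divergence update (colonists participate in the update
of the step that created them). A colonist inherits the divergence row of
its cheapest source (ties to the lowest cell index): a propagule carries
its source population's history, so expansion fronts preserve the refugial
signal instead of erasing it. Zero-initializing colonists would make
post-glacial recolonization genetically structureless, which is both
biologically wrong and empirically refuted by contact zones.

**Burn-in.** The oldest landscape is replayed `burn_in_steps` (default 50)
times before the dynamic run, including within-landscape colonization, so
refugial populations enter the dynamic phase already differentiated
(two refugia isolated through a 50-step burn-in start 150 units apart at
the default ratio).

## The empirical comparison

The simulated `D` is compared against genotype-derived distances:

* **Chord distance** `Dc = 2/(πL) Σ_loci sqrt(2(1 − Σ_a sqrt(x_a y_a)))`,
  including the `2/(πL)` normalization (several published variants omit
  it; only relative structure matters for PCoA and Mantel, but the bound
  `2√2/π` makes endpoint tests exact). Loci undefined in either population
  of a pair are dropped from `L` for that pair.
* **FST** as pairwise Weir & Cockerham (1984) θ, multi-locus as the ratio
  of summed variance components — the de-facto standard for microsatellite
  data. Missing data are handled by available-allele counting per locus;
  slightly negative θ is reported as computed and clamped at zero only
  when a method requires a dissimilarity (`clamp_nonneg()`). The
  implementation (frequency/heterozygosity formulas) is tested to 1e-9
  against an independent ANOVA mean-squares derivation computed from
  individual-level sums of squares.
* **PCoA** by Gower double-centering with no negative-eigenvalue
  correction; axis variance shares are taken over positive eigenvalues
  only, and negative eigenvalues are reported rather than hidden.
* **Mantel tests** with Spearman correlation on the strictly-lower
  triangle, joint row/column permutations of the second matrix, and the
  add-one p-value convention `(count(|rho*| ≥ |rho|) + 1)/(n_perm + 1)`
  (default 999 permutations, seeded). The test's type-I error is checked
  to sit at its nominal 5% level over null replicates.
* **Site assignment**: each sampling site maps to the nearest occupied
  cell center within a 200-km buffer; sites outside the buffer — and
  populations missing from either side — are removed before comparison.
* **Dendrograms** by UPGMA (average linkage, tips at half the merge
  distance), the standard rooted tree from a distance matrix;
  neighbor-joining is available behind the `tree_method` flag.

## What the synthetic scenarios emulate — and what they do not

`two_refugia_scenario()` is a stylized glacial cycle: a 30 × 30 one-degree
grid centered on the equator (so cells are ~111 km and kilometer-scale
dispersal parameters keep their meaning), two suitable blocks separated by
a glacier band for 100 glacial steps, then a corridor for 50 postglacial
steps. It reproduces the mechanism that shapes circumpolar ungulate
structure — refugial isolation, recolonization, secondary contact — but
none of the texture of real paleo-landscapes: no coastline geometry, no
gradual ice retreat, no suitability noise, no isolated peripheral
populations. Passing the two-refugia checks therefore demonstrates that
the machinery (connectivity, inheritance, bookkeeping) behaves as
specified, not that any real species' history is recovered; with real
SDM-derived rasters the interesting output is the *comparison* statistics,
not cluster counts known in advance. `random_scenario()` provides
temporally autocorrelated random landscapes purely as a property-test
input source. `synthetic_genotypes()` uses a hierarchical
(Balding–Nichols-style) frequency model — ancestral Dirichlet frequencies
perturbed per population with concentration `(1 − F)/F` — which gives
expected pairwise FST ≈ F without coalescent machinery; it makes no
attempt at realistic linkage, mutation models or allele-size constraints.

## Numerical choices and degenerate inputs

* Strict inequalities at both thresholds (colonization and connection), so
  a reach exactly equal to a path cost does nothing.
* Ties are broken deterministically everywhere: cheapest-source ties to
  the lowest cell index, equidistant site assignment to the lowest cell
  index, UPGMA label ties alphabetically.
* NODATA raster cells become unsuitable land (cost factor applies, graph
  stays connected).
* A step that extinguishes every population halts the run with a classed
  `global extinction` error carrying the step index.
* The divergence matrix is held symmetric, non-negative and zero-diagonal
  by construction and asserted in the test suite after every step of
  randomized runs.
* All randomness (dispersal draws, Mantel permutations, synthetic data)
  flows from explicit integer seeds; repeated runs are byte-identical.

## Problem sizes

The shipped experiments run on a 30 × 30 grid with ≤ 176 occupied cells
over 200 total steps (burn-in included): about 1.5 s end to end, since
least-cost matrices are computed once per distinct landscape and reused.
The estimator and calibration checks use 2–4 populations, 8–16 loci and
20–40 individuals per population. These sizes give exact or
tight-tolerance oracles throughout; nothing in the implementation is
specific to them, and the same code paths take arbitrarily larger rasters
(cost grows roughly with occupied-cells² per step for the divergence
update and with Dijkstra runs per distinct landscape).

## Known limitations

* No alpha diversity, population sizes or carrying capacity: a cell is
  occupied or not.
* Divergence units are relative; `D` cannot be read as FST without
  calibration against data.
* Cost-path (not circuit-theory) connectivity: one best path, no
  current-flow averaging over alternative routes.
* Single Weibull kernel per run; no kernel mixtures or fat tails beyond
  shape < 1.
* ESRI ASCII grid is the raster interchange format; grids are lon-lat
  with no projection engine.
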