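---
title: "Methods: zone-based demographic analysis of tree species ranges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: zone-based demographic analysis of tree species ranges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zonedemog)
```

This vignette is the package's own account of its models and of the design
choices made where the methodology was genuinely open. The pipeline takes
plot-level forest-inventory records to grid-cell demographic indices, splits
the species' climatic space into cold-leading (CLR), middle-core (MCR) and
warm-trailing (WTR) zones, and contrasts the zones with tree-based models
and a two-sample testing protocol.

## Demographic indices

For species $x$ in a plot, the importance value is
$$IV(x) = 50\,\frac{BA(x)}{\sum BA} + 50\,\frac{NS(x)}{\sum NS},$$
with basal area $BA$ and stem count $NS$ summed over overstory and
understory trees of all species. IV is a *relativized* abundance: the two
halves each sum to 50 over the species in a plot, so per-plot IVs sum to
100 and the index is invariant to rescaling all basal areas. Percent
mortality is $100 \times$ (dead trees of the species) / (all its trees),
pooled over whatever set of plots is supplied. Seedling count applies the
regeneration size filters as printed: diameter strictly below 1 inch and
height at least 12 inches.

Two conventions had to be fixed:

* **Dead trees count in IV.** Abundance and mortality are deliberately
  separate indices, so IV includes all sampled trees by default; the
  documented switch `include_dead = FALSE` restricts to live trees.
* **A treeless plot has undefined IV** (an `NA` with a warning), never 0 —
  zero means "species absent among trees that are there".

Aggregation to cells uses the unweighted mean of plot IVs (per-plot
relativization argues against area weighting; re-relativizing at cell level
would change the index), pooled mortality over the cell's trees (so
cell-level PM equals PM over the union of plots, which the tests assert),
and summed seedling counts. Cells with no plots are excluded — responses are
only defined where there is inventory. Cells whose plots lack the focal
species are *retained* with IV = 0, PM = `NA` (undefined, there are no
trees to be dead), SC = 0, so the grids span the species' full climatic
space including nonpresence; the comparison stage later filters to positive
values.

## Climatic zones

Hardiness zones are intervals of average annual extreme-minimum temperature.
The default table spans $-42.8$ to $10\,^\circ$C in 19 equal steps
($\approx 2.78\,^\circ$C); it is a plain numeric vector, so the published
product's exact boundaries can be substituted. Species zone breakpoints
(CLR/MCR/WTR intervals, degrees C) ship as an editable CSV for eastern
hemlock, sweet birch, tulip poplar and chestnut oak.

All intervals are **lower-closed, upper-open**. Published tables print
touching endpoints (e.g. $-26.1$ both ends hemlock's CLR and begins its
MCR) without saying where the boundary itself belongs; the half-open
convention resolves every tie deterministically toward the warmer zone, and
the same convention is used for hardiness zones and species zones.
The shipped sweet-birch row has a genuine gap (CLR ends at $-26.1$, MCR
starts at $-23.3$); temperatures inside a gap are labelled `outside` with a
warning rather than silently extending either zone. Temperatures beyond the
global hardiness range clamp to zones 1/19, but temperatures outside a
*species'* range are `outside` and excluded from zonal analysis.

## Regression trees

The CART splitter is implemented in the package (it is also the engine of
the multivariate tree, for which no suitable package is installed). Splits
minimize the summed within-child sum of squared deviations about the child
mean vector, searched over every predictor and every midpoint between
adjacent distinct values. Numerical choices:

* **Tie-breaks**: equal-quality splits go to the lower predictor column
  index, then the lower threshold. Improvements within a relative
  $10^{-9}$ of the incumbent are treated as ties, so floating-point noise
  in the cumulative-sum arithmetic cannot flip the choice. The test suite
  holds the splitter equal to an independent exhaustive-enumeration oracle
  on instances up to 15 cells, univariate and multivariate, and to
  `rpart` on a larger fixture.
* **Stopping**: a node splits only if it has at least `2 * min_node`
  observations and both children get at least `min_node` (default 5 cells);
  a pure node (within-SS below $10^{-10}$ of the root SS) or `max_depth`
  stops growth. A constant response yields a root-only tree rather than an
  error.
* **Routing convention**: left is `<`, right is `>=`, and rule extraction
  uses the same comparators, so boundary cells classify identically whether
  predicted by the tree or by its extracted rules (asserted as a
  cell-for-cell round trip).

**Pruning** is weakest-link cost-complexity pruning: repeatedly collapse
the internal node with the smallest per-leaf deviance gain
$g(t) = (SS_t - \sum_{\text{leaves}(t)} SS)/(|\text{leaves}(t)| - 1)$,
ties toward the node nearest the root. The path is nested, deviance
explained is non-decreasing in the leaf budget, and the sequence can skip
leaf counts — pruning stops at the nearest achievable size at or below the
target. The display default of 8 terminal nodes balances interpretability
against resolution of the terminal groups.

**Multivariate trees** apply the same engine to the (IV, PM, SC) triple.
Responses are standardized to unit variance first — otherwise seedling
counts, on an unbounded count scale, would dominate the squared-distance
criterion; a documented switch fits on the raw scale. Node means are
reported back-transformed. Cells with undefined PM (nonpresence) are
excluded: a joint response needs all three components. Tree size is
controlled by a maximum leaf count (default 8, mirroring the univariate
display size) rather than cross-validated complexity pruning, keeping fits
deterministic and reproducible; CV size selection would be a natural
extension.

## Ensemble importance

The random-forest stage (bootstrap ensembles, out-of-bag error, permutation
importance) is delegated to `ranger`, single-threaded and seeded so fits
are reproducible. The package adds:

* **Automated predictor-subset selection**: the published analyses report a
  best-subset automation over many runs without naming an algorithm; the
  package implements a randomized search — each of `subset_runs` (default
  750 in the pipeline configuration) candidate subsets has uniform random
  size, is scored by the out-of-bag $R^2$ of a small ensemble
  (`subset_trees`, default 100), and the best subset is refitted with the
  full `n_trees` (default 1000). This matches the run-count-and-criterion
  description without inventing a named procedure. Unselected predictors
  report zero importance.
* **Grouped percentages**: permutation importances, floored at zero
  (irrelevant predictors can go slightly negative), are summed within
  categories and expressed as percentages of the mapped total, so each
  grouping sums to 100. The default map is climate = {gsai, tmaysep,
  pmaysep}, soil = {ph, clay, sieve10, sprod}, topographic = {elvmax,
  sieve200}, with a climate sub-map of growing-season moisture {gsai,
  pmaysep} versus temperature {tmaysep}. `sieve200` (percent fine texture)
  is grouped with topography following the grouping used in the zonal
  importance analysis rather than its soil-texture origin; the map is an
  ordinary named vector and fully user-editable.
* **Spatial-trend check**: the out-of-bag $R^2$ difference between a fit on
  the environmental predictors and one also given the cell coordinates,
  under a shared seed. Near-zero differences mean environmental distance,
  not geographic distance, carries the signal.

## Zone comparison protocol

`zone_compare()` filters each zone to positive values, draws 100 per zone
without replacement (falling back to all available with a warning), takes
logs — `log(x)` with no offset, since zeros are already excluded — tests
variance equality with an F-test at $\alpha = 0.05$, and runs the matching
two-sided t-test (pooled-variance or Welch). No multiple-testing correction
is applied across responses or species, matching the marginal reporting of
the original protocol; the output is one tidy row per comparison so users
can adjust afterwards if they wish. The tests verify by simulation that the
full protocol (sample → log → F-gate → t) holds its nominal 5% size within
±1.5 points over 1000 null replicates of fresh lognormal populations, and
exceeds 90% power for a 1-SD shift on the log scale at $n = 100$.
`zone_compare_replicates()` repeats the single-draw protocol to show how
sensitive a verdict is to the subsampling draw.

## The synthetic landscape and what it does (not) show

The generator exists so every downstream stage is testable without
inventory data. It emulates:

* **Smooth predictor surfaces**: Gaussian-filtered white noise (separable
  kernel, reflection padding, default length scale 3 fine cells), rescaled
  to field-realistic ranges in the units of the real predictors (gsai
  0.5–2, tmaysep 12–24 °C, pmaysep 300–700 mm, ph 4–8, texture percentages
  0–100, sprod integer 0–19, elvmax 0–1500 m), so configurations transfer
  to real data. Any smooth random field would do; separable Gaussian
  smoothing keeps the implementation dependency-light.
* **Two nested resolutions**: fields are simulated at fine scale and
  averaged into coarse cells, so the coarse value *is* the mean of its fine
  children (consistency by construction, asserted to $10^{-9}$); default
  refinement factor 2 (a 2×2 block of fine cells per coarse cell). The
  coarse `sprod` is consequently non-integer — nesting consistency is
  prioritized over ordinality at the aggregated scale.
* **A latitudinal temperature gradient**: extreme-minimum temperature is
  linear along one axis (default $-35$ to $-5\,^\circ$C, spanning the
  shipped species' zones) plus smooth noise (SD 0.5 °C).
* **Zone-dependent demography**: plot counts per fine cell are Poisson
  (mean 1.5; how many inventory plots fall in a cell is exposed as a
  parameter, not fixed); the focal species' within-plot share follows a
  logistic link on z-scored predictors with zone-specific coefficients,
  per-tree mortality is a clamped linear probability, and seedlings are
  Poisson. The default scenario encodes soil-driven abundance in the cold
  zone, growing-season-moisture-driven abundance in the warm zone, higher
  mortality and weaker regeneration toward the trailing edge — a known
  ground truth that the grouped-importance stage is required to recover in
  at least 8 of 10 seeded replicates.

It does **not** emulate: real inventory plot design (subplots, expansion
factors), realistic species mixtures beyond focal-plus-background,
non-stationary autocorrelation, predictor cross-correlation structure, or
observation error in the temperature surface. Passing tests therefore show
that the machinery is correct and that recoverable signals are recovered —
not that any particular field dataset will yield a given fit quality.

## Problem sizes and reproducibility

The shipped tests run the recovery study on 20×10-coarse-cell landscapes
(800 fine cells, roughly 1200 plots) over 10 seeds with 300-tree ensembles,
the calibration study on 1000 null replicates, and the oracle-equivalence
study on random instances of up to 15 cells — sizes chosen so the whole
suite completes in well under a minute per file while leaving the
statistical assertions comfortable margins. All randomness flows through
explicit seeds (`withr::with_seed`), so landscapes, plot sets, fits and
comparisons are bit-reproducible; the pipeline writes a manifest with the
master seed and a configuration hash.

## Known limitations

* Missing predictor values are rejected, not surrogate-split; synthetic
  data are complete by construction.
* Categorical predictors and classification responses are out of scope;
  `sprod` is treated as numeric, as ordinal soil indices commonly are in
  tree models.
* The hardiness-zone table is an equal-step default, not the published
  interpolated product; users with the real product should supply its
  boundaries.
* Importance percentages depend on the category map; the defaults are a
  documented editorial choice, not an estimate.
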