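---
title: "Gridded biodiversity hotspots, coverage-standardised richness and survey completeness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gridded biodiversity hotspots, coverage-standardised richness and survey completeness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hotspotgrid)
```

## The problem

Point occurrence records — museum specimens, survey data, citizen-science
observations — are the only distributional evidence available for most taxa
in most countries. Mapping biodiversity "hotspots" from such data faces two
entangled obstacles: different hotspot currencies (species richness,
endemism, threatened species) need not coincide in space, and the records
themselves are collected where people go, not where species live. This
package implements a complete analysis chain for quantifying both problems
on square analysis grids: per-cell diversity and vulnerability metrics,
hotspot congruence across definitions, correlation of every metric with
sampling effort (with autocorrelation-corrected inference),
coverage-standardised richness that removes part of the effort artefact, and
accumulation-curve completeness scores that say where more sampling is
needed. A synthetic occurrence generator with known ground truth closes the
loop: every stage is validated against data whose true structure is known.

## Data model and filtering

An occurrence record is a species observation at planar metre coordinates
with an observation year (possibly missing) and IUCN categories under the
global and — for groups that have one — the national assessment. Mammals
carry no national assessment here, so national-level vulnerability metrics
are refused for them and for multi-class (tetrapods-combined) data rather
than silently computed from `NE` codes.

Pseudo-replication is removed before any per-cell counting: one record is
kept per distinct `(species, x, y, year)` key, in original order. Two design
choices matter. Coordinates are compared exactly by default because source
precision is unknowable downstream; an optional decimal-places parameter
coarsens the key (never the stored coordinates) when a user knows their data
are mixed-precision. Missing years form a single key value, so two
coordinate-identical records of unknown year collapse to one — the
conservative choice against over-counting effort.

## Grids and geometry

Analysis grids are half-open square lattices, `[x0 + c s, x0 + (c+1) s) ×
[y0 + r s, y0 + (r+1) s)`, built over the bounding box of a country polygon
and clipped to it. The canonical resolutions are 12.5, 25 and 50 km; the
1 km sub-grids used for incidence sampling require the sub-cell size to
divide the cell size, so the 12.5 km resolution needs an explicit sub-cell
choice (e.g. 500 m) and is excluded from coverage analyses by default.

Kilometre-sized cells are ill-defined in geographic degrees, so all analysis
runs in a projected metric system; a local equirectangular helper converts
longitude/latitude input at country scale (distance distortion grows with
the latitude span — for precise work supply coordinates already projected
with proper GIS tooling). Because no grid origin is canonical, the origin
defaults to the lower-left bounding-box corner and is stored in the grid
object: results are reproducible given (CRS, origin, cell size), and are
*not* comparable across different choices. Cells whose clipped area is zero
are dropped everywhere; partly-inside cells keep their clipped area for area
accounting but their full square for point assignment, so a record just
offshore of the coastline polygon but inside a coastal cell's square is
still counted.

The polygon layer (shoelace areas, Sutherland–Hodgman clipping against
cells, even-odd point-in-polygon, GeoJSON I/O) is deliberately small and
axis-aligned-rectangle-centred: cells are convex rectangles, for which
Sutherland–Hodgman clipping is exact, including multi-part polygons and
holes.

## Per-cell metrics

With records assigned to cells:

* **effort** — record count after deduplication;
* **SR** — distinct species count;
* **E** — range-size-weighted endemism: species *j* occupying `m_j` cells
  contributes `q_ij = 1/m_j` to each occupied cell, and `E_i = Σ_j q_ij`.
  "Fraction of the distribution" is operationalised as occupancy share —
  equal weight per occupied cell — the standard reading of range-size-
  weighted richness from occurrence (not range-polygon) data. The map
  conserves mass: `Σ_i E_i` equals the number of species observed, a
  property the tests exercise on hundreds of random datasets;
* **TSN / TSP** — number and proportion of species assessed CR, EN or VU:
  `TSP = (CR + EN + VU) / N` with `N` the cell's species count. Cells with
  records but no threatened species score 0; only record-free cells are
  undefined.

## Hotspots, congruence and protected-area overlap

A hotspot at definition `d` is the top `k = ⌈d/100 · n⌉` of the `n`
non-empty cells sorted by a metric. The ceiling guarantees at least one cell
at the strict 2.5% definition on small grids; ties at the cut break by
ascending cell index, which makes selections deterministic and nested in
`d`. All metrics in a comparison share one cell universe — cells with at
least one record — because zero-threat cells are data, not gaps.

Congruence of two or more hotspot selections is
`100 · |∩ selections| / |∪ selections|`: the percentage of cells that are
hotspots under *every* metric, relative to all cells that are a hotspot
under any. The congruence curve sweeps `d` from 0.5% to 100% in 0.5% steps
(100% congruence at `d = 100` by construction); the 2.5% and 10% values are
reported as the two canonical summaries. Protected-area overlap is the share
of selected cells whose square intersects any protected-area polygon — "at
least partially covered", so boundary contact counts.

## Correlation under spatial autocorrelation

Per-cell metrics are spatially smooth, so ordinary Pearson tests overstate
significance. The modified t-test keeps the Pearson estimate `r` untouched
and replaces `n` in the inference with an effective sample size: pairwise
centroid distances are binned into `k = 13` equal-width classes (the
convention of reference implementations of this test; configurable), each
variable gets a Moran-type correlogram estimate per class (centred products
over the biased variance; empty classes contribute zero), the two implied
`n × n` correlation matrices `R_A`, `R_B` give `v̂ = tr(R_A R_B)/n²`, and
`M̂ = 1 + 1/v̂`. The statistic `t = r √((M̂−2)/(1−r²))` is referred to a t
distribution with `M̂ − 2` degrees of freedom. With identity matrices
`M̂ = n + 1` exactly (a closed-form test anchor); under iid simulation the
test's type-I error sits at the nominal 5% (validated over 500 replicates at
`n = 200`), and under a shared smooth surface `M̂` drops well below `n`.
Cells without records are removed before all correlations to avoid
double-zero inflation; coincident centroids are rejected (impossible on a
grid).

## Coverage-based rarefaction and standardisation

Observed richness is not comparable across cells sampled with different
intensity. Comparisons are made at equal *sample coverage* — the estimated
fraction of the assemblage's incidence probability represented in the
sample — using incidence-frequency data: for each grid cell, the sampling
units are its 1 km sub-cells with at least one record of the focal group
(`T`), and `Y_j` counts the sub-cells where species *j* was detected.
Visited-but-empty sub-cells are unknowable from presence-only data, which is
why `T` counts occupied units only.

The estimators are the incidence-data forms for Hill number order 0:
interpolated richness `S(t) = Σ_j [1 − C(T−Y_j, t)/C(T, t)]`, reference
coverage `C(T) = 1 − (Q1/U)·(T−1)Q1/((T−1)Q1 + 2Q2)`, the Chao2-type unseen
species count `Q0 = ((T−1)/T)·Q1²/(2Q2)` (bias-corrected fallback when
`Q2 = 0`), extrapolated richness
`S(T+t*) = S_obs + Q0[1 − (1 − Q1/(TQ0+Q1))^{t*}]` and extrapolated coverage
`C(T+t*) = 1 − (Q1/U)[(T−1)Q1/((T−1)Q1+2Q2)]^{t*+1}`. Interpolated coverage
below `T` uses the subsampling estimator
`C(t) = 1 − Σ_j (Y_j/U)·C(T−Y_j, t)/C(T−1, t)`; both richness and coverage
are validated against brute-force subsampling oracles in the tests.

Cells are excluded when `S_obs < 6`, `T < 6`, **or** every species is a
singleton (`U = S_obs`): the three clauses combine with OR because any one
of them leaves the estimators degenerate (an AND reading would admit cells
with, say, five singleton species). Each included cell is extrapolated to
double its reference size; `C_max` is the minimum of those doubled-sample
coverages and `C_5%` their 5th percentile (linear interpolation between
order statistics, the default quantile definition). For each standard the
coverage curve is inverted — linear search on the integer lattice below `T`,
closed form above — and the cell's expected richness at that effort is
reported; a cell that cannot reach the standard by `2T` is capped there and
flagged.

## Completeness and sampling priorities

Inventory incompleteness per cell is scored from the exact (analytically
smoothed) species accumulation curve: with `N_j` the number of samples
containing species *j*, `S_exp(n) = Σ_j [1 − C(N−N_j, n)/C(N, n)]`. The
sampling unit is one occurrence record — the only unit available at
resolutions that are never sub-gridded — and is configurable to sub-cell
units via the incidence machinery. The incompleteness proxy is the mean
slope of the final 10% of the curve; because the exact curve's successive
differences telescope, the mean over the window equals the endpoint slope
`(S_exp(N) − S_exp(n0))/(N − n0)` with `n0 = ⌊0.9N⌋` clamped to `[1, N−1]`,
which is how it is implemented. Priorities: record-free cells are
`VeryHigh`; cells whose curve cannot be fitted (fewer than 2 records by
default) are `High`; otherwise `Null` (slope ≤ 0.05, well sampled), `Low`
(≤ 0.25) or `Medium` (≤ 1), right-closed boundaries. The well-sampled
summary aggregates clipped cell areas: percentage of country area in cells
that are anything other than slope ≤ 0.05.

## The synthetic generator

`simulateOccurrences()` draws datasets whose true structure is known, so
recovery can be verified rather than assumed. Species ranges are discs with
uniform centres and log-normal radii (default median 45 km, `sdlog 0.9` — a
strongly right-skewed range-size distribution over a 480 × 370 km
rectangular country of ~177,600 km², with a default pool of 50 + 68 + 430 +
116 species across the four tetrapod classes and 69,364 records at full
scale); records are drawn by sampling a location from an effort surface
(uniform floor plus Gaussian bias centres), then a species among those whose
disc covers the location, weighted by a per-class detection weight that
makes birds dominate the record stream as they do in real collections.
Threat status is logistic in log range area with a negative effect, so
restricted-range species are likelier to be threatened; national statuses
use a higher intercept (national lists flag more species) and mammals are
`NE`. Years are uniform over 1950–2019. All draws come from one seeded
stream in a documented order (ranges, labels, locations/species, years), so
a seed reproduces a dataset bit-for-bit.

Presets: `"none"` (uniform effort), `"city"` (three bias centres along the
southern coast plus a 0.15 uniform floor) and `"extreme"` (~90% of records
around one centre). Centres scale with the country rectangle. What the
generator does *not* emulate: real coastline geometry, climate-driven
richness gradients, taxonomic error, temporal trends in recording, or
spatially correlated detection within species. Passing tests therefore
demonstrate correctness of the estimators under the stated sampling model,
not that any real dataset satisfies that model.

Tests and the bundled analyses use scaled-down configurations — typically a
200 × 150 km country, 40–90 species and 1,500–12,000 records — which keep
every property (effort artefacts, filter behaviour, recovery by coverage
standardisation) intact at a fraction of the cost; the full-scale defaults
remain available for heavier experiments.

## Worked example

```{r example, eval = FALSE}
cfg <- biasScenario("city", seed = 7, n_records = 3000L,
                    n_species = c(Amphibia = 10L, Reptilia = 12L,
                                  Aves = 40L, Mammalia = 15L),
                    country_km = c(200, 150))
sim <- simulateOccurrences(cfg)
report <- runAll(runConfig(sim$occ, sim$country, sim$pas,
                           cell_sizes = c(25000, 50000)))
report$records        # per-group records, species, unsampled area
report$congruence     # hotspot congruence at the 2.5% and 10% definitions
report$correlations   # effort vs metric, corrected for autocorrelation
report$pa_overlap     # protected-area coverage of richness hotspots
```

## Numerical choices and limitations

* Binomial coefficients are evaluated as `exp(lchoose(...))`, stable far
  beyond the `T` and `N` encountered on 1 km sub-grids.
* The coverage curve is piecewise (subsampling estimator to `T`, closed-form
  extrapolation beyond); the two branches agree at `t* = 0` by construction
  and inversion is monotone on each branch.
* Hotspot tie-breaking by cell index is arbitrary but deterministic; any
  other deterministic rule changes congruence only at exact ties.
* Exact reproduction of a published gridded analysis additionally requires
  that study's projection and grid origin; with those unknown, per-cell
  values are reproducible only under this package's declared conventions.
* The equirectangular projection helper is a convenience for country-scale
  examples, not a substitute for a proper equal-area projection in
  production analyses.
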