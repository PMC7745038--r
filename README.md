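# hotspotgrid

Gridded biodiversity hotspot mapping, hotspot congruence, effort-corrected
spatial statistics and survey-completeness analysis from point occurrence
records.

## Who this is for

Biodiversity informaticians and conservation analysts who have a table of
occurrence records (Darwin-Core-style CSV), a country boundary and a set of
protected-area polygons, and who need to answer four questions that recur in
national biodiversity assessments:

1. **Where are the hotspots** of species richness, endemism and threatened
   species — and do the different hotspot types even coincide?
2. **How much of the apparent pattern is sampling artefact**, given that
   collection effort concentrates around cities?
3. **What would richness look like at equal sampling coverage** across the
   country?
4. **Where should future survey effort go?**

## The methods at the core

All metrics are computed per cell of a half-open square grid (12.5, 25 and
50 km are the canonical resolutions) clipped to the country polygon, after
removing duplicate records per `(species, locality, year)`.

* **Weighted endemism** (range-size-weighted richness): for species *j*
  occupying `m_j` cells, each occupied cell *i* receives `q_ij = 1/m_j`, and
  `E_i = Σ_j q_ij`. The map conserves mass: `Σ_i E_i` = number of species.
* **Threatened-species proportion**: `TSP = (CR + EN + VU) / N` per cell,
  under the global or a national IUCN assessment (refused where no national
  assessment exists, e.g. mammals).
* **Hotspots and congruence**: the top `⌈d% · n⌉` of non-empty cells per
  metric; congruence across metrics is `100 · |∩| / |∪|`, swept over
  definitions `d = 0.5, 1, …, 100%`, summarised at 2.5% and 10%.
* **Modified t-test**: Pearson `r` between per-cell variables with an
  effective sample size `M̂ = 1 + 1/v̂`, `v̂ = tr(R̂_A R̂_B)/n²`, estimated
  from binned Moran correlograms of both variables; `t = r√((M̂−2)/(1−r²))`
  on `M̂ − 2` df.
* **Coverage-standardised richness** (Hill number q = 0, incidence data):
  per-cell incidence frequencies from 1 km sub-grids; interpolation
  `S(t) = Σ_j [1 − C(T−Y_j,t)/C(T,t)]`, Chao2-type extrapolation, sample
  coverage `C(T) = 1 − (Q1/U)·(T−1)Q1/((T−1)Q1+2Q2)`; cells are compared at
  `C_max` (minimum coverage after doubling every sample) and at the 5th
  percentile `C_5%`.
* **Survey completeness**: exact species-accumulation curves per cell,
  scored by the mean slope of their final 10%; priorities `Null` (≤ 0.05,
  well sampled), `Low` (≤ 0.25), `Medium` (≤ 1), `High` (too few records for
  a curve), `VeryHigh` (no records).

A synthetic occurrence generator (`simulateOccurrences()`, presets via
`biasScenario()`) produces datasets with known species ranges, city-biased
effort surfaces and range-size-dependent threat labels, so every stage of
the pipeline is verifiable against ground truth. See the methods vignette
(`vignettes/hotspot-analysis.Rmd`) for models, assumptions and design
choices.

## Worked example

```r
library(hotspotgrid)

cfg <- biasScenario("city", seed = 7, n_records = 3000L,
                    n_species = c(Amphibia = 10L, Reptilia = 12L,
                                  Aves = 40L, Mammalia = 15L),
                    country_km = c(200, 150))
sim <- simulateOccurrences(cfg)
report <- runAll(runConfig(sim$occ, sim$country, sim$pas, cell_sizes = 25000))

report$records
#>       group cell_size n_records n_species unsampled_km2 unsampled_pct
#> 1  Amphibia     25000       181         7         18125         60.42
#> 2  Reptilia     25000       203         7         18750         62.50
#> 3      Aves     25000      2390        35          2500          8.33
#> 4  Mammalia     25000       226        11         19375         64.58
#> 5 Tetrapoda     25000      3000        60          1875          6.25

subset(report$correlations, var_b == "SR")
#>        group cell_size  var_a var_b     r M_hat    t        p  n
#> 1   Amphibia     25000 effort    SR 0.632 11.16 2.47 0.035274 19
#> 3   Reptilia     25000 effort    SR 0.933  6.10 5.24 0.005919 18
#> 5       Aves     25000 effort    SR 0.649 13.33 2.87 0.014747 44
#> 9   Mammalia     25000 effort    SR 0.896  9.26 5.44 0.000854 17
#> 13 Tetrapoda     25000 effort    SR 0.791 12.36 4.16 0.001798 45
```

Reading the output: the city-biased generator produces bird-dominated
records (2,390 of 3,000) and leaves 60%+ of the country unsampled for the
smaller groups. Observed richness correlates strongly with sampling effort
in every group (`r` 0.63–0.93) — but the effective sample sizes (`M_hat`
6–13, versus 17–45 cells) show how much the spatial autocorrelation deflates
the evidence: the corrected p-values are orders of magnitude larger than a
naive Pearson test would report. The same report also contains hotspot
congruence at the 2.5%/10% definitions (near zero for most groups in this
run: different metrics pick different cells), coverage standardisation for
the birds (`C_max = 0.574` over 15 included cells) and the completeness
summary (7 well-sampled cells; 85.4% of the country under-sampled).

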