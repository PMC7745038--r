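Package: hotspotgrid
Title: Gridded Biodiversity Hotspot Mapping, Congruence and
    Survey-Completeness Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping biodiversity hotspots from point occurrence
    records on square analysis grids: per-cell sampling effort, species
    richness, range-size-weighted endemism, and threatened-species number
    and proportion under global or national IUCN assessments; hotspot
    selection and congruence sweeps across hotspot-definition thresholds;
    Pearson correlations with significance corrected for spatial
    autocorrelation via an effective sample size; incidence-based
    coverage rarefaction and extrapolation of species richness (Hill
    number of order 0) with coverage-standardised comparisons; exact
    species-accumulation curves and terminal-slope survey-completeness
    scoring with sampling-priority classification; protected-area overlap
    of hotspot cells; and a synthetic occurrence-data generator with
    known ground truth for end-to-end verification.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
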