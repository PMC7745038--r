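# Survey-completeness ("ignorance") scoring: exact species-accumulation
# curves per cell, terminal-slope incompleteness, and the five-level
# sampling-priority classification.

#' Exact (smoothed) species accumulation curve
#'
#' Expected number of species after `n` of the `N` samples, averaged
#' analytically over all sample orders: with `N_j` the number of samples
#' containing species j, `S_exp(n) = sum_j [1 - choose(N - N_j, n) /
#' choose(N, n)]`. The curve is non-decreasing, concave, and ends at the
#' observed richness.
#'
#' @param counts Integer vector `N_j`: per-species number of samples
#'   containing the species.
#' @param N Total number of samples; defaults to `sum(counts)` for
#'   record-based sampling units, where each record is one sample holding one
#'   species.
#' @return A `sac_curve`: numeric vector `S_exp(1..N)` with attribute `N`.
#' @export
exactSac <- function(counts, N = sum(counts)) {
  counts <- as.integer(counts)
  N <- as.integer(N)
  if (N < 1L || !length(counts)) stop("empty cell: no accumulation curve")
  if (any(counts < 1L) || any(counts > N) || sum(counts) < max(counts))
    stop("invalid per-species sample counts")
  curve <- vapply(seq_len(N), function(n)
    sum(1 - exp(lchoose(N - counts, n) - lchoose(N, n))), 0)
  structure(curve, N = N, class = "sac_curve")
}

#' Exact SAC from a vector of sample species labels
#'
#' Record-based sampling units: each occurrence record is one sample
#' contributing one species incidence.
#'
#' @param species Character vector: the species label of each sample/record.
#' @return A `sac_curve`.
#' @export
sacFromRecords <- function(species) {
  if (!length(species)) stop("empty cell: no accumulation curve")
  exactSac(as.integer(table(species)), N = length(species))
}

#' @export
print.sac_curve <- function(x, ...) {
  N <- attr(x, "N")
  cat(sprintf("sac_curve: N = %d samples, S_obs = %.0f, terminal slope = %s\n",
              N, x[N], format(terminalSlope(x), digits = 3)))
  invisible(x)
}

#' Terminal slope of a species accumulation curve
#'
#' Mean slope of the final 10% of the curve, the incompleteness proxy: with
#' `n0 = floor(0.9 N)` clamped to `[1, N - 1]`, the slope is
#' `(S_exp(N) - S_exp(n0)) / (N - n0)`. (For the exact curve, averaging the
#' successive finite differences over the window telescopes to exactly this
#' endpoint slope.) Values near 1 mean every extra sample still adds a
#' species (incomplete inventory); values near 0 mean saturation. Undefined
#' (`NA`) when the cell has fewer than `min_records` samples.
#'
#' @param curve A `sac_curve`.
#' @param min_records Minimum samples needed to fit a slope (default 2).
#' @return Slope in `[0, 1]`, or `NA_real_` when not computable.
#' @export
terminalSlope <- function(curve, min_records = 2L) {
  stopifnot(inherits(curve, "sac_curve"))
  N <- attr(curve, "N")
  if (N < max(min_records, 2L)) return(NA_real_)
  n0 <- min(max(floor(0.9 * N), 1L), N - 1L)
  (curve[N] - curve[n0]) / (N - n0)
}

#' Sampling-priority classification of a cell
#'
#' Five ordered levels from the completeness evidence available: `VeryHigh`
#' for cells without records; `High` for cells with records but too few to
#' fit an accumulation curve (undefined slope); then by terminal slope,
#' `Null` (slope <= 0.05, well sampled), `Low` (0.05 < slope <= 0.25) and
#' `Medium` (0.25 < slope <= 1). Boundaries are right-closed.
#'
#' @param n_records Number of records in the cell.
#' @param slope Terminal SAC slope, or `NA` when not computable.
#' @return One of `"Null"`, `"Low"`, `"Medium"`, `"High"`, `"VeryHigh"`
#'   (factor with those levels).
#' @export
classifyPriority <- function(n_records, slope) {
  lev <- c("Null", "Low", "Medium", "High", "VeryHigh")
  cls <- if (n_records == 0L) "VeryHigh"
    else if (is.na(slope)) "High"
    else if (slope <= 0.05) "Null"
    else if (slope <= 0.25) "Low"
    else "Medium"
  factor(cls, levels = lev)
}

#' Per-cell completeness table for a grid
#'
#' Builds the exact SAC of every cell (record-based sampling units), scores
#' its terminal slope and assigns the sampling priority, including the
#' record-free cells of the grid (priority `VeryHigh`).
#'
#' @param occ An `occurrence_set` (one group, deduplicated).
#' @param grid An `analysis_grid`.
#' @param assignment Optional precomputed [assignCells()] vector.
#' @param min_records_sac Minimum records to fit a SAC slope (default 2).
#' @return Data frame: `cell`, `col`, `row`, `area_km2`, `N`, `S_obs`,
#'   `slope`, `priority`.
#' @export
completenessTable <- function(occ, grid, assignment = NULL, min_records_sac = 2L) {
  stopifnot(inherits(occ, "occurrence_set"), inherits(grid, "analysis_grid"))
  if (is.null(assignment)) assignment <- assignCells(occ, grid)
  keep <- !is.na(assignment)
  res <- lapply(seq_len(nrow(grid$cells)), function(i) {
    cell <- grid$cells$cell[i]
    sp <- occ$species[keep & assignment == cell]
    N <- length(sp)
    if (N == 0L) return(list(N = 0L, S_obs = 0L, slope = NA_real_))
    curve <- sacFromRecords(sp)
    list(N = N, S_obs = length(unique(sp)),
         slope = terminalSlope(curve, min_records_sac))
  })
  out <- data.frame(
    grid$cells[, c("cell", "col", "row", "area_km2")],
    N = vapply(res, `[[`, 0L, "N"),
    S_obs = vapply(res, `[[`, 0L, "S_obs"),
    slope = vapply(res, `[[`, 0, "slope"))
  out$priority <- factor(mapply(function(n, s) as.character(classifyPriority(n, s)),
                                out$N, out$slope),
                         levels = c("Null", "Low", "Medium", "High", "VeryHigh"))
  out
}

#' Well-sampled summary of a completeness table
#'
#' Cells with a terminal slope `<= 0.05` count as well sampled; everything
#' else — steeper slopes, cells without a computable curve (`High`) and
#' record-free cells (`VeryHigh`) — is under-sampled. The under-sampled
#' percentage aggregates clipped cell areas over the country area.
#'
#' @param tab A [completenessTable()] data frame.
#' @param country_area_km2 Country area (km^2).
#' @return List: `n_wellsampled`, `pct_undersampled_area`.
#' @export
wellsampledSummary <- function(tab, country_area_km2) {
  well <- !is.na(tab$slope) & tab$slope <= 0.05
  under_km2 <- sum(tab$area_km2[!well])
  list(n_wellsampled = sum(well),
       pct_undersampled_area = 100 * under_km2 / country_area_km2)
}
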