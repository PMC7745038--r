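# End-to-end orchestration: dedup -> grids -> metrics -> hotspot congruence ->
# corrected correlations -> coverage rarefaction -> completeness -> protected-
# area overlap, per class group and for all tetrapods combined.

#' Run configuration for the full analysis
#'
#' @param occ An `occurrence_set` (raw; deduplicated internally), or a CSV
#'   path readable by [readOccurrences()].
#' @param country A `geo_polygon` or GeoJSON path.
#' @param pas Protected areas: list of `geo_polygon`s, a single one, a
#'   GeoJSON path, or `NULL` to skip overlap analysis.
#' @param cell_sizes Analysis resolutions in metres
#'   (default `c(12500, 25000, 50000)`).
#' @param sub_size Sub-cell size for incidence sampling (default 1000 m);
#'   rarefaction runs only at resolutions it divides.
#' @param definitions Hotspot definitions in percent (default `c(2.5, 10)`).
#' @param congruence_metrics Metrics entering the congruence comparison
#'   (default `c("SR", "E", "TSN_g")`).
#' @param k Distance classes for the corrected correlations.
#' @param grid_origin Optional grid origin.
#' @param out_dir Optional directory for per-stage CSV output.
#' @return A `run_config` list.
#' @export
runConfig <- function(occ, country, pas = NULL,
                      cell_sizes = c(12500, 25000, 50000), sub_size = 1000,
                      definitions = c(2.5, 10),
                      congruence_metrics = c("SR", "E", "TSN_g"),
                      k = 13, grid_origin = NULL, out_dir = NULL) {
  stopifnot(all(cell_sizes > 0), all(definitions > 0), all(definitions <= 100))
  if (is.character(occ)) occ <- readOccurrences(occ)
  if (is.character(country)) country <- readGeoJSON(country)
  if (is.character(pas)) pas <- readGeoJSON(pas, split = TRUE)
  if (inherits(pas, "geo_polygon")) pas <- list(pas)
  structure(list(occ = occ, country = country, pas = pas,
                 cell_sizes = cell_sizes, sub_size = sub_size,
                 definitions = definitions,
                 congruence_metrics = congruence_metrics, k = k,
                 grid_origin = grid_origin, out_dir = out_dir),
            class = "run_config")
}

#' Run the full hotspot, congruence, rarefaction and completeness analysis
#'
#' Deduplicates once, then for every resolution and group (four classes plus
#' all tetrapods combined) computes the per-cell metric table, hotspot
#' congruence at the configured definitions, autocorrelation-corrected
#' correlations of effort against each metric, coverage-standardised richness
#' (at resolutions divisible by the sub-cell size), completeness priorities,
#' and protected-area overlap of richness hotspots. National-level metrics are
#' skipped with an explicit note for mammals and the combined set (no
#' national assessment exists for them).
#'
#' @param config A [runConfig()].
#' @return A `run_report` list: `records` (per-group record/species counts and
#'   unsampled areas per resolution), `congruence`, `correlations`,
#'   `rarefaction`, `completeness`, `pa_overlap`, `notes`, `metrics` (the raw
#'   per-cell tables, keyed `group/cell_size`).
#' @export
runAll <- function(config) {
  stopifnot(inherits(config, "run_config"))
  occ <- deduplicate(config$occ)
  groups <- c(as.list(splitByClass(occ)), list(Tetrapoda = occ))
  notes <- character(0)
  records <- data.frame(); congr <- data.frame(); cors <- data.frame()
  rare <- list(); compl <- list(); pa_tab <- data.frame(); mtabs <- list()

  for (cs in config$cell_sizes) {
    grid <- buildGrid(config$country, cs, origin = config$grid_origin,
                      crs_tag = attr(occ, "crs_tag"))
    for (g in names(groups)) {
      go <- groups[[g]]
      if (!nrow(go)) { notes <- c(notes, sprintf("%s/%d: no records", g, cs)); next }
      asg <- assignCells(go, grid)
      mt <- cellMetrics(go, grid, asg)
      mtabs[[sprintf("%s/%d", g, cs)]] <- mt
      ua <- unsampledArea(grid, asg)
      records <- rbind(records, data.frame(
        group = g, cell_size = cs, n_records = sum(!is.na(asg)),
        n_species = length(unique(go$species[!is.na(asg)])),
        unsampled_km2 = ua[["km2"]], unsampled_pct = ua[["percent"]]))

      nonempty <- mt$effort > 0
      if (sum(nonempty) >= 2L) {
        vals <- function(col) stats::setNames(mt[[col]][nonempty], mt$cell[nonempty])
        met_ok <- config$congruence_metrics[
          !vapply(config$congruence_metrics, function(m) anyNA(mt[[m]][nonempty]), TRUE)]
        if (length(met_ok) >= 2L) {
          curve <- congruenceCurve(lapply(stats::setNames(met_ok, met_ok), vals))
          for (d in config$definitions) {
            cc <- congruence(lapply(met_ok, function(m) selectHotspots(vals(m), d)))
            congr <- rbind(congr, data.frame(group = g, cell_size = cs, d = d,
                                             congruence = cc))
          }
        }
        # corrected correlations: effort vs each diversity metric
        cent <- cbind(grid$cells$cx, grid$cells$cy)[nonempty, , drop = FALSE]
        for (m in c("SR", "E", "TSN_g", "TSP_g")) {
          v <- mt[[m]][nonempty]
          if (anyNA(v) || stats::sd(v) == 0 || sum(nonempty) < 5L) next
          mc <- tryCatch(modifiedCorrelation(mt$effort[nonempty], v, cent,
                                             k = config$k),
                         error = function(e) NULL)
          if (!is.null(mc))
            cors <- rbind(cors, data.frame(group = g, cell_size = cs,
                                           var_a = "effort", var_b = m, r = mc$r,
                                           M_hat = mc$M_hat, t = mc$t_stat,
                                           p = mc$p_value, n = mc$n))
        }
        # protected-area overlap of richness hotspots at each definition
        if (!is.null(config$pas)) for (d in config$definitions) {
          sel <- selectHotspots(vals("SR"), d)
          pa_tab <- rbind(pa_tab, data.frame(
            group = g, cell_size = cs, d = d, metric = "SR",
            overlap_pct = paOverlap(sel, config$pas, grid)))
        }
      }
      if (g %in% c("Mammalia", "Tetrapoda"))
        notes <- c(notes, sprintf(
          "%s/%d: national-level threat metrics skipped (no national assessment)", g, cs))

      # coverage rarefaction only where the sub-grid tiles the cell exactly
      if (cs %% config$sub_size == 0 && g != "Tetrapoda") {
        incs <- cellIncidences(go, grid, config$sub_size)
        if (length(incs)) rare[[sprintf("%s/%d", g, cs)]] <- standardiseRichness(incs)
        else notes <- c(notes, sprintf("%s/%d: no cells pass the rarefaction filter", g, cs))
      }
      if (g != "Tetrapoda") {
        ct <- completenessTable(go, grid, asg)
        compl[[sprintf("%s/%d", g, cs)]] <-
          list(table = ct, summary = wellsampledSummary(ct, grid$country_area_km2))
      }
    }
  }
  report <- structure(list(records = records, congruence = congr,
                           correlations = cors, rarefaction = rare,
                           completeness = compl, pa_overlap = pa_tab,
                           notes = notes, metrics = mtabs),
                      class = "run_report")
  if (!is.null(config$out_dir)) writeReport(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report\n")
  cat(sprintf(" records table: %d rows; congruence: %d rows; correlations: %d rows\n",
              nrow(x$records), nrow(x$congruence), nrow(x$correlations)))
  cat(sprintf(" rarefaction: %d group/size combinations; completeness: %d; PA overlap rows: %d\n",
              length(x$rarefaction), length(x$completeness), nrow(x$pa_overlap)))
  if (length(x$notes)) cat(" notes:\n", paste(" -", x$notes, collapse = "\n"), "\n")
  invisible(x)
}

#' Write a run report's tables to CSV
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
writeReport <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) if (is.data.frame(df) && nrow(df))
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  wr(report$records, "records.csv")
  wr(report$congruence, "congruence.csv")
  wr(report$correlations, "correlations.csv")
  wr(report$pa_overlap, "pa_overlap.csv")
  for (nm in names(report$rarefaction))
    wr(report$rarefaction[[nm]]$table,
       paste0("rarefaction_", gsub("/", "_", nm), ".csv"))
  for (nm in names(report$completeness))
    wr(report$completeness[[nm]]$table,
       paste0("completeness_", gsub("/", "_", nm), ".csv"))
  for (nm in names(report$metrics))
    wr(as.data.frame(report$metrics[[nm]]),
       paste0("metrics_", gsub("/", "_", nm), ".csv"))
  if (length(report$notes))
    writeLines(report$notes, file.path(dir, "notes.txt"))
  invisible(dir)
}
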