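# Per-cell diversity and vulnerability metrics: sampling effort, species
# richness, range-size-weighted endemism, threatened-species number/proportion.

#' Per-cell sampling effort
#'
#' Number of (deduplicated) records in each non-empty-area cell of the grid.
#'
#' @param grid An `analysis_grid`.
#' @param assignment An [assignCells()] vector.
#' @return Named integer vector over `grid$cells$cell` (zeros included).
#' @export
cellEffort <- function(grid, assignment) {
  stopifnot(inherits(grid, "analysis_grid"))
  tab <- table(factor(assignment[!is.na(assignment)], levels = grid$cells$cell))
  stats::setNames(as.integer(tab), grid$cells$cell)
}

#' Per-cell species richness
#'
#' Count of distinct species with at least one record in each cell.
#'
#' @param occ An `occurrence_set`.
#' @param grid An `analysis_grid`.
#' @param assignment An [assignCells()] vector for `occ` on `grid`.
#' @return Named integer vector over `grid$cells$cell`.
#' @export
speciesRichness <- function(occ, grid, assignment) {
  stopifnot(inherits(occ, "occurrence_set"), inherits(grid, "analysis_grid"))
  keep <- !is.na(assignment)
  sr <- stats::setNames(integer(nrow(grid$cells)), grid$cells$cell)
  if (any(keep)) {
    u <- unique(data.frame(cell = assignment[keep], species = occ$species[keep]))
    tab <- table(factor(u$cell, levels = grid$cells$cell))
    sr[] <- as.integer(tab)
  }
  sr
}

#' Per-cell weighted endemism (range-size-weighted richness)
#'
#' For each species j occupying `m_j` cells, every occupied cell receives
#' weight `q_ij = 1/m_j`; a cell's endemism is the sum of the weights of the
#' species present there. Species found in a single cell contribute 1 to it;
#' widespread species are diluted across their occupied cells, so the metric
#' highlights restricted-range (endemic-like) taxa. Endemism mass is
#' conserved: the map sums to the number of species with at least one
#' assigned record.
#'
#' @inheritParams speciesRichness
#' @return Named numeric vector over `grid$cells$cell`.
#' @export
weightedEndemism <- function(occ, grid, assignment) {
  stopifnot(inherits(occ, "occurrence_set"), inherits(grid, "analysis_grid"))
  E <- stats::setNames(numeric(nrow(grid$cells)), grid$cells$cell)
  keep <- !is.na(assignment)
  if (!any(keep)) return(E)
  u <- unique(data.frame(cell = assignment[keep], species = occ$species[keep]))
  occ_cells <- table(u$species)              # m_j: cells occupied by species j
  w <- 1 / as.numeric(occ_cells[u$species])  # q_ij for each (species, cell)
  sums <- tapply(w, factor(u$cell, levels = grid$cells$cell), sum)
  sums[is.na(sums)] <- 0
  E[] <- as.numeric(sums)
  E
}

#' Per-cell threatened-species number and proportion
#'
#' `TSN` counts the distinct species in a cell assessed CR, EN or VU at the
#' requested level; `TSP = TSN / SR` (0 when the cell holds species but none
#' threatened; `NA` for cells without records). National-level metrics exist
#' only for groups with a national red list (amphibians, reptiles, birds):
#' requesting them for mammals or for multi-class (tetrapods-combined) data
#' raises a "no national assessment" error, mirroring the maps left grey for
#' those groups.
#'
#' @inheritParams speciesRichness
#' @param level `"global"` or `"national"`.
#' @return List with named vectors `TSN` (integer) and `TSP` (numeric, `NA`
#'   for empty cells).
#' @export
threatenedMetrics <- function(occ, grid, assignment, level = c("global", "national")) {
  level <- match.arg(level)
  stopifnot(inherits(occ, "occurrence_set"), inherits(grid, "analysis_grid"))
  if (level == "national") {
    groups <- unique(occ$class_group)
    if (length(groups) > 1L)
      stop("no national assessment for tetrapods combined; use level = \"global\"")
    if (identical(groups, "Mammalia"))
      stop("no national assessment for Mammalia")
  }
  status <- if (level == "global") occ$status_global else occ$status_national
  keep <- !is.na(assignment)
  TSN <- stats::setNames(integer(nrow(grid$cells)), grid$cells$cell)
  if (any(keep)) {
    u <- unique(data.frame(cell = assignment[keep], species = occ$species[keep],
                           thr = isThreatened(status)[keep]))
    # a species is threatened or not irrespective of cell; dedup keeps that
    tab <- table(factor(u$cell[u$thr], levels = grid$cells$cell))
    TSN[] <- as.integer(tab)
  }
  SR <- speciesRichness(occ, grid, assignment)
  TSP <- ifelse(SR > 0, TSN / SR, NA_real_)
  names(TSP) <- names(TSN)
  list(TSN = TSN, TSP = TSP)
}

#' Per-cell metric table
#'
#' Computes the full per-cell table: clipped area, sampling effort, species
#' richness `SR`, weighted endemism `E`, and threatened-species number and
#' proportion under the global (`TSN_g`, `TSP_g`) and — where a national
#' assessment exists (single non-mammal class group) — national (`TSN_n`,
#' `TSP_n`) red lists. National columns are `NA` sentinels otherwise.
#'
#' @param occ An `occurrence_set` (ideally deduplicated).
#' @param grid An `analysis_grid`.
#' @param assignment Optional precomputed [assignCells()] vector.
#' @return A `cell_metric_table`: data frame keyed by (`cell`, `col`, `row`)
#'   with columns `area_km2`, `effort`, `SR`, `E`, `TSN_g`, `TSP_g`, `TSN_n`,
#'   `TSP_n`.
#' @export
cellMetrics <- function(occ, grid, assignment = NULL) {
  stopifnot(inherits(occ, "occurrence_set"), inherits(grid, "analysis_grid"))
  if (is.null(assignment)) assignment <- assignCells(occ, grid)
  eff <- cellEffort(grid, assignment)
  SR <- speciesRichness(occ, grid, assignment)
  E <- weightedEndemism(occ, grid, assignment)
  tg <- threatenedMetrics(occ, grid, assignment, "global")
  groups <- unique(occ$class_group)
  national_ok <- length(groups) == 1L && groups != "Mammalia" && nrow(occ) > 0L
  if (national_ok) {
    tn <- threatenedMetrics(occ, grid, assignment, "national")
  } else {
    tn <- list(TSN = rep(NA_integer_, nrow(grid$cells)),
               TSP = rep(NA_real_, nrow(grid$cells)))
  }
  out <- data.frame(grid$cells[, c("cell", "col", "row", "area_km2")],
                    effort = as.integer(eff), SR = as.integer(SR), E = as.numeric(E),
                    TSN_g = as.integer(tg$TSN), TSP_g = as.numeric(tg$TSP),
                    TSN_n = as.integer(tn$TSN), TSP_n = as.numeric(tn$TSP))
  class(out) <- c("cell_metric_table", "data.frame")
  out
}

#' @export
print.cell_metric_table <- function(x, ...) {
  cat(sprintf("cell_metric_table: %d cells, %d sampled, total SR-weighted endemism %.3f\n",
              nrow(x), sum(x$effort > 0), sum(x$E)))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  invisible(x)
}
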