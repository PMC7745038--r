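# Square analysis grids over a country polygon, record-to-cell assignment,
# 1 km sub-grids for incidence sampling, and sampled/unsampled area accounting.

#' Build a square analysis grid over a country polygon
#'
#' Lays half-open square cells `[x0 + c*s, x0 + (c+1)*s) x [y0 + r*s, y0 +
#' (r+1)*s)` over the country's bounding box and intersects every cell with
#' the country polygon. Cells whose clipped area is zero (entirely outside)
#' are dropped; partially covered cells keep their clipped area for area
#' accounting but their full square extent for point assignment. The default
#' origin is the lower-left corner of the country's bounding box — results
#' are reproducible given (CRS, origin, cell size), which are therefore part
#' of the grid object.
#'
#' @param country A `geo_polygon` in planar metres.
#' @param cell_size Cell side in metres (the canonical analysis resolutions
#'   are 12500, 25000 and 50000).
#' @param origin Optional `c(x0, y0)` grid origin in metres.
#' @param crs_tag Label of the planar system; must match the occurrence data.
#' @return An `analysis_grid`: list with `origin`, `cell_size`, `n_cols`,
#'   `n_rows`, `crs_tag`, `country`, `country_area_km2` and `cells`, a data
#'   frame with one row per non-empty cell (`cell` integer key, `col`, `row`
#'   0-based indices, `area_km2` clipped area, `cx`, `cy` full-square
#'   centroid).
#' @export
buildGrid <- function(country, cell_size, origin = NULL, crs_tag = "local-metres") {
  stopifnot(inherits(country, "geo_polygon"))
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a positive number of metres")
  carea <- polygonArea(country)
  if (carea <= 0) stop("empty country polygon")
  bb <- polygonBBox(country)
  if (is.null(origin)) origin <- c(bb[["xmin"]], bb[["ymin"]])
  n_cols <- ceiling((bb[["xmax"]] - origin[1L]) / cell_size)
  n_rows <- ceiling((bb[["ymax"]] - origin[2L]) / cell_size)
  # points on the upper bbox edge fall in the next half-open cell
  if (origin[1L] + n_cols * cell_size <= bb[["xmax"]]) n_cols <- n_cols + 1L
  if (origin[2L] + n_rows * cell_size <= bb[["ymax"]]) n_rows <- n_rows + 1L
  stopifnot(n_cols >= 1L, n_rows >= 1L)
  grid_idx <- expand.grid(col = 0:(n_cols - 1L), row = 0:(n_rows - 1L))
  areas <- vapply(seq_len(nrow(grid_idx)), function(i) {
    x0 <- origin[1L] + grid_idx$col[i] * cell_size
    y0 <- origin[2L] + grid_idx$row[i] * cell_size
    polygonRectArea(country, x0, y0, x0 + cell_size, y0 + cell_size)
  }, 0)
  if (abs(sum(areas) - carea) > 1e-6 * carea)
    stop("clipped cell areas do not sum to the country area (grid does not cover it)")
  keep <- areas > 0
  cells <- data.frame(
    cell = grid_idx$col[keep] + grid_idx$row[keep] * n_cols + 1L,
    col = grid_idx$col[keep], row = grid_idx$row[keep],
    area_km2 = areas[keep] / 1e6,
    cx = origin[1L] + (grid_idx$col[keep] + 0.5) * cell_size,
    cy = origin[2L] + (grid_idx$row[keep] + 0.5) * cell_size)
  structure(list(origin = as.numeric(origin), cell_size = cell_size,
                 n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
                 crs_tag = crs_tag, country = country,
                 country_area_km2 = carea / 1e6, cells = cells),
            class = "analysis_grid")
}

#' @export
print.analysis_grid <- function(x, ...) {
  cat(sprintf("analysis_grid: %.0f m cells, %d x %d lattice, %d non-empty cells, country %.1f km^2\n",
              x$cell_size, x$n_cols, x$n_rows, nrow(x$cells), x$country_area_km2))
  invisible(x)
}

#' Assign occurrence records to grid cells
#'
#' Half-open interval arithmetic: a record at `(x, y)` falls in cell
#' `(floor((x - x0)/s), floor((y - y0)/s))`; a point exactly on a cell's
#' upper boundary belongs to the next cell. Records outside the gridded
#' lattice, or inside cells dropped for zero clipped area, are flagged
#' "outside" (`NA`) and excluded from per-cell tallies.
#'
#' @param occ An `occurrence_set` in the grid's CRS.
#' @param grid An `analysis_grid`.
#' @return Integer vector of cell keys (matching `grid$cells$cell`), `NA` for
#'   outside records; attribute `n_outside` counts them.
#' @export
assignCells <- function(occ, grid) {
  stopifnot(inherits(occ, "occurrence_set"), inherits(grid, "analysis_grid"))
  if (!identical(attr(occ, "crs_tag"), grid$crs_tag))
    stop("CRS mismatch: occurrences '", attr(occ, "crs_tag"),
         "' vs grid '", grid$crs_tag, "'")
  col <- floor((occ$x - grid$origin[1L]) / grid$cell_size)
  row <- floor((occ$y - grid$origin[2L]) / grid$cell_size)
  inside <- col >= 0 & col < grid$n_cols & row >= 0 & row < grid$n_rows
  key <- ifelse(inside, col + row * grid$n_cols + 1L, NA_integer_)
  key[!is.na(key) & !(key %in% grid$cells$cell)] <- NA_integer_
  structure(as.integer(key), n_outside = sum(is.na(key)))
}

#' Sub-grid incidence of species within one cell
#'
#' Tiles a cell with square sub-cells (the cell size must be divisible by the
#' sub-cell size) and records, for each species, the set of sub-cells where
#' it occurs. The incidence count of species j is the number of sub-cells
#' holding at least one of its records — repeated records in one sub-cell
#' collapse to a single incidence.
#'
#' @param occ An `occurrence_set` (typically one class group).
#' @param grid An `analysis_grid`.
#' @param cell Integer cell key (a value of `grid$cells$cell`).
#' @param sub_size Sub-cell side in metres (default 1000). Must divide
#'   `grid$cell_size`; for resolutions it does not divide (e.g. 12.5 km),
#'   supply a divisor explicitly.
#' @param assignment Optional precomputed [assignCells()] vector.
#' @return A `sub_grid`: list with `cell`, `sub_size`, `n_sub` (sub-cells per
#'   side), `T` (sub-cells with >= 1 record), and `incidence`, a named integer
#'   vector of per-species incidence counts `Y_j`.
#' @export
subgridIncidence <- function(occ, grid, cell, sub_size = 1000, assignment = NULL) {
  stopifnot(inherits(grid, "analysis_grid"))
  if (grid$cell_size %% sub_size != 0)
    stop("cell_size (", grid$cell_size, " m) is not divisible by sub_size (",
         sub_size, " m); choose a divisor explicitly")
  if (!cell %in% grid$cells$cell) stop("no such non-empty cell: ", cell)
  if (is.null(assignment)) assignment <- assignCells(occ, grid)
  idx <- which(!is.na(assignment) & assignment == cell)
  n_sub <- as.integer(grid$cell_size / sub_size)
  if (!length(idx)) {
    return(structure(list(cell = cell, sub_size = sub_size, n_sub = n_sub,
                          T = 0L, incidence = integer(0)), class = "sub_grid"))
  }
  ccol <- (cell - 1L) %% grid$n_cols
  crow <- (cell - 1L) %/% grid$n_cols
  x0 <- grid$origin[1L] + ccol * grid$cell_size
  y0 <- grid$origin[2L] + crow * grid$cell_size
  sc <- floor((occ$x[idx] - x0) / sub_size)
  sr <- floor((occ$y[idx] - y0) / sub_size)
  sc <- pmin(pmax(sc, 0L), n_sub - 1L)  # guard FP edge on the cell boundary
  sr <- pmin(pmax(sr, 0L), n_sub - 1L)
  sub <- sc + sr * n_sub
  pres <- unique(data.frame(species = occ$species[idx], sub = sub))
  inc <- table(pres$species)
  structure(list(cell = cell, sub_size = sub_size, n_sub = n_sub,
                 T = length(unique(sub)),
                 incidence = stats::setNames(as.integer(inc), names(inc))),
            class = "sub_grid")
}

#' Unsampled area of a grid
#'
#' Sums the clipped areas of cells with zero assigned records and expresses
#' it also as a percentage of the country area.
#'
#' @param grid An `analysis_grid`.
#' @param assignment An [assignCells()] vector for the records of interest.
#' @return Named numeric `c(km2, percent)`.
#' @export
unsampledArea <- function(grid, assignment) {
  stopifnot(inherits(grid, "analysis_grid"))
  occupied <- unique(assignment[!is.na(assignment)])
  empty <- !(grid$cells$cell %in% occupied)
  km2 <- sum(grid$cells$area_km2[empty])
  c(km2 = km2, percent = 100 * km2 / grid$country_area_km2)
}

#' Export an analysis grid as GeoJSON cell polygons
#'
#' One MultiPolygon feature per non-empty cell, with properties `cell`,
#' `col`, `row` and `area_km2`.
#'
#' @param grid An `analysis_grid`.
#' @param path Output GeoJSON path.
#' @return Invisibly, `path`.
#' @export
writeGridGeoJSON <- function(grid, path) {
  stopifnot(inherits(grid, "analysis_grid"))
  polys <- lapply(seq_len(nrow(grid$cells)), function(i) {
    x0 <- grid$origin[1L] + grid$cells$col[i] * grid$cell_size
    y0 <- grid$origin[2L] + grid$cells$row[i] * grid$cell_size
    rectPolygon(x0, y0, x0 + grid$cell_size, y0 + grid$cell_size)
  })
  writeGeoJSON(polys, path, properties = grid$cells[, c("cell", "col", "row", "area_km2")])
}
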