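# Hotspot selection on a per-cell metric gradient, the congruence sweep across
# hotspot definitions, and protected-area overlap of hotspot cells.

#' Select hotspot cells: the top d% of non-empty cells
#'
#' Cells without records are removed first; the remaining cells are sorted
#' from high to low metric value and the top `k = ceiling(d/100 * n_nonempty)`
#' are selected. Ties at the cut are broken deterministically by ascending
#' cell key, which makes selections nested across definitions.
#'
#' @param values Named numeric vector of the metric over the *non-empty*
#'   cells (names are cell keys). `NA` values are not allowed.
#' @param d Hotspot definition in percent, in (0, 100].
#' @return A `hotspot_selection`: list with `metric` values used, `d`, `k`,
#'   `n_nonempty` and `cells` (character vector of selected cell keys).
#' @export
selectHotspots <- function(values, d) {
  if (!length(values)) stop("no non-empty cells to select from")
  if (is.null(names(values)) || anyNA(values))
    stop("values must be a named, NA-free vector over non-empty cells")
  if (!is.numeric(d) || length(d) != 1L || d <= 0 || d > 100)
    stop("d must be a percentage in (0, 100]")
  n <- length(values)
  k <- min(ceiling(d / 100 * n), n)
  ord <- order(-values, as.numeric(names(values)))
  structure(list(d = d, k = k, n_nonempty = n,
                 cells = names(values)[ord[seq_len(k)]]),
            class = "hotspot_selection")
}

#' @export
print.hotspot_selection <- function(x, ...) {
  cat(sprintf("hotspot_selection: top %.1f%% -> %d of %d non-empty cells\n",
              x$d, x$k, x$n_nonempty))
  invisible(x)
}

#' Congruence of two or more hotspot selections
#'
#' The percentage of matching cells over the unique cells: `100 *
#' |intersection| / |union|` across all selections. Cells count as matching
#' only when selected by every metric under comparison.
#'
#' @param selections List of `hotspot_selection`s at the same definition `d`,
#'   drawn from the same grid universe.
#' @return Congruence percentage in `[0, 100]`.
#' @export
congruence <- function(selections) {
  stopifnot(length(selections) >= 2L,
            all(vapply(selections, inherits, TRUE, "hotspot_selection")))
  ds <- vapply(selections, `[[`, 0, "d")
  if (length(unique(ds)) != 1L) stop("selections use different definitions d")
  ns <- vapply(selections, `[[`, 0, "n_nonempty")
  if (length(unique(ns)) != 1L)
    stop("selections drawn from different cell universes")
  sets <- lapply(selections, `[[`, "cells")
  inter <- Reduce(intersect, sets)
  uni <- Reduce(union, sets)
  if (!length(uni)) return(NA_real_)
  100 * length(inter) / length(uni)
}

#' Congruence curve across hotspot definitions
#'
#' Sweeps the hotspot definition from `0.5` to `100` percent in steps of
#' `0.5` and evaluates the congruence of the given metrics at each step.
#'
#' @param metrics Named list (>= 2) of named numeric vectors: each a per-cell
#'   metric over the same non-empty-cell universe.
#' @param d_seq Definition grid in percent (default `seq(0.5, 100, 0.5)`).
#' @return A `congruence_curve` data frame with columns `d` and `congruence`;
#'   attributes `at_2.5` and `at_10` hold the two canonical summary values.
#' @export
congruenceCurve <- function(metrics, d_seq = seq(0.5, 100, by = 0.5)) {
  stopifnot(is.list(metrics), length(metrics) >= 2L)
  nm <- lapply(metrics, names)
  if (!all(vapply(nm[-1L], identical, TRUE, nm[[1L]])))
    stop("all metrics must be defined over the same non-empty cells")
  vals <- vapply(d_seq, function(d)
    congruence(lapply(metrics, selectHotspots, d = d)), 0)
  out <- data.frame(d = d_seq, congruence = vals)
  class(out) <- c("congruence_curve", "data.frame")
  at <- function(dd) if (dd %in% d_seq) vals[match(dd, d_seq)] else
    congruence(lapply(metrics, selectHotspots, d = dd))
  attr(out, "at_2.5") <- at(2.5)
  attr(out, "at_10") <- at(10)
  out
}

#' @export
print.congruence_curve <- function(x, ...) {
  cat(sprintf("congruence_curve: %d definitions; 2.5%% -> %.1f%%, 10%% -> %.1f%%, 100%% -> %.1f%%\n",
              nrow(x), attr(x, "at_2.5"), attr(x, "at_10"),
              x$congruence[nrow(x)]))
  invisible(x)
}

#' Protected-area overlap of a hotspot selection
#'
#' Percentage of the selected cells whose full square geometry intersects at
#' least one protected-area polygon. "At least partially covered" is the
#' criterion, so any shared point — including a boundary-only contact —
#' counts.
#'
#' @param selection A `hotspot_selection`.
#' @param pas A `geo_polygon` (possibly multi-part) or list of them.
#' @param grid The `analysis_grid` the selection was drawn from.
#' @return Percentage in `[0, 100]`.
#' @export
paOverlap <- function(selection, pas, grid) {
  stopifnot(inherits(selection, "hotspot_selection"), inherits(grid, "analysis_grid"))
  if (inherits(pas, "geo_polygon")) pas <- list(pas)
  if (!length(selection$cells)) stop("empty hotspot selection")
  covered <- vapply(selection$cells, function(key) {
    key <- as.numeric(key)
    ccol <- (key - 1) %% grid$n_cols
    crow <- (key - 1) %/% grid$n_cols
    x0 <- grid$origin[1L] + ccol * grid$cell_size
    y0 <- grid$origin[2L] + crow * grid$cell_size
    any(vapply(pas, polygonIntersectsRect, TRUE,
               xmin = x0, ymin = y0,
               xmax = x0 + grid$cell_size, ymax = y0 + grid$cell_size))
  }, TRUE)
  100 * mean(covered)
}

#' Export a hotspot selection as GeoJSON
#'
#' @param selection A `hotspot_selection`.
#' @param grid The source `analysis_grid`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeHotspotsGeoJSON <- function(selection, grid, path) {
  stopifnot(inherits(selection, "hotspot_selection"), inherits(grid, "analysis_grid"))
  keys <- as.numeric(selection$cells)
  polys <- lapply(keys, function(key) {
    ccol <- (key - 1) %% grid$n_cols
    crow <- (key - 1) %/% grid$n_cols
    x0 <- grid$origin[1L] + ccol * grid$cell_size
    y0 <- grid$origin[2L] + crow * grid$cell_size
    rectPolygon(x0, y0, x0 + grid$cell_size, y0 + grid$cell_size)
  })
  writeGeoJSON(polys, path,
               properties = data.frame(cell = keys, d = selection$d))
}
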