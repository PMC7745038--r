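# Planar polygon utilities used by the gridding and hotspot modules.
# Coordinates are metres in a projected planar system; polygons follow the
# GeoJSON ring model: a part is a list of rings (first outer, rest holes),
# a geo_polygon is a list of parts (multi-part allowed).

#' Construct a planar polygon
#'
#' Builds a `geo_polygon`: a (multi-part) polygon in planar metre coordinates.
#' Each part is a list of rings; each ring a two-column numeric matrix of
#' vertices (not necessarily closed — closure is implicit). The first ring of
#' a part is the outer boundary, subsequent rings are holes.
#'
#' @param parts A list of parts, each a list of two-column vertex matrices,
#'   or a single ring matrix (promoted to one single-ring part).
#' @return An object of class `geo_polygon`.
#' @export
#' @examples
#' sq <- geoPolygon(cbind(c(0, 1e3, 1e3, 0), c(0, 0, 1e3, 1e3)))
#' polygonArea(sq)  # 1 km^2 in m^2
geoPolygon <- function(parts) {
  if (is.matrix(parts)) parts <- list(list(parts))
  if (length(parts) && is.matrix(parts[[1L]])) parts <- list(parts)
  parts <- lapply(parts, function(part) lapply(part, function(r) {
    r <- as.matrix(r)
    if (ncol(r) != 2L || nrow(r) < 3L)
      stop("each ring must be a matrix with >= 3 vertices and 2 columns")
    storage.mode(r) <- "double"
    # drop an explicitly closed final vertex
    if (isTRUE(all(r[1L, ] == r[nrow(r), ])) && nrow(r) > 3L) r <- r[-nrow(r), , drop = FALSE]
    if (any(!is.finite(r))) stop("non-finite polygon coordinates")
    r
  }))
  structure(list(parts = parts), class = "geo_polygon")
}

#' @export
print.geo_polygon <- function(x, ...) {
  nr <- sum(vapply(x$parts, length, 1L))
  cat(sprintf("geo_polygon: %d part(s), %d ring(s), area %.2f km^2\n",
              length(x$parts), nr, polygonArea(x) / 1e6))
  invisible(x)
}

#' Rectangle polygon helper
#'
#' @param xmin,ymin,xmax,ymax Rectangle bounds in metres.
#' @return A `geo_polygon` covering the rectangle.
#' @export
rectPolygon <- function(xmin, ymin, xmax, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  geoPolygon(cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax)))
}

# signed shoelace area of one ring (m^2)
ringSignedArea <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  sum(x * ys - xs * y) / 2
}

#' Polygon area
#'
#' Area of a (multi-part) polygon in square metres; hole rings subtract.
#'
#' @param poly A `geo_polygon`.
#' @return Numeric area in m^2.
#' @export
polygonArea <- function(poly) {
  stopifnot(inherits(poly, "geo_polygon"))
  total <- 0
  for (part in poly$parts) {
    a <- abs(ringSignedArea(part[[1L]]))
    if (length(part) > 1L)
      a <- a - sum(vapply(part[-1L], function(r) abs(ringSignedArea(r)), 0))
    total <- total + max(a, 0)
  }
  total
}

#' Bounding box of a polygon
#'
#' @param poly A `geo_polygon`.
#' @return Named numeric vector `c(xmin, ymin, xmax, ymax)`.
#' @export
polygonBBox <- function(poly) {
  stopifnot(inherits(poly, "geo_polygon"))
  xy <- do.call(rbind, unlist(poly$parts, recursive = FALSE))
  c(xmin = min(xy[, 1L]), ymin = min(xy[, 2L]),
    xmax = max(xy[, 1L]), ymax = max(xy[, 2L]))
}

# Sutherland-Hodgman clip of one ring against an axis-aligned rectangle.
# The rectangle is convex so the classic four-half-plane sweep is exact.
# Points on the boundary are kept (inside test uses >=/<=).
clipRingRect <- function(ring, xmin, ymin, xmax, ymax) {
  pts <- ring
  for (edge in 1:4) {
    n <- nrow(pts)
    if (is.null(pts) || n == 0L) return(NULL)
    inside <- switch(edge,
      pts[, 1L] >= xmin, pts[, 1L] <= xmax,
      pts[, 2L] >= ymin, pts[, 2L] <= ymax)
    out <- matrix(0, nrow = 2L * n, ncol = 2L)
    m <- 0L
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      p <- pts[i, ]; q <- pts[j, ]
      pin <- inside[i]; qin <- inside[j]
      if (pin) { m <- m + 1L; out[m, ] <- p }
      if (xor(pin, qin)) {
        # intersection with the clip line
        if (edge <= 2L) {
          xc <- if (edge == 1L) xmin else xmax
          t <- (xc - p[1L]) / (q[1L] - p[1L])
          m <- m + 1L; out[m, ] <- c(xc, p[2L] + t * (q[2L] - p[2L]))
        } else {
          yc <- if (edge == 3L) ymin else ymax
          t <- (yc - p[2L]) / (q[2L] - p[2L])
          m <- m + 1L; out[m, ] <- c(p[1L] + t * (q[1L] - p[1L]), yc)
        }
      }
    }
    if (m == 0L) return(NULL)
    pts <- out[seq_len(m), , drop = FALSE]
  }
  pts
}

#' Area of the intersection of a polygon with a rectangle
#'
#' Clips each ring to the rectangle (the rectangle is convex, so
#' Sutherland-Hodgman clipping is exact) and accumulates outer-ring area
#' minus hole area.
#'
#' @param poly A `geo_polygon`.
#' @param xmin,ymin,xmax,ymax Rectangle bounds in metres.
#' @return Intersection area in m^2.
#' @export
polygonRectArea <- function(poly, xmin, ymin, xmax, ymax) {
  stopifnot(inherits(poly, "geo_polygon"))
  total <- 0
  for (part in poly$parts) {
    outer <- clipRingRect(part[[1L]], xmin, ymin, xmax, ymax)
    if (is.null(outer) || nrow(outer) < 3L) next
    a <- abs(ringSignedArea(outer))
    if (length(part) > 1L) for (h in part[-1L]) {
      hc <- clipRingRect(h, xmin, ymin, xmax, ymax)
      if (!is.null(hc) && nrow(hc) >= 3L) a <- a - abs(ringSignedArea(hc))
    }
    total <- total + max(a, 0)
  }
  total
}

#' Does a polygon intersect a rectangle?
#'
#' True when the polygon and the rectangle share any point, including a
#' boundary-only contact (an edge or vertex touch counts).
#'
#' @inheritParams polygonRectArea
#' @return Logical scalar.
#' @export
polygonIntersectsRect <- function(poly, xmin, ymin, xmax, ymax) {
  stopifnot(inherits(poly, "geo_polygon"))
  if (polygonRectArea(poly, xmin, ymin, xmax, ymax) > 0) return(TRUE)
  # degenerate contacts: clipped ring retains vertices even at zero area
  for (part in poly$parts) {
    cl <- clipRingRect(part[[1L]], xmin, ymin, xmax, ymax)
    if (!is.null(cl) && nrow(cl) >= 1L) return(TRUE)
  }
  # rectangle entirely inside a hole would be caught above via outer ring
  corners <- cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
  any(pointInPolygon(corners[, 1L], corners[, 2L], poly))
}

#' Point-in-polygon test
#'
#' Even-odd ray-casting over all rings of all parts, so holes are respected.
#' Points exactly on an edge may fall on either side (grid assignment uses
#' half-open cell arithmetic, never this test, for records).
#'
#' @param x,y Numeric coordinate vectors (metres).
#' @param poly A `geo_polygon`.
#' @return Logical vector, TRUE where the point lies inside.
#' @export
pointInPolygon <- function(x, y, poly) {
  stopifnot(inherits(poly, "geo_polygon"), length(x) == length(y))
  inside <- logical(length(x))
  for (part in poly$parts) for (ring in part) {
    rx <- ring[, 1L]; ry <- ring[, 2L]
    n <- nrow(ring)
    j <- n
    for (i in seq_len(n)) {
      cross <- ((ry[i] > y) != (ry[j] > y)) &
        (x < (rx[j] - rx[i]) * (y - ry[i]) / (ry[j] - ry[i]) + rx[i])
      inside <- xor(inside, cross)
      j <- i
    }
  }
  inside
}

#' Read polygons from a GeoJSON file
#'
#' Accepts a Feature, FeatureCollection, Polygon or MultiPolygon. All polygonal
#' geometries are merged into one `geo_polygon` unless `split = TRUE`, in which
#' case a list of per-feature polygons is returned (with `properties`
#' attributes when present).
#'
#' @param path Path to a GeoJSON file.
#' @param split Return one polygon per feature instead of a merged polygon?
#' @return A `geo_polygon`, or a list of them when `split = TRUE`.
#' @export
readGeoJSON <- function(path, split = FALSE) {
  if (!file.exists(path)) stop("GeoJSON file not found: ", path)
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- switch(g$type,
    FeatureCollection = g$features,
    Feature = list(g),
    Polygon = , MultiPolygon = list(list(geometry = g, properties = NULL)),
    stop("unsupported GeoJSON type: ", g$type))
  polys <- lapply(feats, function(f) {
    geom <- f$geometry
    parts <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      NULL)
    if (is.null(parts)) return(NULL)
    p <- geoPolygon(lapply(parts, function(part)
      lapply(part, function(ring)
        do.call(rbind, lapply(ring, function(pt) c(pt[[1L]], pt[[2L]]))))))
    attr(p, "properties") <- f$properties
    p
  })
  polys <- polys[!vapply(polys, is.null, TRUE)]
  if (!length(polys)) stop("no polygonal features in ", path)
  if (split) return(polys)
  geoPolygon(unlist(lapply(polys, `[[`, "parts"), recursive = FALSE))
}

#' Write polygons to a GeoJSON file
#'
#' @param polys A `geo_polygon` or a list of them; each becomes a MultiPolygon
#'   feature. Per-feature properties may be supplied via `properties`, a list
#'   (or data.frame row set) parallel to `polys`.
#' @param path Output path.
#' @param properties Optional list/data.frame of per-feature properties.
#' @return Invisibly, `path`.
#' @export
writeGeoJSON <- function(polys, path, properties = NULL) {
  if (inherits(polys, "geo_polygon")) polys <- list(polys)
  feats <- lapply(seq_along(polys), function(i) {
    p <- polys[[i]]
    coords <- lapply(p$parts, function(part)
      lapply(part, function(ring) {
        ring <- rbind(ring, ring[1L, ])  # GeoJSON rings are closed
        lapply(seq_len(nrow(ring)), function(k) c(ring[k, 1L], ring[k, 2L]))
      }))
    props <- if (is.data.frame(properties)) as.list(properties[i, , drop = FALSE])
             else if (!is.null(properties)) properties[[i]]
             else attr(p, "properties")
    list(type = "Feature",
         properties = if (is.null(props)) structure(list(), names = character()) else props,
         geometry = list(type = "MultiPolygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Project longitude/latitude to local planar metres
#'
#' Equirectangular projection about a reference point: metric, rectangular
#' coordinates adequate at country scale (distance distortion grows with
#' latitude span). Used to bring geographic input onto the metre-based
#' analysis grids.
#'
#' @param lon,lat Numeric degree vectors.
#' @param lon0,lat0 Reference point (defaults: midpoint of the input range).
#' @param radius Earth radius in metres.
#' @return A two-column matrix (x, y) in metres; reference point maps to (0,0).
#' @export
lonlatToPlanar <- function(lon, lat, lon0 = NULL, lat0 = NULL, radius = 6378137) {
  if (is.null(lon0)) lon0 <- mean(range(lon, na.rm = TRUE))
  if (is.null(lat0)) lat0 <- mean(range(lat, na.rm = TRUE))
  k <- pi / 180
  cbind(x = radius * cos(lat0 * k) * (lon - lon0) * k,
        y = radius * (lat - lat0) * k)
}
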