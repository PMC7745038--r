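# Occurrence-record data model: reading, validation, deduplication, splitting.

THREAT_CODES <- c("CR", "EN", "VU", "NT", "LC", "DD", "NE")
THREATENED <- c("CR", "EN", "VU")
CLASS_GROUPS <- c("Amphibia", "Reptilia", "Aves", "Mammalia")

DEFAULT_COLUMN_MAP <- c(
  species = "scientificName", class_group = "classGroup",
  x = "x", y = "y", year = "year",
  status_global = "iucnGlobal", status_national = "iucnNational")

#' Construct an occurrence set
#'
#' An `occurrence_set` is a validated data frame of point occurrence records:
#' one row per observation of a species at planar coordinates, with an
#' observation year (possibly missing) and IUCN threat categories under the
#' global and the national assessment. Mammals carry no national assessment
#' (`NE`), mirroring the data situation the analyses assume.
#'
#' @param species Character vector of taxon identifiers (non-empty).
#' @param class_group Character vector; each of `"Amphibia"`, `"Reptilia"`,
#'   `"Aves"`, `"Mammalia"`.
#' @param x,y Numeric planar coordinates in metres (finite).
#' @param year Integer observation years; `NA` allowed.
#' @param status_global,status_national IUCN codes among
#'   `CR, EN, VU, NT, LC, DD, NE`; unknown or blank codes become `NE` (counted
#'   in the `n_unknown_status` attribute).
#' @param crs_tag Character label naming the planar reference system.
#' @return An `occurrence_set` (a data frame subclass) with attributes
#'   `crs_tag` and `n_unknown_status`.
#' @export
occurrenceSet <- function(species, class_group, x, y, year = NA_integer_,
                          status_global = "NE", status_national = "NE",
                          crs_tag = "local-metres") {
  n <- length(species)
  df <- data.frame(
    species = as.character(species),
    class_group = as.character(class_group),
    x = as.numeric(x), y = as.numeric(y),
    year = suppressWarnings(as.integer(rep_len(year, n))),
    status_global = as.character(rep_len(status_global, n)),
    status_national = as.character(rep_len(status_national, n)),
    stringsAsFactors = FALSE)
  n_unknown <- 0L
  for (col in c("status_global", "status_national")) {
    v <- toupper(trimws(df[[col]]))
    v[is.na(v) | v == ""] <- "NE"
    bad <- !(v %in% THREAT_CODES)
    n_unknown <- n_unknown + sum(bad)
    v[bad] <- "NE"
    df[[col]] <- v
  }
  if (any(!nzchar(df$species) | is.na(df$species)))
    stop("species identifiers must be non-empty")
  if (any(!df$class_group %in% CLASS_GROUPS))
    stop("class_group must be one of: ", paste(CLASS_GROUPS, collapse = ", "))
  if (any(!is.finite(df$x)) || any(!is.finite(df$y)))
    stop("coordinates must be finite numbers")
  # mammals have no national assessment
  mam <- df$class_group == "Mammalia" & df$status_national != "NE"
  if (any(mam)) {
    warning(sum(mam), " mammal record(s) carried a national category; reset to NE")
    df$status_national[mam] <- "NE"
  }
  structure(df, class = c("occurrence_set", "data.frame"),
            crs_tag = crs_tag, n_unknown_status = n_unknown)
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("occurrence_set: %d records, %d species, %d class group(s) [crs: %s]\n",
              nrow(x), length(unique(x$species)),
              length(unique(x$class_group)), attr(x, "crs_tag")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

# keep class/attributes through row subsetting
#' @export
`[.occurrence_set` <- function(x, i, ...) {
  out <- `[.data.frame`(as.data.frame(x), i, , drop = FALSE)
  structure(out, class = c("occurrence_set", "data.frame"),
            crs_tag = attr(x, "crs_tag"),
            n_unknown_status = attr(x, "n_unknown_status"))
}

#' Read occurrence records from CSV
#'
#' Reads a UTF-8 CSV with a header row, maps columns via `column_map`
#' (defaults: `scientificName, classGroup, x, y, year, iucnGlobal,
#' iucnNational`), validates rows and returns an [occurrenceSet()]. Rows with
#' unparsable coordinates or invalid class groups are rejected and reported in
#' the `validation` attribute (row index + reason); unknown threat codes map
#' to `NE` and are counted. Geographic input may instead carry
#' `decimalLongitude`/`decimalLatitude` columns: set `lonlat = TRUE` and the
#' coordinates are projected to local planar metres via [lonlatToPlanar()].
#'
#' @param path CSV file path.
#' @param column_map Named character vector overriding default column names;
#'   names are the canonical fields (`species`, `class_group`, `x`, `y`,
#'   `year`, `status_global`, `status_national`).
#' @param lonlat Interpret coordinate columns as lon/lat degrees and project?
#' @param lon0,lat0 Projection reference point (see [lonlatToPlanar()]).
#' @param crs_tag Label for the planar system of the returned set.
#' @return An `occurrence_set`; attribute `validation` is a data frame of
#'   rejected rows (columns `row`, `reason`), attribute `n_unknown_status`
#'   counts threat codes coerced to `NE`.
#' @export
readOccurrences <- function(path, column_map = NULL, lonlat = FALSE,
                            lon0 = NULL, lat0 = NULL, crs_tag = "local-metres") {
  if (!file.exists(path)) stop("occurrence CSV not found: ", path)
  cmap <- DEFAULT_COLUMN_MAP
  if (lonlat) { cmap[["x"]] <- "decimalLongitude"; cmap[["y"]] <- "decimalLatitude" }
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  if (!nrow(raw)) stop("empty occurrence table: ", path)
  mandatory <- c("species", "class_group", "x", "y")
  missing_cols <- cmap[mandatory][!cmap[mandatory] %in% names(raw)]
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  get <- function(field) {
    col <- cmap[[field]]
    if (col %in% names(raw)) raw[[col]] else rep(NA_character_, nrow(raw))
  }
  x <- suppressWarnings(as.numeric(get("x")))
  y <- suppressWarnings(as.numeric(get("y")))
  species <- trimws(get("species"))
  cls <- trimws(get("class_group"))
  reasons <- character(0); rows <- integer(0)
  flag <- function(bad, why) {
    rows <<- c(rows, which(bad)); reasons <<- c(reasons, rep(why, sum(bad)))
  }
  flag(is.na(x) | is.na(y), "unparsable coordinates")
  flag(!is.na(x) & !is.na(y) & (!is.finite(x) | !is.finite(y)), "non-finite coordinates")
  flag(is.na(species) | !nzchar(species), "empty species")
  flag(!cls %in% CLASS_GROUPS, "invalid class group")
  keep <- setdiff(seq_len(nrow(raw)), rows)
  if (!length(keep)) stop("no valid rows in ", path)
  if (lonlat) {
    xy <- lonlatToPlanar(x[keep], y[keep], lon0 = lon0, lat0 = lat0)
    px <- xy[, 1L]; py <- xy[, 2L]
  } else { px <- x[keep]; py <- y[keep] }
  occ <- occurrenceSet(
    species = species[keep], class_group = cls[keep], x = px, y = py,
    year = suppressWarnings(as.integer(get("year")[keep])),
    status_global = get("status_global")[keep],
    status_national = get("status_national")[keep],
    crs_tag = crs_tag)
  if (attr(occ, "n_unknown_status") > 0L)
    warning(attr(occ, "n_unknown_status"), " unknown threat code(s) mapped to NE")
  attr(occ, "validation") <- data.frame(row = rows, reason = reasons,
                                        stringsAsFactors = FALSE)
  occ
}

#' Write an occurrence set (and its validation report) to CSV
#'
#' Round-trips all fields using the default column names understood by
#' [readOccurrences()].
#'
#' @param occ An `occurrence_set`.
#' @param path Output CSV path.
#' @param validation_path Optional path for the validation report CSV.
#' @return Invisibly, `path`.
#' @export
writeOccurrences <- function(occ, path, validation_path = NULL) {
  stopifnot(inherits(occ, "occurrence_set"))
  out <- data.frame(
    scientificName = occ$species, classGroup = occ$class_group,
    x = occ$x, y = occ$y, year = occ$year,
    iucnGlobal = occ$status_global, iucnNational = occ$status_national,
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  if (!is.null(validation_path)) {
    v <- attr(occ, "validation")
    if (is.null(v)) v <- data.frame(row = integer(0), reason = character(0))
    utils::write.csv(v, validation_path, row.names = FALSE)
  }
  invisible(path)
}

#' Remove duplicated records per species, locality and year
#'
#' Retains one record per distinct `(species, x, y, year)` key, preserving
#' the original order of the kept records. Missing years form their own key
#' value, so two coordinate-identical records with unknown years collapse to
#' one. Coordinates are compared exactly by default; `precision` optionally
#' rounds them to that many decimal places for key construction only (record
#' coordinates are untouched).
#'
#' @param occ An `occurrence_set`.
#' @param precision Optional integer: decimal places used when building the
#'   coordinate part of the duplicate key. `NULL` (default) compares exactly.
#' @return The deduplicated `occurrence_set`, with attribute `n_removed`.
#' @export
deduplicate <- function(occ, precision = NULL) {
  stopifnot(inherits(occ, "occurrence_set"))
  kx <- occ$x; ky <- occ$y
  if (!is.null(precision)) { kx <- round(kx, precision); ky <- round(ky, precision) }
  key <- paste(occ$species,
               sprintf("%.17g", kx), sprintf("%.17g", ky),
               ifelse(is.na(occ$year), "unknown", occ$year), sep = "\r")
  keep <- !duplicated(key)
  out <- occ[keep, ]
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "validation") <- attr(occ, "validation")
  out
}

#' Split an occurrence set by tetrapod class
#'
#' Partitions the records into the four class groups; the union of the
#' outputs equals the input and the groups are pairwise disjoint.
#'
#' @param occ An `occurrence_set`.
#' @return Named list of four `occurrence_set`s
#'   (`Amphibia`, `Reptilia`, `Aves`, `Mammalia`), possibly empty.
#' @export
splitByClass <- function(occ) {
  stopifnot(inherits(occ, "occurrence_set"))
  out <- lapply(CLASS_GROUPS, function(g) occ[occ$class_group == g, ])
  names(out) <- CLASS_GROUPS
  out
}

#' Is a threat category "threatened"?
#'
#' Threatened means assessed CR, EN or VU; NT, LC, DD and NE are not.
#'
#' @param status Character vector of IUCN codes.
#' @return Logical vector.
#' @export
isThreatened <- function(status) status %in% THREATENED

#' Proportion of threatened species from counts
#'
#' The threatened-species proportion: the number of species assessed CR, EN
#' or VU divided by the total number of species `N`.
#'
#' @param n_threatened Count of CR + EN + VU species.
#' @param n_total Total species count `N` (> 0).
#' @return Proportion in `[0, 1]`.
#' @export
#' @examples
#' threatenedProportion(4, 50) * 100  # 8 percent
threatenedProportion <- function(n_threatened, n_total) {
  stopifnot(all(n_total > 0), all(n_threatened >= 0), all(n_threatened <= n_total))
  n_threatened / n_total
}
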