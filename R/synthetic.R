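# Synthetic occurrence-data generator with known ground truth: species ranges
# as discs with log-normal radii, city-biased sampling-effort surfaces,
# per-record years, and threat categories driven by range size.

#' Configuration for the synthetic occurrence generator
#'
#' Defaults emulate a data-poor, country-scale tetrapod database: a
#' rectangular country of 480 x 370 km (~177,600 km^2), a species pool of
#' 50 amphibians, 68 reptiles, 430 birds and 116 mammals, 69,364 records,
#' coastal-city-biased sampling effort, log-normal range-size variation, and
#' a logistic threat model where small-ranged species are likelier to be
#' threatened. Tests and examples use smaller `n_records`/`n_species`.
#'
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @param n_species Named integer vector of species per class group.
#' @param country_km `c(width, height)` of the rectangular country in km.
#' @param range_meanlog,range_sdlog Log-normal parameters of the species
#'   range-disc radius in metres (default median 45 km, sdlog 0.9).
#' @param effort_centres `NULL` or a data frame with columns `x`, `y`
#'   (metres), `weight`, `decay` (Gaussian sd, metres): sampling-bias centres.
#' @param effort_floor Weight of the uniform background component.
#' @param n_records Number of occurrence records to draw.
#' @param class_weights Relative per-species detection weight by class
#'   (emulates bird-heavy recording).
#' @param threat_intercept,threat_slope Logistic model
#'   `P(threatened) = plogis(intercept + slope * log(range area km^2))`;
#'   the default slope is negative in effect (small ranges more threatened).
#' @param national_extra Added to the intercept for the national-level draw
#'   (national lists flag more species); mammals get no national assessment.
#' @param year_range `c(min, max)` calendar years, sampled uniformly.
#' @param n_pa,pa_size_km Number and typical side (km) of rectangular
#'   protected areas.
#' @return A `synthetic_config` list.
#' @export
syntheticConfig <- function(seed = 1L,
                            n_species = c(Amphibia = 50L, Reptilia = 68L,
                                          Aves = 430L, Mammalia = 116L),
                            country_km = c(480, 370),
                            range_meanlog = log(45000), range_sdlog = 0.9,
                            effort_centres = NULL, effort_floor = 1,
                            n_records = 69364L,
                            class_weights = c(Amphibia = 1.5, Reptilia = 1,
                                              Aves = 4, Mammalia = 1),
                            threat_intercept = 4, threat_slope = -0.8,
                            national_extra = 0.9,
                            year_range = c(1950L, 2019L),
                            n_pa = 8L, pa_size_km = 15) {
  stopifnot(all(n_species >= 0), all(country_km > 0), n_records >= 0,
            effort_floor >= 0, range_sdlog >= 0,
            year_range[1L] <= year_range[2L])
  if (!all(CLASS_GROUPS %in% names(n_species)))
    stop("n_species must name all four class groups")
  if (!is.null(effort_centres)) {
    effort_centres <- as.data.frame(effort_centres)
    stopifnot(all(c("x", "y", "weight", "decay") %in% names(effort_centres)),
              all(effort_centres$decay > 0), all(effort_centres$weight >= 0))
    w_m <- country_km[1L] * 1000; h_m <- country_km[2L] * 1000
    if (any(effort_centres$x < 0 | effort_centres$x > w_m |
            effort_centres$y < 0 | effort_centres$y > h_m))
      stop("effort bias centres must lie inside the country rectangle")
  }
  diag_m <- sqrt(sum((country_km * 1000)^2))
  if (exp(range_meanlog) > 2 * diag_m)
    stop("infeasible config: median range radius exceeds twice the country diagonal")
  if (is.null(effort_centres) && effort_floor <= 0)
    stop("effort surface has no mass: no centres and zero floor")
  structure(list(seed = as.integer(seed), n_species = n_species,
                 country_km = country_km, range_meanlog = range_meanlog,
                 range_sdlog = range_sdlog, effort_centres = effort_centres,
                 effort_floor = effort_floor, n_records = as.integer(n_records),
                 class_weights = class_weights,
                 threat_intercept = threat_intercept, threat_slope = threat_slope,
                 national_extra = national_extra, year_range = year_range,
                 n_pa = as.integer(n_pa), pa_size_km = pa_size_km),
            class = "synthetic_config")
}

#' Preset sampling-bias scenarios
#'
#' Three effort surfaces: `"none"` (uniform effort), `"city"` (three bias
#' centres along the southern coast, mimicking collection concentrated around
#' coastal cities, plus a uniform floor), and `"extreme"` (~90% of records
#' drawn around a single coastal centre). Centre positions and decay lengths
#' scale with the country rectangle, so the presets work at any
#' `country_km`.
#'
#' @param level One of `"none"`, `"city"`, `"extreme"`.
#' @param ... Overrides passed to [syntheticConfig()].
#' @return A `synthetic_config`.
#' @export
biasScenario <- function(level = c("none", "city", "extreme"), ...) {
  level <- match.arg(level)
  dots <- list(...)
  ckm <- if (!is.null(dots$country_km)) dots$country_km
         else eval(formals(syntheticConfig)$country_km)
  w <- ckm[1L] * 1000; h <- ckm[2L] * 1000
  args <- switch(level,
    none = list(effort_centres = NULL, effort_floor = 1),
    city = list(
      effort_centres = data.frame(
        x = c(0.25, 0.5, 0.75) * w, y = c(0.055, 0.04, 0.07) * h,
        weight = c(1, 1.5, 1), decay = rep(w / 16, 3)),
      effort_floor = 0.15),
    extreme = list(
      effort_centres = data.frame(x = 0.5 * w, y = 0.04 * h,
                                  weight = 0.98, decay = w / 19),
      effort_floor = 0.02))
  do.call(syntheticConfig, utils::modifyList(args, dots))
}

# draw n locations from the effort surface, truncated to the country rectangle
sampleEffortSurface <- function(n, config) {
  w <- config$country_km[1L] * 1000
  h <- config$country_km[2L] * 1000
  ec <- config$effort_centres
  weights <- c(config$effort_floor, if (is.null(ec)) NULL else ec$weight)
  comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  x <- numeric(n); y <- numeric(n)
  unif <- comp == 1L
  x[unif] <- stats::runif(sum(unif), 0, w)
  y[unif] <- stats::runif(sum(unif), 0, h)
  if (!is.null(ec)) for (i in seq_len(nrow(ec))) {
    sel <- which(comp == i + 1L)
    if (!length(sel)) next
    cx <- ec$x[i]; cy <- ec$y[i]; s <- ec$decay[i]
    px <- stats::rnorm(length(sel), cx, s)
    py <- stats::rnorm(length(sel), cy, s)
    bad <- px < 0 | px > w | py < 0 | py > h
    while (any(bad)) {  # truncate by resampling
      px[bad] <- stats::rnorm(sum(bad), cx, s)
      py[bad] <- stats::rnorm(sum(bad), cy, s)
      bad <- px < 0 | px > w | py < 0 | py > h
    }
    x[sel] <- px; y[sel] <- py
  }
  cbind(x, y)
}

#' Generate a synthetic occurrence dataset with ground truth
#'
#' Draw order (one global stream seeded from `config$seed`): (1) species
#' range placement — disc centres uniform in the country, radii log-normal;
#' (2) threat labels from the logistic range-size model; (3) record draws —
#' a location from the effort surface, then a species among those whose
#' range disc covers the location (weighted by class detection weight;
#' locations covered by no range are redrawn); (4) record years. Every record
#' falls inside its species' true range by construction.
#'
#' @param config A [syntheticConfig()].
#' @param out_dir Optional directory: writes `occurrences.csv`,
#'   `country.geojson`, `pas.geojson` and `truth.json`.
#' @return A `synthetic_dataset` list: `occ` (an `occurrence_set`), `country`
#'   and `pas` (`geo_polygon`s; `pas` a list), and `truth` (per-species true
#'   centres, radii, range areas and labels, plus the config).
#' @export
simulateOccurrences <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  w <- config$country_km[1L] * 1000
  h <- config$country_km[2L] * 1000
  country <- rectPolygon(0, 0, w, h)

  # 1) species pool and ranges
  cls <- rep(CLASS_GROUPS, times = config$n_species[CLASS_GROUPS])
  S <- length(cls)
  if (S == 0L) stop("empty species pool")
  sp_id <- sprintf("%s_sp%04d", substr(cls, 1, 3), stats::ave(seq_len(S), cls, FUN = seq_along))
  cx <- stats::runif(S, 0, w)
  cy <- stats::runif(S, 0, h)
  radius <- stats::rlnorm(S, config$range_meanlog, config$range_sdlog)
  # true range area: disc clipped to the country (km^2), via the exact
  # circle-rectangle overlap is overkill; the threat model only needs a
  # monotone size measure, so use min(disc, country) area
  area_km2 <- pmin(pi * radius^2, w * h) / 1e6

  # 2) threat labels, decreasing in range size
  lp <- config$threat_intercept + config$threat_slope * log(area_km2)
  thr_g <- stats::runif(S) < stats::plogis(lp)
  cat_thr <- function(n) sample(c("CR", "EN", "VU"), n, replace = TRUE,
                                prob = c(0.2, 0.3, 0.5))
  cat_ok <- function(n) sample(c("NT", "LC", "DD"), n, replace = TRUE,
                               prob = c(0.1, 0.8, 0.1))
  status_global <- character(S)
  status_global[thr_g] <- cat_thr(sum(thr_g))
  status_global[!thr_g] <- cat_ok(sum(!thr_g))
  thr_n <- stats::runif(S) < stats::plogis(lp + config$national_extra)
  status_national <- character(S)
  status_national[thr_n] <- cat_thr(sum(thr_n))
  status_national[!thr_n] <- cat_ok(sum(!thr_n))
  status_national[cls == "Mammalia"] <- "NE"

  # 3) records: effort-surface locations, species by coverage
  n <- config$n_records
  rx <- numeric(n); ry <- numeric(n); rsp <- integer(n)
  todo <- seq_len(n)
  wcls <- log(config$class_weights[cls])
  guard <- 0L
  while (length(todo)) {
    guard <- guard + 1L
    if (guard > 1000L)
      stop("infeasible config: effort surface repeatedly misses all species ranges")
    loc <- sampleEffortSurface(length(todo), config)
    # chunked coverage test + Gumbel-max categorical pick among covering species
    pick <- integer(length(todo))
    chunk <- 4000L
    for (s0 in seq(1L, length(todo), by = chunk)) {
      s1 <- min(s0 + chunk - 1L, length(todo))
      idx <- s0:s1
      d2 <- outer(loc[idx, 1L], cx, "-")^2 + outer(loc[idx, 2L], cy, "-")^2
      covers <- d2 <= rep(radius^2, each = length(idx))
      score <- matrix(rep(wcls, each = length(idx)), nrow = length(idx)) -
        log(-log(stats::runif(length(idx) * S)))
      score[!covers] <- -Inf
      p <- max.col(score, ties.method = "first")
      p[!covers[cbind(seq_along(idx), p)]] <- 0L  # no covering species
      pick[idx] <- p
    }
    ok <- pick > 0L
    done <- todo[ok]
    rx[done] <- loc[ok, 1L]; ry[done] <- loc[ok, 2L]; rsp[done] <- pick[ok]
    todo <- todo[!ok]
  }

  # 4) years
  years <- sample(seq.int(config$year_range[1L], config$year_range[2L]),
                  n, replace = TRUE)

  occ <- occurrenceSet(
    species = sp_id[rsp], class_group = cls[rsp], x = rx, y = ry, year = years,
    status_global = status_global[rsp], status_national = status_national[rsp],
    crs_tag = "synthetic-metres")

  # protected areas: random rectangles clipped to the country
  pas <- lapply(seq_len(config$n_pa), function(i) {
    px <- stats::runif(1, 0, w); py <- stats::runif(1, 0, h)
    half <- config$pa_size_km * 1000 / 2 * stats::rlnorm(1, 0, 0.3)
    rectPolygon(max(px - half, 0), max(py - half, 0),
                min(px + half, w), min(py + half, h))
  })

  truth <- list(
    species = data.frame(species = sp_id, class_group = cls, cx = cx, cy = cy,
                         radius_m = radius, range_area_km2 = area_km2,
                         status_global = status_global,
                         status_national = status_national,
                         stringsAsFactors = FALSE),
    config = unclass(config))

  out <- structure(list(occ = occ, country = country, pas = pas, truth = truth),
                   class = "synthetic_dataset")
  if (!is.null(out_dir)) writeSimulation(out, out_dir)
  out
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d records, %d species, country %.0f km^2, %d protected areas\n",
              nrow(x$occ), nrow(x$truth$species),
              polygonArea(x$country) / 1e6, length(x$pas)))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes `occurrences.csv`, `country.geojson`, `pas.geojson` and
#' `truth.json` under `dir`.
#'
#' @param sim A `synthetic_dataset`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
writeSimulation <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeOccurrences(sim$occ, file.path(dir, "occurrences.csv"))
  writeGeoJSON(sim$country, file.path(dir, "country.geojson"))
  writeGeoJSON(sim$pas, file.path(dir, "pas.geojson"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
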