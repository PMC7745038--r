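# Incidence-based coverage rarefaction/extrapolation of species richness
# (Hill number of order q = 0), per-cell inclusion filters, and richness
# standardised to a common sample coverage (Cmax / C5%).

#' Incidence frequencies of a grid cell
#'
#' Container for the incidence sample of one grid cell: `T` sampling units
#' (1 km sub-cells holding at least one record of the focal group) and the
#' per-species incidence counts `Y_j` (sub-cells where species j was
#' detected). Derived totals: observed richness `S_obs`, total incidences
#' `U = sum(Y)`, uniques `Q1 = #{Y_j = 1}` and duplicates `Q2 = #{Y_j = 2}`.
#'
#' @param Y Integer vector of per-species incidence counts (each in `1..T`),
#'   optionally named by species.
#' @param T Number of sampling units with at least one record.
#' @return An `incidence_freq` list: `T`, `Y`, `S_obs`, `U`, `Q1`, `Q2`.
#' @export
incidenceFreq <- function(Y, T) {
  Y <- as.integer(Y); T <- as.integer(T)
  if (length(Y) && (any(Y < 1L) || any(Y > T)))
    stop("incidence counts must lie in 1..T")
  structure(list(T = T, Y = Y, S_obs = length(Y), U = sum(Y),
                 Q1 = sum(Y == 1L), Q2 = sum(Y == 2L)),
            class = "incidence_freq")
}

#' @export
print.incidence_freq <- function(x, ...) {
  cat(sprintf("incidence_freq: T = %d units, S_obs = %d, U = %d, Q1 = %d, Q2 = %d\n",
              x$T, x$S_obs, x$U, x$Q1, x$Q2))
  invisible(x)
}

#' Convert a sub-grid to incidence frequencies
#'
#' @param sg A `sub_grid` from [subgridIncidence()].
#' @return An `incidence_freq`.
#' @export
asIncidenceFreq <- function(sg) {
  stopifnot(inherits(sg, "sub_grid"))
  incidenceFreq(sg$incidence, sg$T)
}

#' Cell-inclusion filter for rarefaction
#'
#' A cell is excluded from coverage-based estimation when any of the
#' following holds: fewer than six observed species (`S_obs < 6`), fewer than
#' six sampling units with an incidence (`T < 6`), or every species detected
#' in exactly one unit (`U == S_obs`, no repeat detections to estimate
#' from). The clauses combine with OR: failing any one excludes the cell.
#'
#' @param inc An `incidence_freq`.
#' @param min_species,min_units Thresholds (default 6 and 6).
#' @return Logical: include the cell?
#' @export
includeCell <- function(inc, min_species = 6L, min_units = 6L) {
  stopifnot(inherits(inc, "incidence_freq"))
  !(inc$S_obs < min_species || inc$T < min_units || inc$U == inc$S_obs)
}

#' Estimated sample coverage at the reference sample size
#'
#' `C(T) = 1 - (Q1/U) * ((T-1) Q1) / ((T-1) Q1 + 2 Q2)`: the estimated
#' fraction of the assemblage's total incidence probability represented by
#' the species detected in the sample. 1 when there are no uniques; 0 when
#' every detection is a unique.
#'
#' @param inc An `incidence_freq` with `U > 0`.
#' @return Coverage estimate in `[0, 1]`.
#' @export
referenceCoverage <- function(inc) {
  stopifnot(inherits(inc, "incidence_freq"))
  if (inc$U == 0L) stop("no incidences (U = 0)")
  if (inc$Q1 == 0L) return(1)
  with(inc, 1 - (Q1 / U) * ((T - 1) * Q1) / ((T - 1) * Q1 + 2 * Q2))
}

#' Rarefied (interpolated) species richness
#'
#' Expected richness in `t` of the `T` sampling units, averaged over all
#' subsamples without replacement:
#' `S(t) = sum_j [1 - choose(T - Y_j, t) / choose(T, t)]`.
#'
#' @param inc An `incidence_freq`.
#' @param t Integer effort(s), each in `1..T`.
#' @return Expected richness, same length as `t`. `S(T) = S_obs` exactly.
#' @export
rarefyRichness <- function(inc, t) {
  stopifnot(inherits(inc, "incidence_freq"))
  if (any(t < 1L | t > inc$T)) stop("t out of range 1..T")
  vapply(t, function(tt) {
    # lchoose handles choose(a, b) = 0 for a < b via -Inf -> exp() = 0
    sum(1 - exp(lchoose(inc$T - inc$Y, tt) - lchoose(inc$T, tt)))
  }, 0)
}

# Chao2-type estimate of the number of undetected species
chao2Unseen <- function(inc) {
  with(inc, if (Q2 > 0L) ((T - 1) / T) * Q1^2 / (2 * Q2)
            else ((T - 1) / T) * Q1 * (Q1 - 1) / 2)
}

#' Extrapolated species richness beyond the reference sample
#'
#' `S(T + t*) = S_obs + Q0 * [1 - (1 - Q1 / (T*Q0 + Q1))^t*]` with `Q0` the
#' Chao2-type estimate of undetected species (bias-corrected form when
#' `Q2 = 0`). Flat at `S_obs` when there are no uniques.
#'
#' @param inc An `incidence_freq`.
#' @param t_star Additional effort beyond `T` (real, >= 0).
#' @return Expected richness at `T + t_star`.
#' @export
extrapolateRichness <- function(inc, t_star) {
  stopifnot(inherits(inc, "incidence_freq"))
  if (any(t_star < 0)) stop("t_star must be >= 0")
  if (inc$Q1 == 0L) return(rep(inc$S_obs, length(t_star)))
  Q0 <- chao2Unseen(inc)
  if (Q0 <= 0) return(rep(inc$S_obs, length(t_star)))
  inc$S_obs + Q0 * (1 - (1 - inc$Q1 / (inc$T * Q0 + inc$Q1))^t_star)
}

#' Extrapolated sample coverage
#'
#' `C(T + t*) = 1 - (Q1/U) * [((T-1) Q1) / ((T-1) Q1 + 2 Q2)]^(t* + 1)`;
#' reduces to [referenceCoverage()] at `t_star = 0` and tends to 1 as effort
#' grows (when `Q2 > 0`).
#'
#' @param inc An `incidence_freq` with `U > 0`.
#' @param t_star Additional effort beyond `T` (real, >= 0).
#' @return Coverage estimate in `[0, 1]`.
#' @export
extrapolatedCoverage <- function(inc, t_star) {
  stopifnot(inherits(inc, "incidence_freq"))
  if (inc$U == 0L) stop("no incidences (U = 0)")
  if (any(t_star < 0)) stop("t_star must be >= 0")
  if (inc$Q1 == 0L) return(rep(1, length(t_star)))
  A <- with(inc, ((T - 1) * Q1) / ((T - 1) * Q1 + 2 * Q2))
  1 - (inc$Q1 / inc$U) * A^(t_star + 1)
}

#' Interpolated sample coverage at reduced effort
#'
#' Expected coverage of a subsample of `t < T` units:
#' `C(t) = 1 - sum_j (Y_j/U) * choose(T - Y_j, t) / choose(T - 1, t)`.
#' At `t = T` the reference-sample estimator [referenceCoverage()] is used
#' (the subsampling form degenerates there).
#'
#' @param inc An `incidence_freq`.
#' @param t Integer effort(s) in `1..T`.
#' @return Coverage estimates.
#' @export
interpolatedCoverage <- function(inc, t) {
  stopifnot(inherits(inc, "incidence_freq"))
  if (inc$U == 0L) stop("no incidences (U = 0)")
  if (any(t < 1L | t > inc$T)) stop("t out of range 1..T")
  vapply(t, function(tt) {
    if (tt == inc$T) return(referenceCoverage(inc))
    1 - sum((inc$Y / inc$U) * exp(lchoose(inc$T - inc$Y, tt) - lchoose(inc$T - 1, tt)))
  }, 0)
}

#' Coverage at arbitrary (interpolated or extrapolated) effort
#'
#' Piecewise coverage curve: subsampling estimator on the integer lattice for
#' `t <= T` (linear interpolation in between), extrapolation formula beyond.
#'
#' @param inc An `incidence_freq`.
#' @param t Real effort(s) > 0.
#' @return Coverage estimates.
#' @export
coverageAt <- function(inc, t) {
  stopifnot(inherits(inc, "incidence_freq"))
  vapply(t, function(tt) {
    if (tt <= 0) stop("effort must be positive")
    if (tt > inc$T) return(extrapolatedCoverage(inc, tt - inc$T))
    lo <- floor(tt); hi <- ceiling(tt)
    if (lo == hi) return(interpolatedCoverage(inc, tt))
    if (lo == 0L) return(tt * interpolatedCoverage(inc, 1L))
    cl <- interpolatedCoverage(inc, lo); ch <- interpolatedCoverage(inc, hi)
    cl + (tt - lo) * (ch - cl)
  }, 0)
}

#' Richness at arbitrary (interpolated or extrapolated) effort
#'
#' @param inc An `incidence_freq`.
#' @param t Real effort(s) > 0; interpolated linearly between integer efforts
#'   below `T`, closed-form extrapolation beyond.
#' @return Expected richness values.
#' @export
richnessAt <- function(inc, t) {
  stopifnot(inherits(inc, "incidence_freq"))
  vapply(t, function(tt) {
    if (tt <= 0) stop("effort must be positive")
    if (tt > inc$T) return(extrapolateRichness(inc, tt - inc$T))
    lo <- floor(tt); hi <- ceiling(tt)
    if (lo == hi) return(rarefyRichness(inc, tt))
    if (lo == 0L) return(tt * rarefyRichness(inc, 1L))
    sl <- rarefyRichness(inc, lo); sh <- rarefyRichness(inc, hi)
    sl + (tt - lo) * (sh - sl)
  }, 0)
}

#' Effort at which a target coverage is reached
#'
#' Inverts the monotone coverage curve: searches the integer interpolation
#' lattice (linear interpolation between adjacent efforts) below `T` and
#' solves the extrapolation branch in closed form above. Efforts are capped
#' at `2T` (doubled reference size); a target above the doubled-sample
#' coverage returns the capped effort with `capped = TRUE`.
#'
#' @param inc An `incidence_freq`.
#' @param target Coverage in `(0, 1]`.
#' @return List: `t` (real effort), `capped` (logical).
#' @export
effortForCoverage <- function(inc, target) {
  stopifnot(inherits(inc, "incidence_freq"), target > 0, target <= 1)
  cref <- referenceCoverage(inc)
  if (target <= cref) {
    cgrid <- interpolatedCoverage(inc, seq_len(inc$T))
    hi <- which(cgrid >= target)[1L]
    if (is.na(hi)) hi <- inc$T  # numeric guard; cref >= target ensures existence
    if (hi == 1L) {
      t <- if (cgrid[1L] > 0) target / cgrid[1L] else 1
      return(list(t = max(t, .Machine$double.eps), capped = FALSE))
    }
    lo <- hi - 1L
    span <- cgrid[hi] - cgrid[lo]
    frac <- if (span > 0) (target - cgrid[lo]) / span else 0
    return(list(t = lo + frac, capped = FALSE))
  }
  # extrapolation branch: 1 - (Q1/U) A^(t*+1) = target
  if (inc$Q1 == 0L) return(list(t = inc$T, capped = FALSE))  # coverage already 1
  A <- with(inc, ((T - 1) * Q1) / ((T - 1) * Q1 + 2 * Q2))
  c2T <- extrapolatedCoverage(inc, inc$T)
  if (target > c2T || A >= 1) return(list(t = 2 * inc$T, capped = TRUE))
  t_star <- log((1 - target) * inc$U / inc$Q1) / log(A) - 1
  t_star <- min(max(t_star, 0), inc$T)
  list(t = inc$T + t_star, capped = FALSE)
}

#' Coverage-standardised richness across cells
#'
#' Extrapolates every included cell to double its reference sample size,
#' takes `C_max` (the minimum of those doubled-sample coverages) and `C_5pct`
#' (their 5th percentile, linear interpolation between order statistics), and
#' reports each cell's expected richness at the effort where its coverage
#' curve reaches each standard. Cells whose doubled-sample coverage falls
#' short of a standard are capped at `2T` and flagged.
#'
#' @param incs Named list of `incidence_freq` objects (cells already filtered
#'   with [includeCell()]).
#' @return A `coverage_standardisation` list: `C_max`, `C_5pct` and `table`, a
#'   data frame with per-cell `T`, `S_obs`, `U`, `Q1`, `Q2`, `C_ref`, `C_2T`,
#'   `S_at_Cmax`, `S_at_C5`, `capped_Cmax`, `capped_C5`.
#' @export
standardiseRichness <- function(incs) {
  stopifnot(is.list(incs), length(incs) >= 1L,
            all(vapply(incs, inherits, TRUE, "incidence_freq")))
  c2T <- vapply(incs, function(ic) extrapolatedCoverage(ic, ic$T), 0)
  C_max <- min(c2T)
  C_5 <- as.numeric(stats::quantile(c2T, 0.05, type = 7))
  atCoverage <- function(ic, target) {
    sol <- effortForCoverage(ic, target)
    c(S = richnessAt(ic, sol$t), capped = as.numeric(sol$capped))
  }
  per <- t(vapply(incs, function(ic) {
    a <- atCoverage(ic, C_max); b <- atCoverage(ic, C_5)
    c(T = ic$T, S_obs = ic$S_obs, U = ic$U, Q1 = ic$Q1, Q2 = ic$Q2,
      C_ref = referenceCoverage(ic), C_2T = extrapolatedCoverage(ic, ic$T),
      S_at_Cmax = a[["S"]], capped_Cmax = a[["capped"]],
      S_at_C5 = b[["S"]], capped_C5 = b[["capped"]])
  }, numeric(11)))
  tab <- as.data.frame(per)
  tab$cell <- if (is.null(names(incs))) as.character(seq_along(incs)) else names(incs)
  tab <- tab[, c("cell", "T", "S_obs", "U", "Q1", "Q2", "C_ref", "C_2T",
                 "S_at_Cmax", "S_at_C5", "capped_Cmax", "capped_C5")]
  structure(list(C_max = C_max, C_5pct = C_5, table = tab),
            class = "coverage_standardisation")
}

#' @export
print.coverage_standardisation <- function(x, ...) {
  cat(sprintf("coverage standardisation: %d cells, C_max = %.4f, C_5pct = %.4f\n",
              nrow(x$table), x$C_max, x$C_5pct))
  print.data.frame(utils::head(x$table, 6L))
  invisible(x)
}

#' Build per-cell incidence frequencies for a grid
#'
#' Runs [subgridIncidence()] for every cell with records and returns the
#' incidence samples, optionally filtered by [includeCell()].
#'
#' @param occ An `occurrence_set` (one class group, deduplicated).
#' @param grid An `analysis_grid`.
#' @param sub_size Sub-cell side in metres (default 1000).
#' @param filter Apply the inclusion filter? (default TRUE)
#' @return Named list of `incidence_freq` objects keyed by cell.
#' @export
cellIncidences <- function(occ, grid, sub_size = 1000, filter = TRUE) {
  assignment <- assignCells(occ, grid)
  occupied <- sort(unique(assignment[!is.na(assignment)]))
  incs <- lapply(occupied, function(cell)
    asIncidenceFreq(subgridIncidence(occ, grid, cell, sub_size, assignment)))
  names(incs) <- occupied
  if (filter) incs <- incs[vapply(incs, includeCell, TRUE)]
  incs
}
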