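# Pearson correlation with significance corrected for spatial autocorrelation
# (modified t-test with an effective sample size estimated from binned
# Moran-type correlograms of the two variables).

# effective sample size from two estimated spatial correlation matrices:
# vhat = tr(Ra Rb)/n^2 (both symmetric, so tr(Ra Rb) = sum(Ra * Rb)),
# M_hat = 1 + 1/vhat. With Ra = Rb = I this gives M_hat = n + 1.
effectiveSampleSize <- function(Ra, Rb) {
  n <- nrow(Ra)
  vhat <- sum(Ra * Rb) / n^2
  list(vhat = vhat, M_hat = 1 + 1 / vhat)
}

#' Spatially corrected Pearson correlation (modified t-test)
#'
#' Computes the ordinary Pearson correlation between two per-cell variables
#' and corrects its significance test for spatial autocorrelation by
#' estimating an effective sample size from the data:
#'
#' 1. `r = cor(a, b)` (the estimate itself is never altered);
#' 2. pairwise centroid distances are binned into `k` equal-width classes
#'    over `(0, max distance]`;
#' 3. for each class and variable, a Moran-type autocorrelation estimate
#'    `rho(h) = mean over pairs in h of z_i z_j / s^2`, with `z` the centred
#'    values and `s^2` the biased variance (empty classes contribute 0);
#' 4. spatial correlation matrices with unit diagonal and `rho(class(i, j))`
#'    off-diagonal give the estimated variance of r,
#'    `vhat = tr(Ra Rb) / n^2`;
#' 5. effective sample size `M_hat = 1 + 1/vhat`; the statistic
#'    `t = r * sqrt((M_hat - 2) / (1 - r^2))` is referred to a t distribution
#'    with `M_hat - 2` degrees of freedom (two-sided).
#'
#' Cells without records must be removed beforehand (double zeros otherwise
#' inflate the correlation). Under independence `M_hat` is close to `n`; under
#' strong positive autocorrelation it shrinks, widening the test.
#'
#' @param a,b Numeric per-cell vectors (aligned).
#' @param centroids Two-column matrix of cell centroid coordinates (metres).
#' @param k Number of distance classes (default 13).
#' @return A `modified_cor` list: `r`, `M_hat`, `t_stat`, `p_value`, `n`, `k`.
#'   When `|r| = 1` or `M_hat <= 2` the test is undefined: `t_stat`/`p_value`
#'   are `NA` with a `note`.
#' @export
modifiedCorrelation <- function(a, b, centroids, k = 13) {
  centroids <- as.matrix(centroids)
  n <- length(a)
  if (length(b) != n || nrow(centroids) != n)
    stop("a, b and centroids must be aligned")
  if (n < 5L) stop("need at least 5 cells")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance in a or b")
  r <- stats::cor(a, b)
  dmat <- as.matrix(stats::dist(centroids))
  off <- upper.tri(dmat)
  if (any(dmat[off] == 0))
    stop("coincident cell centroids are not allowed")
  dmax <- max(dmat[off])
  breaks <- seq(0, dmax, length.out = k + 1L)
  cls <- matrix(0L, n, n)
  cls[off] <- pmin(pmax(findInterval(dmat[off], breaks, left.open = TRUE,
                                     rightmost.closed = TRUE), 1L), k)
  cls[lower.tri(cls)] <- t(cls)[lower.tri(cls)]
  rhoClass <- function(v) {
    z <- v - mean(v)
    s2 <- mean(z^2)
    zz <- tcrossprod(z) / s2
    vapply(seq_len(k), function(h) {
      sel <- cls == h & off
      if (!any(sel)) 0 else mean(zz[sel])
    }, 0)
  }
  rho_a <- rhoClass(a)
  rho_b <- rhoClass(b)
  Ra <- diag(n); Rb <- diag(n)
  nz <- cls > 0L
  Ra[nz] <- rho_a[cls[nz]]
  Rb[nz] <- rho_b[cls[nz]]
  ess <- effectiveSampleSize(Ra, Rb)
  out <- list(r = r, M_hat = ess$M_hat, t_stat = NA_real_,
              p_value = NA_real_, n = n, k = k, note = NA_character_)
  if (abs(r) >= 1) {
    out$note <- "perfect correlation; t undefined"
  } else if (!is.finite(ess$M_hat) || ess$M_hat <= 2) {
    out$note <- "effective sample size <= 2; test undefined"
  } else {
    out$t_stat <- r * sqrt((ess$M_hat - 2) / (1 - r^2))
    out$p_value <- 2 * stats::pt(abs(out$t_stat), df = ess$M_hat - 2,
                                 lower.tail = FALSE)
  }
  class(out) <- "modified_cor"
  out
}

#' @export
print.modified_cor <- function(x, ...) {
  cat(sprintf("modified correlation: r = %.4f, M_hat = %.1f (n = %d), t = %.3f, p = %.4g\n",
              x$r, x$M_hat, x$n, x$t_stat, x$p_value))
  if (!is.na(x$note)) cat(" note:", x$note, "\n")
  invisible(x)
}

#' Modified correlations for a set of metric pairs
#'
#' Runs [modifiedCorrelation()] for each requested pair of named per-cell
#' metrics over a shared non-empty-cell universe.
#'
#' @param tables Named list of per-cell numeric vectors, all aligned.
#' @param pairs List of length-2 character vectors naming metrics in
#'   `tables`; may be empty.
#' @param centroids Two-column centroid matrix aligned with the vectors.
#' @param k Distance classes (default 13).
#' @return Data frame: `var_a`, `var_b`, `r`, `M_hat`, `t`, `p`, `n`.
#' @export
correlationMatrix <- function(tables, pairs, centroids, k = 13) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  rows <- lapply(pairs, function(pr) {
    if (!all(pr %in% names(tables))) stop("unknown metric name: ",
                                          paste(setdiff(pr, names(tables)), collapse = ", "))
    if (pr[1L] == pr[2L]) {
      return(data.frame(var_a = pr[1L], var_b = pr[2L], r = 1, M_hat = NA_real_,
                        t = NA_real_, p = NA_real_, n = length(tables[[pr[1L]]])))
    }
    m <- modifiedCorrelation(tables[[pr[1L]]], tables[[pr[2L]]], centroids, k = k)
    data.frame(var_a = pr[1L], var_b = pr[2L], r = m$r, M_hat = m$M_hat,
               t = m$t_stat, p = m$p_value, n = m$n)
  })
  if (!length(rows))
    return(data.frame(var_a = character(0), var_b = character(0), r = numeric(0),
                      M_hat = numeric(0), t = numeric(0), p = numeric(0), n = integer(0)))
  do.call(rbind, rows)
}
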