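# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

# quick occurrence set: vectors recycled to the longest
makeOcc <- function(species, x, y, year = 2000L, class_group = "Aves",
                    status_global = "LC", status_national = "LC",
                    crs_tag = "local-metres") {
  n <- max(length(species), length(x), length(y))
  cg <- rep_len(class_group, n)
  status_national <- ifelse(cg == "Mammalia", "NE", rep_len(status_national, n))
  occurrenceSet(species = rep_len(species, n),
                class_group = cg,
                x = rep_len(x, n), y = rep_len(y, n),
                year = rep_len(year, n),
                status_global = rep_len(status_global, n),
                status_national = status_national,
                crs_tag = crs_tag)
}

# square country polygon of side `side_km`
squareCountry <- function(side_km = 100) {
  rectPolygon(0, 0, side_km * 1000, side_km * 1000)
}

# independent oracle for the overlap area of an axis-aligned rectangle
# decomposition with a cell rectangle
rectOverlapArea <- function(rects, xmin, ymin, xmax, ymax) {
  sum(apply(rects, 1L, function(r) {
    w <- max(0, min(r[3L], xmax) - max(r[1L], xmin))
    h <- max(0, min(r[4L], ymax) - max(r[2L], ymin))
    w * h
  }))
}

# brute-force accumulation-curve oracle: mean observed richness over random
# orderings of the samples (each sample a species label vector)
permutationSacOracle <- function(samples, n_perm = 2000L) {
  N <- length(samples)
  acc <- matrix(0, n_perm, N)
  for (p in seq_len(n_perm)) {
    ord <- sample.int(N)
    seen <- character(0)
    for (i in seq_len(N)) {
      seen <- union(seen, samples[[ord[i]]])
      acc[p, i] <- length(seen)
    }
  }
  colMeans(acc)
}

# brute-force rarefaction oracle: mean richness over random subsets of t of
# the T incidence units (units encoded as a T x S presence matrix)
subsampleRichnessOracle <- function(pres, t, n_rep = 2000L) {
  T <- nrow(pres)
  mean(replicate(n_rep, {
    rows <- sample.int(T, t)
    sum(colSums(pres[rows, , drop = FALSE]) > 0)
  }))
}

# presence matrix (T units x S species) consistent with incidence counts Y
presenceFromY <- function(Y, T) {
  pres <- matrix(0L, T, length(Y))
  for (j in seq_along(Y)) pres[sample.int(T, Y[j]), j] <- 1L
  pres
}
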