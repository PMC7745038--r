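inc411 <- function() incidenceFreq(c(2, 1, 1), T = 4)

test_that("incidence frequencies derive the right totals", {
  inc <- inc411()
  expect_equal(inc$S_obs, 3L)
  expect_equal(inc$U, 4L)
  expect_equal(inc$Q1, 2L)
  expect_equal(inc$Q2, 1L)
  expect_error(incidenceFreq(c(5, 1), T = 4), "1..T")
})

test_that("the inclusion filter applies its three clauses with OR", {
  expect_false(includeCell(incidenceFreq(rep(2, 5), T = 10)))        # S_obs = 5 < 6
  expect_false(includeCell(incidenceFreq(rep(1, 8), T = 8)))         # U == S_obs
  expect_false(includeCell(incidenceFreq(c(3, 2, 2, 2, 2, 2), T = 5)))  # T = 5 < 6
  expect_true(includeCell(incidenceFreq(c(3, 3, 2, 2, 2, 2, 1), T = 9)))
})

test_that("reference coverage matches the closed form and its limits", {
  # 1 - (Q1/U) * (T-1)Q1 / ((T-1)Q1 + 2 Q2) = 1 - 0.5 * 6/8
  expect_equal(referenceCoverage(inc411()), 0.625)
  expect_equal(referenceCoverage(incidenceFreq(c(3, 2, 2), T = 5)), 1)  # Q1 = 0
  expect_equal(referenceCoverage(incidenceFreq(c(1, 1, 1), T = 6)), 0)  # all uniques
})

test_that("rarefied richness reproduces the worked values and identities", {
  inc <- inc411()
  expect_equal(rarefyRichness(inc, 4), 3)            # t = T -> S_obs
  expect_equal(rarefyRichness(inc, 1), inc$U / inc$T)  # t = 1 -> mean per-unit richness
  # exhaustive 2-unit enumeration oracle: (1 - 1/6) + 2 (1 - 3/6)
  expect_equal(rarefyRichness(inc, 2), 11 / 6, tolerance = 1e-12)
  expect_error(rarefyRichness(inc, 5), "out of range")
})

test_that("rarefied richness equals the subsampling-mean oracle at small T", {
  set.seed(31)
  for (rep in 1:3) {
    T <- sample(6:12, 1)
    Y <- sample(1:T, sample(5:9, 1), replace = TRUE)
    inc <- incidenceFreq(Y, T)
    pres <- presenceFromY(Y, T)
    for (t in c(2, T - 1)) {
      oracle <- subsampleRichnessOracle(pres, t, n_rep = 2000L)
      expect_equal(rarefyRichness(inc, t), oracle, tolerance = 0.08)
    }
  }
})

test_that("the interpolated curve is concave, non-decreasing, continuous at T", {
  inc <- incidenceFreq(c(4, 3, 2, 2, 1, 1, 1), T = 10)
  s <- rarefyRichness(inc, 1:10)
  expect_true(all(diff(s) > -1e-12))
  expect_true(all(diff(diff(s)) < 1e-12))
  expect_equal(s[10], inc$S_obs)
  expect_equal(extrapolateRichness(inc, 0), inc$S_obs)  # continuity at T
  expect_equal(extrapolatedCoverage(inc, 0), referenceCoverage(inc))
})

test_that("extrapolated richness and coverage reproduce the worked values", {
  inc <- inc411()
  # Q0 = (3/4) * 4 / 2 = 1.5; S(8) = 3 + 1.5 (1 - (1 - 2/8)^4)
  expect_equal(extrapolateRichness(inc, 4), 3 + 1.5 * (1 - 0.75^4), tolerance = 1e-12)
  # C(8) = 1 - 0.5 * 0.75^5
  expect_equal(extrapolatedCoverage(inc, 4), 1 - 0.5 * 0.75^5, tolerance = 1e-12)
  # no uniques: flat richness, full coverage
  inc0 <- incidenceFreq(c(3, 2, 2), T = 6)
  expect_equal(extrapolateRichness(inc0, 10), inc0$S_obs)
  expect_equal(extrapolatedCoverage(inc0, 10), 1)
  # Q2 = 0 engages the bias-corrected fallback without division by zero
  inc_q2 <- incidenceFreq(c(3, 1, 1), T = 6)
  expect_true(is.finite(extrapolateRichness(inc_q2, 6)))
  expect_gt(extrapolateRichness(inc_q2, 6), inc_q2$S_obs)
})

test_that("coverage estimators agree with a known-truth detection simulation", {
  # species detection probabilities known: true coverage of a sample is the
  # summed incidence probability of the detected species over the total
  set.seed(77)
  S <- 30; T <- 25
  p <- rbeta(S, 0.8, 3)  # per-unit detection probability by species
  reps <- 200
  est <- tru <- numeric(reps)
  for (i in seq_len(reps)) {
    pres <- matrix(rbinom(T * S, 1, rep(p, each = T)), T, S)
    Y <- colSums(pres)
    det <- Y > 0
    if (sum(Y) == 0) next
    inc <- incidenceFreq(Y[det], T)
    est[i] <- referenceCoverage(inc)
    tru[i] <- sum(p[det]) / sum(p)
  }
  expect_equal(mean(est), mean(tru), tolerance = 0.03)
})

test_that("effortForCoverage inverts the coverage curve on both branches", {
  inc <- incidenceFreq(c(5, 4, 3, 2, 2, 1, 1, 1), T = 12)
  cref <- referenceCoverage(inc)
  sol_lo <- effortForCoverage(inc, cref * 0.7)
  expect_false(sol_lo$capped)
  expect_lt(sol_lo$t, inc$T)
  expect_equal(coverageAt(inc, sol_lo$t), cref * 0.7, tolerance = 1e-6)
  target_hi <- (cref + extrapolatedCoverage(inc, inc$T)) / 2
  sol_hi <- effortForCoverage(inc, target_hi)
  expect_false(sol_hi$capped)
  expect_gt(sol_hi$t, inc$T)
  expect_equal(coverageAt(inc, sol_hi$t), target_hi, tolerance = 1e-9)
  # unreachable target: capped at doubled effort
  sol_cap <- effortForCoverage(inc, extrapolatedCoverage(inc, inc$T) + 1e-4)
  expect_true(sol_cap$capped)
  expect_equal(sol_cap$t, 2 * inc$T)
})

test_that("standardisation takes C_max as the minimum doubled-sample coverage", {
  inc1 <- incidenceFreq(c(5, 4, 3, 2, 2, 1, 1, 1), T = 12)
  single <- standardiseRichness(list(`1` = inc1))
  expect_equal(single$C_max, extrapolatedCoverage(inc1, inc1$T))
  expect_equal(single$C_max, single$C_5pct)

  # identical cells: a common effort, so identical standardised richness
  incs <- list(`1` = inc1, `2` = inc1, `3` = inc1)
  st <- standardiseRichness(incs)
  expect_equal(st$C_5pct, st$C_max)
  expect_length(unique(round(st$table$S_at_Cmax, 9)), 1L)

  # heterogeneous cells: C_5pct >= C_max by construction
  inc2 <- incidenceFreq(c(6, 6, 5, 4, 3, 3, 2, 1), T = 15)
  st2 <- standardiseRichness(list(`1` = inc1, `2` = inc2))
  expect_gte(st2$C_5pct, st2$C_max)
  expect_true(all(st2$table$S_at_Cmax <= st2$table$S_at_C5 + 1e-9))
})

test_that("cell incidences respect the grid sub-division and the filter", {
  set.seed(12)
  g <- buildGrid(squareCountry(50), 25000)
  occ <- makeOcc(paste0("s", sample(1:15, 400, TRUE)),
                 x = runif(400, 0, 5e4), y = runif(400, 0, 5e4))
  incs_all <- cellIncidences(occ, g, filter = FALSE)
  expect_length(incs_all, 4L)
  incs <- cellIncidences(occ, g)
  expect_true(all(vapply(incs, includeCell, TRUE)))
  expect_true(all(vapply(incs, function(ic) ic$T >= 6 && ic$S_obs >= 6, TRUE)))
})
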