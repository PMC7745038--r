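grid4 <- function() buildGrid(squareCountry(20), 10000)  # 4 cells

test_that("species richness counts distinct species per cell", {
  g <- grid4()
  occ <- makeOcc(c("A", "A", "B"), x = 1, y = 1)
  sr <- speciesRichness(occ, g, assignCells(occ, g))
  expect_equal(unname(sr[1]), 2L)
  expect_equal(sum(sr), 2L)  # all other cells empty

  empty <- speciesRichness(occ[0, ], g, assignCells(occ[0, ], g))
  expect_true(all(empty == 0L))
})

test_that("weighted endemism distributes reciprocal occupancy", {
  g <- grid4()
  # A occupies cells 1 and 2, B only cell 1
  occ <- makeOcc(c("A", "A", "B"), x = c(1, 10001, 1), y = 1)
  E <- weightedEndemism(occ, g, assignCells(occ, g))
  expect_equal(unname(E[1]), 1.5)
  expect_equal(unname(E[2]), 0.5)

  # one species present in all M cells -> E = 1/M everywhere
  M <- nrow(g$cells)
  occ_u <- makeOcc("U", x = c(1, 10001, 1, 10001), y = c(1, 1, 10001, 10001))
  Eu <- weightedEndemism(occ_u, g, assignCells(occ_u, g))
  expect_equal(unname(Eu), rep(1 / M, M))

  # species confined to one cell: E == SR there
  occ_c <- makeOcc(c("A", "B", "C"), x = 1, y = 1)
  Ec <- weightedEndemism(occ_c, g, assignCells(occ_c, g))
  expect_equal(unname(Ec[1]), 3)
})

test_that("endemism mass is conserved on random datasets", {
  set.seed(99)
  g <- grid4()
  for (i in 1:25) {
    n <- sample(5:60, 1)
    occ <- makeOcc(paste0("s", sample(1:12, n, TRUE)),
                   x = runif(n, 0, 2e4), y = runif(n, 0, 2e4))
    asg <- assignCells(occ, g)
    E <- weightedEndemism(occ, g, asg)
    expect_equal(sum(E), length(unique(occ$species[!is.na(asg)])),
                 tolerance = 1e-9)
  }
})

test_that("threatened metrics follow the CR/EN/VU rule", {
  g <- grid4()
  occ <- makeOcc(c("a", "b", "c", "d"), x = 1, y = 1,
                 status_global = c("EN", "LC", "VU", "DD"))
  tm <- threatenedMetrics(occ, g, assignCells(occ, g), "global")
  expect_equal(unname(tm$TSN[1]), 2L)
  expect_equal(unname(tm$TSP[1]), 0.5)
  expect_true(is.na(tm$TSP[2]))  # empty cell: undefined

  # no threatened species -> zero, not missing
  occ0 <- makeOcc(c("a", "b"), x = 1, y = 1, status_global = "LC")
  tm0 <- threatenedMetrics(occ0, g, assignCells(occ0, g), "global")
  expect_equal(unname(tm0$TSN[1]), 0L)
  expect_equal(unname(tm0$TSP[1]), 0)
})

test_that("national metrics are refused without a national assessment", {
  g <- grid4()
  mam <- makeOcc("m", 1, 1, class_group = "Mammalia", status_national = "NE")
  expect_error(threatenedMetrics(mam, g, assignCells(mam, g), "national"),
               "Mammalia")
  mixed <- makeOcc(c("m", "b"), x = 1, y = 1,
                   class_group = c("Mammalia", "Aves"))
  expect_error(threatenedMetrics(mixed, g, assignCells(mixed, g), "national"),
               "combined")
})

test_that("effort counts records and is order invariant", {
  g <- grid4()
  occ <- makeOcc(c("A", "B", "A"), x = 1, y = 1)
  eff <- cellEffort(g, assignCells(occ, g))
  expect_equal(unname(eff[1]), 3L)
  expect_equal(sum(eff), 3L)
  shuffled <- occ[c(3, 1, 2), ]
  expect_equal(cellEffort(g, assignCells(shuffled, g)), eff)
  expect_true(all(cellEffort(g, assignCells(occ[0, ], g)) == 0L))
})

test_that("adding a record never decreases effort, SR or TSN", {
  set.seed(123)
  g <- grid4()
  occ <- makeOcc(paste0("s", sample(1:6, 30, TRUE)),
                 x = runif(30, 0, 2e4), y = runif(30, 0, 2e4),
                 status_global = sample(c("EN", "LC"), 30, TRUE))
  base_a <- assignCells(occ, g)
  extra <- makeOcc("s_new", x = runif(1, 0, 2e4), y = runif(1, 0, 2e4),
                   status_global = "CR")
  occ2 <- occurrenceSet(c(occ$species, extra$species),
                        c(occ$class_group, extra$class_group),
                        c(occ$x, extra$x), c(occ$y, extra$y),
                        c(occ$year, extra$year),
                        c(occ$status_global, extra$status_global),
                        c(occ$status_national, extra$status_national))
  a2 <- assignCells(occ2, g)
  expect_true(all(cellEffort(g, a2) >= cellEffort(g, base_a)))
  expect_true(all(speciesRichness(occ2, g, a2) >= speciesRichness(occ, g, base_a)))
  expect_true(all(threatenedMetrics(occ2, g, a2, "global")$TSN >=
                  threatenedMetrics(occ, g, base_a, "global")$TSN))
})

test_that("cellMetrics assembles a consistent table with NA national sentinels", {
  g <- grid4()
  occ <- makeOcc(c("a", "b", "m"), x = c(1, 1, 10001), y = 1,
                 class_group = c("Aves", "Aves", "Mammalia"),
                 status_global = c("VU", "LC", "LC"))
  mt <- cellMetrics(occ, g)
  expect_s3_class(mt, "cell_metric_table")
  expect_equal(mt$SR[1], 2L)
  expect_equal(mt$TSP_g[1], 0.5)
  expect_true(all(is.na(mt$TSN_n)))  # multi-class: no national assessment
  # TSP equals TSN/SR cell-by-cell wherever defined
  ok <- mt$SR > 0
  expect_equal(mt$TSP_g[ok], mt$TSN_g[ok] / mt$SR[ok])

  birds <- makeOcc(c("a", "b"), x = 1, y = 1, status_national = c("CR", "LC"))
  mtb <- cellMetrics(birds, g)
  expect_equal(mtb$TSN_n[1], 1L)
  expect_equal(mtb$TSP_n[1], 0.5)
})
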