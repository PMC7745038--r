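test_that("buildGrid tiles a square country exactly", {
  sq <- squareCountry(100)
  g50 <- buildGrid(sq, 50000)
  expect_equal(nrow(g50$cells), 4L)
  expect_equal(g50$cells$area_km2, rep(2500, 4))
  expect_equal(sum(g50$cells$area_km2), g50$country_area_km2)

  g40 <- buildGrid(sq, 40000)
  expect_equal(nrow(g40$cells), 9L)
  expect_equal(sum(g40$cells$area_km2), 10000)
  # per-cell clipped areas match the independent rectangle-overlap oracle
  cntry <- matrix(c(0, 0, 1e5, 1e5), 1)
  for (i in seq_len(nrow(g40$cells))) {
    x0 <- g40$cells$col[i] * 4e4; y0 <- g40$cells$row[i] * 4e4
    expect_equal(g40$cells$area_km2[i] * 1e6,
                 rectOverlapArea(cntry, x0, y0, x0 + 4e4, y0 + 4e4))
  }
})

test_that("buildGrid rejects invalid input and drops zero-area cells", {
  degenerate <- geoPolygon(cbind(c(0, 1, 2), c(0, 0, 0)))  # zero area
  expect_error(buildGrid(degenerate, 1000), "empty country polygon")
  expect_error(buildGrid(squareCountry(10), -5), "positive")

  # an off-centre origin creates partial cells but never zero-area ones
  g <- buildGrid(squareCountry(100), 50000, origin = c(-25000, -25000))
  expect_true(all(g$cells$area_km2 > 0))
  expect_equal(sum(g$cells$area_km2), 10000)
})

test_that("assignment follows the half-open convention", {
  g <- buildGrid(squareCountry(100), 25000)
  occ <- makeOcc(c("A", "B", "C"), x = c(0, 25000, -1), y = c(0, 0, 0))
  asg <- assignCells(occ, g)
  cell_of <- function(col, row) col + row * g$n_cols + 1L
  expect_equal(asg[1], cell_of(0, 0))
  expect_equal(asg[2], cell_of(1, 0))   # boundary point -> next cell
  expect_true(is.na(asg[3]))            # outside
  expect_equal(attr(asg, "n_outside"), 1L)

  bad <- makeOcc("A", 1, 1, crs_tag = "other")
  expect_error(assignCells(bad, g), "CRS mismatch")
})

test_that("every in-country point lands in exactly one cell (half-open tiling)", {
  set.seed(42)
  g <- buildGrid(squareCountry(100), 30000)  # ragged tiling
  x <- runif(500, 0, 1e5 - 1e-6); y <- runif(500, 0, 1e5 - 1e-6)
  occ <- makeOcc(paste0("s", seq_along(x)), x = x, y = y)
  asg <- assignCells(occ, g)
  expect_false(anyNA(asg))
  # manual recomputation agrees
  expect_equal(asg[seq_along(x)],
               as.integer(floor(x / 3e4) + floor(y / 3e4) * g$n_cols + 1L),
               ignore_attr = TRUE)
})

test_that("nested grids refine consistently: parent counts = sum of children", {
  set.seed(7)
  sq <- squareCountry(100)
  occ <- makeOcc(paste0("s", 1:300), x = runif(300, 0, 1e5), y = runif(300, 0, 1e5))
  g25 <- buildGrid(sq, 25000)
  g125 <- buildGrid(sq, 12500)
  e25 <- cellEffort(g25, assignCells(occ, g25))
  e125 <- cellEffort(g125, assignCells(occ, g125))
  for (i in seq_len(nrow(g25$cells))) {
    pc <- g25$cells$col[i]; pr <- g25$cells$row[i]
    kids <- expand.grid(col = 2 * pc + 0:1, row = 2 * pr + 0:1)
    kid_keys <- as.character(kids$col + kids$row * g125$n_cols + 1L)
    expect_equal(unname(e25[as.character(g25$cells$cell[i])]),
                 sum(e125[kid_keys], na.rm = TRUE))
  }
})

test_that("sub-grid incidence collapses abundance within a sub-cell", {
  g <- buildGrid(squareCountry(50), 25000)
  cell <- g$cells$cell[1]
  # two records of A in the same 1 km sub-cell; A also in 2 other sub-cells; B once
  occ <- makeOcc(c("A", "A", "A", "A", "B"),
                 x = c(100, 200, 1500, 2500, 100),
                 y = c(100, 150, 1500, 2500, 800))
  sg <- subgridIncidence(occ, g, cell)
  expect_equal(unname(sg$incidence["A"]), 3L)
  expect_equal(unname(sg$incidence["B"]), 1L)
  expect_equal(sg$T, 3L)  # occupied sub-cells: (0,0) shared by A and B, (1,1), (2,2)
  expect_error(subgridIncidence(occ, g, cell, sub_size = 7000), "divisible")

  empty <- subgridIncidence(occ[0, ], g, cell)
  expect_equal(empty$T, 0L)
  expect_length(empty$incidence, 0L)
})

test_that("unsampled area accounts clipped areas of record-free cells", {
  g <- buildGrid(squareCountry(20), 10000)  # 4 cells of 100 km^2
  occ <- makeOcc(c("A", "B", "C"), x = c(1, 10001, 1), y = c(1, 1, 10001))
  ua <- unsampledArea(g, assignCells(occ, g))
  expect_equal(unname(ua["km2"]), 100)
  expect_equal(unname(ua["percent"]), 25)

  all_occ <- makeOcc(paste0("s", 1:4), x = c(1, 10001, 1, 10001),
                     y = c(1, 1, 10001, 10001))
  expect_equal(unname(unsampledArea(g, assignCells(all_occ, g))["percent"]), 0)

  ua_none <- unsampledArea(g, assignCells(occ[0, ], g))
  expect_equal(unname(ua_none["km2"]), g$country_area_km2)
  expect_equal(unname(ua_none["percent"]), 100)
  # sampled + unsampled = country
  expect_equal(unname(ua["km2"]) + 300, g$country_area_km2)
})

test_that("grid GeoJSON export round-trips cell geometry", {
  g <- buildGrid(squareCountry(50), 25000)
  path <- tempfile(fileext = ".geojson")
  writeGridGeoJSON(g, path)
  cells <- readGeoJSON(path, split = TRUE)
  expect_length(cells, nrow(g$cells))
  expect_equal(polygonArea(cells[[1]]) / 1e6, 625)
})
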