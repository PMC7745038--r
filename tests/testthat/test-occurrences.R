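test_that("CSV reading validates rows, maps unknown threat codes to NE", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c(
    "scientificName,classGroup,x,y,year,iucnGlobal,iucnNational",
    "Hyla pulchella,Amphibia,1000,2000,1999,LC,EN",
    "Turdus rufiventris,Aves,1500,2500,2005,,",
    "Bothrops alternatus,Reptilia,2000,3000,2010,XX,VU",
    "Broken row,Aves,abc,3000,2010,LC,LC",
    "Another break,Fungi,10,20,2010,LC,LC"), csv)
  occ <- suppressWarnings(readOccurrences(csv))
  expect_s3_class(occ, "occurrence_set")
  expect_equal(nrow(occ), 3L)
  expect_equal(occ$status_global[2], "NE")      # blank -> NE
  expect_equal(occ$status_national[2], "NE")
  expect_equal(occ$status_global[3], "NE")      # unknown code -> NE
  expect_equal(attr(occ, "n_unknown_status"), 1L)
  v <- attr(occ, "validation")
  expect_setequal(v$row, c(4L, 5L))
  expect_true(any(grepl("coordinates", v$reason)))
  expect_true(any(grepl("class group", v$reason)))
})

test_that("reading errors on missing file, missing columns and empty tables", {
  expect_error(readOccurrences(tempfile()), "not found")
  csv <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), csv)
  expect_error(readOccurrences(csv), "mandatory column")
  writeLines("scientificName,classGroup,x,y", csv)
  expect_error(readOccurrences(csv), "empty")
})

test_that("column maps and lon/lat projection are honoured", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("sp,grp,decimalLongitude,decimalLatitude",
               "A,Aves,-56.0,-34.0", "B,Aves,-55.0,-34.0"), csv)
  occ <- readOccurrences(csv, column_map = c(species = "sp", class_group = "grp"),
                         lonlat = TRUE, lon0 = -56, lat0 = -34)
  expect_equal(occ$x[1], 0)
  # one degree of longitude at 34S is about 92.4 km
  expect_equal(occ$x[2], 6378137 * cos(-34 * pi / 180) * pi / 180, tolerance = 1e-12)
})

test_that("write -> read round-trip preserves all fields", {
  occ <- occurrenceSet(
    species = c("A", "B", "C"), class_group = c("Aves", "Amphibia", "Reptilia"),
    x = c(1000.25, 2000.5, 3000.75), y = c(10, 20, 30),
    year = c(2001L, NA, 2003L),
    status_global = c("EN", "LC", "DD"), status_national = c("VU", "NE", "CR"))
  csv <- tempfile(fileext = ".csv")
  writeOccurrences(occ, csv)
  back <- readOccurrences(csv)
  for (col in names(occ)) expect_equal(back[[col]], occ[[col]], label = col)
})

test_that("mammal national categories are reset to NE with a warning", {
  expect_warning(
    occ <- occurrenceSet("m1", "Mammalia", 0, 0, status_national = "EN"),
    "national")
  expect_equal(occ$status_national, "NE")
})

test_that("deduplication keeps one record per (species, x, y, year) key", {
  occ <- makeOcc(c("A", "A", "A"), x = c(1, 1, 1), y = c(1, 1, 1),
                 year = c(2000L, 2000L, 2001L))
  dd <- deduplicate(occ)
  expect_equal(nrow(dd), 2L)
  expect_equal(attr(dd, "n_removed"), 1L)

  # five copies collapse to one
  occ5 <- makeOcc(rep("A", 5), x = 7, y = 9, year = 1990L)
  expect_equal(nrow(deduplicate(occ5)), 1L)
  expect_equal(attr(deduplicate(occ5), "n_removed"), 4L)

  # no repeated keys: unchanged, original order preserved
  occ0 <- makeOcc(c("B", "A", "C"), x = 1:3, y = 1:3)
  expect_equal(deduplicate(occ0)$species, c("B", "A", "C"))
  expect_equal(attr(deduplicate(occ0), "n_removed"), 0L)
})

test_that("deduplication is idempotent and treats missing years as one key", {
  set.seed(11)
  occ <- makeOcc(sample(LETTERS[1:4], 40, TRUE),
                 x = sample(1:4, 40, TRUE), y = sample(1:3, 40, TRUE),
                 year = sample(c(NA, 2000L, 2001L), 40, TRUE))
  d1 <- deduplicate(occ)
  d2 <- deduplicate(d1)
  expect_equal(as.data.frame(d1), as.data.frame(d2), ignore_attr = TRUE)
  expect_equal(nrow(d1), nrow(d2))
  expect_equal(attr(d2, "n_removed"), 0L)
  # two coordinate-identical records with unknown years collapse
  occ_na <- makeOcc(c("Z", "Z"), x = 5, y = 5, year = NA_integer_)
  expect_equal(nrow(deduplicate(occ_na)), 1L)
})

test_that("optional coordinate precision coarsens the duplicate key only", {
  occ <- makeOcc(c("A", "A"), x = c(1.0001, 1.0002), y = 1)
  expect_equal(nrow(deduplicate(occ)), 2L)              # exact: distinct
  dd <- deduplicate(occ, precision = 2)
  expect_equal(nrow(dd), 1L)                            # rounded key: same
  expect_equal(dd$x, 1.0001)                            # coordinates untouched
})

test_that("splitByClass partitions the set", {
  occ <- makeOcc(c("a1", "a2", "b1"), x = 1:3, y = 1:3,
                 class_group = c("Amphibia", "Amphibia", "Aves"))
  sp <- splitByClass(occ)
  expect_named(sp, c("Amphibia", "Reptilia", "Aves", "Mammalia"))
  expect_equal(nrow(sp$Amphibia), 2L)
  expect_equal(nrow(sp$Aves), 1L)
  expect_equal(nrow(sp$Reptilia), 0L)
  expect_equal(sum(vapply(sp, nrow, 0L)), nrow(occ))

  empty <- occ[0, ]
  expect_true(all(vapply(splitByClass(empty), nrow, 0L) == 0L))

  mam <- makeOcc("m", 1, 1, class_group = "Mammalia")
  expect_equal(nrow(splitByClass(mam)$Mammalia), 1L)
})
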