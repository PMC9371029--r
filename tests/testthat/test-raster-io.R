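test_that("label rasters round-trip exactly, including nodata", {
  set.seed(21)
  vals <- matrix(sample(c(0:10), 100, replace = TRUE), 10, 10)
  lr <- label_raster(vals, grid_meta(10, 10, pixel_size = 30,
                                     origin = c(500, 900),
                                     crs_label = "EPSG:32651"),
                     year = 2019)
  f <- file.path(tempdir(), "lab.tif")
  write_label_raster(lr, f)
  back <- read_label_raster(f)
  expect_identical(back$values, lr$values)
  expect_true(same_grid(back, lr))
  expect_equal(back$year, 2019L)

  # nodata cells are counted faithfully after the round trip
  v2 <- matrix(1L, 10, 10)
  v2[sample(100, 17)] <- 0L
  write_label_raster(label_raster(v2, year = 2020), f)
  expect_equal(sum(read_label_raster(f)$values == 0), 17)

  expect_error(label_raster(matrix(42L, 3, 3)), "unknown class code")
  expect_error(read_label_raster(file.path(tempdir(), "nope.tif")),
               "no such file")
})

test_that("monthly cubes round-trip values and validity masks", {
  set.seed(22)
  d <- c(8, 9, 4, 6)
  # values representable in the writer's 16-bit quantization grid
  vals <- array(sample(0:65535, prod(d), replace = TRUE) / 65535, d)
  valid <- array(runif(prod(d[c(1, 2, 4)])) > 0.1, d[c(1, 2, 4)])
  vmask <- aperm(array(valid, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  vals[!vmask] <- NA_real_
  cube <- monthly_cube(vals, valid, year = 2018, months = 5:10)
  dir <- file.path(tempdir(), "cube1")
  write_monthly_cube(cube, dir)
  back <- read_monthly_cube(dir)
  expect_identical(back$values, cube$values)
  expect_identical(back$valid, cube$valid)
  expect_equal(back$months, 5:10)
  expect_true(same_grid(back, cube))

  # a known number of invalid cells per month survives the round trip
  expect_equal(apply(back$valid, 3, function(m) sum(!m)),
               apply(valid, 3, function(m) sum(!m)))

  # month gaps at read time: read a named subset of month files
  sub <- read_monthly_cube(stats::setNames(
    as.list(file.path(dir, c("month_06.tif", "month_09.tif"))), c(6, 9)))
  expect_equal(sub$months, c(6L, 9L))
  expect_identical(sub$values[, , , 1], cube$values[, , , 2])

  # band-count mismatch across months is a validation error
  tiff::writeTIFF(list(matrix(0.5, d[1], d[2]), matrix(1, d[1], d[2])),
                  file.path(dir, "month_07.tif"), bits.per.sample = 16L)
  expect_error(read_monthly_cube(dir), "band page")

  # grid-size mismatch is an alignment error
  write_monthly_cube(cube, dir)
  tiff::writeTIFF(rep(list(matrix(0.5, 3, 3)), 5),
                  file.path(dir, "month_07.tif"), bits.per.sample = 16L)
  expect_error(read_monthly_cube(dir), "alignment")
})

test_that("reclassification follows the shipped table with a catch-all", {
  raw <- matrix(c(5L, 12L, 13L, 999L, 3L, 83L, 176L, 64L, 0L), 3, 3)
  lr <- reclassify(raw)
  expect_equal(as.vector(lr$values), c(2L, 1L, 1L, 10L, 3L, 4L, 7L, 9L, 0L))
  # unmapped small codes also fall through to Other; the map has no
  # identity rows for the condensed scheme, so reclassify is not
  # idempotent on condensed grids (documented)
  expect_equal(reclassify(matrix(2L, 1, 1))$values[1, 1], 10L)
  expect_equal(reclassify(matrix(1L, 1, 1))$values[1, 1], 1L)
  map <- default_class_map()
  expect_named(map, c("raw_code", "new_code", "name"))
  expect_setequal(unique(map$new_code), 1:9)
})

test_that("sample tables round-trip through CSV losslessly", {
  set.seed(23)
  n <- 40
  df <- data.frame(row = sample(50, n, TRUE), col = sample(50, n, TRUE),
                   year = sample(2017:2021, n, TRUE),
                   label = sample(1:10, n, TRUE))
  feats <- matrix(c(runif(n * 3), rnorm(n * 3) * 1e-7,
                    runif(n * 2) * 1e6), n, 8)
  colnames(feats) <- sprintf("f_%d", 0:7)
  df <- cbind(df, feats)
  df$provenance <- sample(c("candidate", "retained"), n, TRUE)
  df$discard_reason <- NA_character_
  df$discard_reason[1:3] <- "cross-year vote: 2/3 agreed"
  class(df) <- c("sample_table", "data.frame")
  f <- file.path(tempdir(), "samples.csv")
  write_samples(df, f)
  back <- read_samples(f)
  for (cn in sprintf("f_%d", 0:7))
    expect_identical(back[[cn]], df[[cn]])
  expect_identical(back$label, df$label)
  expect_identical(back$discard_reason, df$discard_reason)
})
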