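test_that("cloud filtering keeps strictly-below-threshold acquisitions in order", {
  # 10x10 grids so the requested cloud fractions are exactly representable
  acqs <- list(make_acq(0.2, rows = 10, cols = 10, seed = 1),
               make_acq(0.6, rows = 10, cols = 10, seed = 2),
               make_acq(0.49, rows = 10, cols = 10, seed = 3))
  kept <- filter_acquisitions(acqs)
  expect_equal(vapply(kept, `[[`, numeric(1), "cloud_fraction"),
               c(0.2, 0.49))
  # boundary: exactly at the threshold is removed (strict inequality)
  expect_length(filter_acquisitions(list(make_acq(0.5))), 0)
  # clear skies: identity
  all_clear <- list(make_acq(0), make_acq(0, seed = 2))
  expect_identical(filter_acquisitions(all_clear), all_clear)
})

test_that("monthly composite is a per-pixel masked median", {
  one <- make_acq(0.3, seed = 4)
  comp <- composite_month(list(one))
  expect_equal(comp$values, one$values)
  expect_equal(comp$valid, one$valid)

  # odd-count median at a constructed pixel
  mk <- function(v) acquisition(array(v, c(1, 1, 1)), month = 6)
  comp <- composite_month(list(mk(0.1), mk(0.3), mk(0.2)))
  expect_equal(comp$values[1, 1, 1], 0.2)

  # 5 acquisitions with random masks vs per-pixel brute-force recomputation
  set.seed(11)
  acqs <- lapply(1:5, function(k) make_acq(runif(1, 0.2, 0.6), rows = 6,
                                           cols = 7, bands = 3, seed = k))
  comp <- composite_month(acqs)
  for (i in 1:6) for (j in 1:7) for (b in 1:3) {
    vals <- unlist(lapply(acqs, function(a)
      if (a$valid[i, j]) a$values[i, j, b] else NULL))
    if (length(vals) == 0) {
      expect_false(comp$valid[i, j])
      expect_true(is.na(comp$values[i, j, b]))
    } else {
      expect_equal(comp$values[i, j, b], median(vals))
    }
  }

  # permutation invariance
  comp2 <- composite_month(rev(acqs))
  expect_equal(comp2$values, comp$values)
  expect_equal(comp2$valid, comp$valid)

  expect_error(composite_month(list()), "at least 1")
})

test_that("gap interpolation averages the nearest valid neighbours", {
  expect_equal(interpolate_gaps(c(0.2, NA, 0.4)), c(0.2, 0.3, 0.4))
  x <- c(0.15, 0.3, 0.45, 0.5)
  expect_identical(interpolate_gaps(x), x)  # gap-free: identity
  # hand-traced fill incl. leading/trailing nearest-value extension and a
  # run of two interior gaps
  expect_equal(interpolate_gaps(c(NA, 0.5, NA, NA, 0.9, 0.7)),
               c(0.5, 0.5, 0.7, 0.7, 0.9, 0.7))
  expect_error(interpolate_gaps(c(NA, 0.5, NA)), "fewer than 2")
})

test_that("Savitzky-Golay smoothing reproduces polynomials and matches the LS oracle", {
  expect_equal(smooth_series(rep(0.4, 6)), rep(0.4, 6), tolerance = 1e-12)
  t <- 1:8
  quad <- 0.1 + 0.05 * t - 0.004 * t^2
  expect_equal(smooth_series(quad), quad, tolerance = 1e-9)
  set.seed(5)
  for (i in 1:10) {
    x <- runif(7)
    expect_equal(smooth_series(x, window = 5, polyorder = 2),
                 oracle_sgolay(x, 5, 2), tolerance = 1e-9)
  }
  expect_warning(out <- smooth_series(runif(3), window = 5), "skipped")
  expect_length(out, 3)
  expect_error(smooth_series(runif(7), window = 4), "odd")
  expect_error(smooth_series(runif(7), window = 5, polyorder = 5),
               "polyorder")
})

test_that("build_cube composes filter/composite/fill/smooth deterministically", {
  bnd <- get_small_scene()
  scene <- bnd$scene
  acqs <- make_acquisitions(scene, scene$years[1], per_month = 2,
                            cloud_rate = 0.3, seed = 9)
  c1 <- build_cube(acqs, months = scene$config$months)
  c2 <- build_cube(acqs, months = scene$config$months)
  expect_identical(c1$values, c2$values)
  expect_identical(c1$valid, c2$valid)

  # with one acquisition per month, no cloud and no missing cells, the
  # cube is the smoothed scene reflectance exactly
  clean <- make_acquisitions(scene, scene$years[1], per_month = 1,
                             cloud_rate = 0)
  cube <- build_cube(clean, months = scene$config$months)
  raw <- scene$cubes[[1]]
  S <- cropsift:::sg_operator(6, 5, 2)
  i <- 7; j <- 13; b <- 2
  expect_equal(cube$values[i, j, b, ],
               pmin(pmax(as.vector(S %*% raw$values[i, j, b, ]), 0), 1),
               tolerance = 1e-12)

  # a pixel observed in fewer than two months is flagged unusable
  few <- lapply(clean, function(a) {
    if (a$month >= 6) a$valid[2, 3] <- FALSE  # only May left: unusable
    vm <- array(a$valid, dim(a$values)); a$values[!vm] <- NA_real_
    acquisition(a$values, a$valid, a$year, a$month, a$ordinal, a$meta)
  })
  cube2 <- build_cube(few, months = scene$config$months)
  expect_false(any(cube2$valid[2, 3, ]))
  expect_true(all(cube2$valid[2, 4, ]))
})
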