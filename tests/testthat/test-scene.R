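test_that("degenerate noise settings reproduce the phenology exactly", {
  cfg <- scene_config(grid_rows = 20, grid_cols = 20, n_years = 2,
                      noise_sd = 0, missing_rate = 0, label_noise_rate = 0,
                      seed = 3)
  sc <- generate_scene(cfg)
  for (yr in as.character(sc$years)) {
    expect_identical(sc$noisy_labels[[yr]]$values, sc$true_labels[[yr]]$values)
    expect_false(any(sc$noise_masks[[yr]]))
    ci <- match(sc$true_labels[[yr]]$values, cfg$class_set)
    for (mi in 1:6) for (b in 1:4)
      expect_equal(sc$cubes[[yr]]$values[, , b, mi],
                   matrix(cfg$phenology[ci, b, mi], 20, 20))
  }
  # noise-free class signatures are pairwise distinct (injectivity)
  sigs <- apply(cfg$phenology, 1, c)  # one column per class
  expect_equal(nrow(unique(t(sigs))), 10)
})

test_that("scenes are deterministic given the seed and rotate crops correctly", {
  cfg <- scene_config(grid_rows = 30, grid_cols = 30, n_years = 3,
                      field_size_px = 10, seed = 8)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$true_labels[["2019"]]$values, b$true_labels[["2019"]]$values)
  expect_identical(a$cubes[["2018"]]$values, b$cubes[["2018"]]$values)
  expect_identical(a$noise_masks, b$noise_masks)

  # rotation property on every consecutive pair of years: corn <-> soy,
  # rice continuous, non-crop constant
  rot <- c(2L, 1L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L)
  big <- generate_scene(scene_config(seed = 4))
  for (yi in seq_len(big$config$n_years - 1)) {
    expect_identical(big$true_labels[[yi + 1]]$values,
                     matrix(rot[big$true_labels[[yi]]$values], 100, 100))
  }
})

test_that("label-noise counts sit inside the central 99% binomial band", {
  sc <- generate_scene(scene_config(label_noise_rate = 0.1, seed = 12))
  lo <- qbinom(0.005, 10000, 0.1)
  hi <- qbinom(0.995, 10000, 0.1)
  for (yr in as.character(sc$years)) {
    n_noise <- sum(sc$noise_masks[[yr]])
    expect_gte(n_noise, lo)
    expect_lte(n_noise, hi)
    # noisy labels differ from truth exactly on the mask
    expect_identical(sc$noisy_labels[[yr]]$values != sc$true_labels[[yr]]$values,
                     sc$noise_masks[[yr]])
  }
})

test_that("field-mode label noise corrupts whole fields", {
  sc <- generate_scene(scene_config(grid_rows = 50, grid_cols = 50,
                                    field_size_px = 10, n_years = 2,
                                    label_noise_rate = 0.3,
                                    noise_mode = "field", seed = 5))
  for (yr in as.character(sc$years)) {
    m <- sc$noise_masks[[yr]]
    per_field <- tapply(as.vector(m), as.vector(sc$field_id), mean)
    expect_true(all(per_field %in% c(0, 1)))
  }
})

test_that("acquisitions copy the cube and respect the cloud budget", {
  bnd <- get_small_scene()
  scene <- bnd$scene
  # per_month 1, no cloud: acquisitions equal the cube slices
  acqs <- make_acquisitions(scene, scene$years[1], per_month = 1,
                            cloud_rate = 0)
  expect_length(acqs, 6)
  for (k in seq_along(acqs)) {
    expect_equal(acqs[[k]]$values[, , 1],
                 scene$cubes[[1]]$values[, , 1, k])
    expect_equal(acqs[[k]]$valid, scene$cubes[[1]]$valid[, , k])
  }
  # full overcast: everything invalid
  dark <- make_acquisitions(scene, scene$years[1], per_month = 2,
                            cloud_rate = 1)
  expect_true(all(vapply(dark, function(a) !any(a$valid), logical(1))))

  # per-pixel valid counts equal an independent recount of emitted masks
  acqs <- make_acquisitions(scene, scene$years[1], per_month = 5,
                            cloud_rate = 0.3, seed = 77)
  of_june <- acqs[vapply(acqs, function(a) a$month == 6, logical(1))]
  expect_length(of_june, 5)
  counted <- Reduce(`+`, lapply(of_june, function(a) a$valid * 1L))
  recount <- matrix(0L, 40, 40)
  for (a in of_june) for (i in 1:40) for (j in 1:40)
    recount[i, j] <- recount[i, j] + as.integer(a$valid[i, j])
  expect_identical(counted, recount)
  # cloud fraction is consistent with its mask by construction
  expect_equal(of_june[[3]]$cloud_fraction, 1 - mean(of_june[[3]]$valid))
})

test_that("invalid configurations are rejected", {
  expect_error(scene_config(grid_rows = 95), "tile the grid")
  expect_error(scene_config(label_noise_rate = 1), "label_noise_rate")
  expect_error(scene_config(missing_rate = -0.1), "missing_rate")
  bad_phen <- default_phenology()[, , 1:3]
  expect_error(scene_config(phenology = bad_phen), "phenology must cover")
  expect_error(scene_config(rotation_scheme = c(`1` = 77)), "rotation_scheme")
})

test_that("flood injection overwrites only the requested block and months", {
  bnd <- get_small_scene()
  scene <- bnd$scene
  mod <- inject_flood_signal(scene, rows = 1:10, cols = 1:10,
                             years = scene$years[1], months = c(5, 10),
                             donor_class = 3, seed = 99)
  orig <- scene$cubes[[1]]$values
  new <- mod$cubes[[1]]$values
  # untouched outside the block and in mid-season months
  expect_identical(new[11:40, , , ], orig[11:40, , , ])
  expect_identical(new[1:10, 1:10, , 2:5], orig[1:10, 1:10, , 2:5])
  # May values moved to the rice signature
  phen <- scene$config$phenology
  expect_lt(max(abs(new[1:10, 1:10, 3, 1] - phen["3", 3, 1])), 0.12)
  expect_identical(mod$true_labels, scene$true_labels)
})
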