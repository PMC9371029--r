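# Synthetic multi-year scene generator: crop rotation, phenology, cloud
# gaps and label noise with known ground truth.

#' Scene configuration
#'
#' Parameters of the synthetic scene generator. The generator lays out
#' axis-aligned square fields that tile the grid exactly; every pixel of a
#' field shares the field's class in a given year. Crop fields alternate
#' between years according to `rotation_scheme` (default: corn and soybeans
#' swap each year -- a two-year rotation -- while rice is continuous);
#' non-crop fields keep their class. Reflectance is the class phenology mean
#' plus Gaussian noise, clipped to \[0, 1\]; a `missing_rate` fraction of
#' (pixel, month) cells is invalid; a `label_noise_rate` fraction of pixels
#' (or whole fields, see `noise_mode`) is relabeled to a uniformly random
#' other class each year, emulating error in historical crop-data-layer
#' products.
#'
#' @param grid_rows,grid_cols Grid dimensions; must be multiples of
#'   `field_size_px`.
#' @param n_years Number of label years (default 5).
#' @param start_year First year (default 2017).
#' @param months Ordered month indices (default 5:10, May--October).
#' @param bands Number of spectral bands (default 4).
#' @param field_size_px Side of the square fields in pixels (default 10).
#' @param class_set Class codes (default 1:10).
#' @param class_weights Field-class sampling weights; default favours the
#'   three crops (corn 20%, soybeans 15%, rice 15%, the rest split evenly).
#' @param rotation_scheme Named map class -> class applied each year to crop
#'   fields; classes absent from the map never rotate.
#' @param phenology Array `(class, band, month)` of mean reflectances, as
#'   from [default_phenology()].
#' @param noise_sd Reflectance noise SD (default 0.02).
#' @param missing_rate Fraction of invalid (pixel, month) cells (default 0.05).
#' @param label_noise_rate Fraction of mislabeled pixels per year (default 0.1).
#' @param noise_mode `"pixel"` (independent per pixel, the harder filtering
#'   test) or `"field"` (whole fields mislabeled, mimicking the spatially
#'   correlated error structure of real label products).
#' @param seed Integer seed; sub-seeds per year are derived deterministically.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(grid_rows = 100, grid_cols = 100, n_years = 5,
                         start_year = 2017, months = 5:10, bands = 4,
                         field_size_px = 10, class_set = 1:10,
                         class_weights = NULL,
                         rotation_scheme = c(`1` = 2, `2` = 1, `3` = 3),
                         phenology = NULL, noise_sd = 0.02,
                         missing_rate = 0.05, label_noise_rate = 0.1,
                         noise_mode = c("pixel", "field"), seed = 1) {
  noise_mode <- match.arg(noise_mode)
  stopifnot(is_count(grid_rows), is_count(grid_cols), is_count(n_years),
            is_count(field_size_px), is_count(bands))
  if (grid_rows %% field_size_px != 0 || grid_cols %% field_size_px != 0)
    stopf("configuration error: fields must tile the grid exactly (%dx%d vs field size %d)",
          grid_rows, grid_cols, field_size_px)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stopf("configuration error: noise_sd must be non-negative")
  if (!is_fraction(missing_rate) || missing_rate >= 1)
    stopf("configuration error: missing_rate must be in [0, 1)")
  if (!is_fraction(label_noise_rate) || label_noise_rate >= 1)
    stopf("configuration error: label_noise_rate must be in [0, 1)")
  class_set <- as.integer(class_set)
  if (is.null(phenology))
    phenology <- default_phenology(months, bands, class_set)
  d <- dim(phenology)
  if (is.null(d) || length(d) != 3 || d[1] < length(class_set) ||
      d[2] != bands || d[3] != length(months))
    stopf("configuration error: phenology must cover every (class, band, month)")
  if (any(!is.finite(phenology)) || any(phenology < 0) || any(phenology > 1))
    stopf("configuration error: phenology means must lie in [0, 1]")
  rot <- as.integer(rotation_scheme)
  names(rot) <- names(rotation_scheme)
  if (length(rot) && !all(rot %in% class_set))
    stopf("configuration error: rotation_scheme maps outside class_set")
  if (is.null(class_weights)) {
    class_weights <- rep(0.5 / max(length(class_set) - 3, 1), length(class_set))
    names(class_weights) <- as.character(class_set)
    if ("1" %in% names(class_weights)) class_weights["1"] <- 0.20
    if ("2" %in% names(class_weights)) class_weights["2"] <- 0.15
    if ("3" %in% names(class_weights)) class_weights["3"] <- 0.15
  }
  structure(list(grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 n_years = as.integer(n_years),
                 start_year = as.integer(start_year),
                 months = as.integer(months), bands = as.integer(bands),
                 field_size_px = as.integer(field_size_px),
                 class_set = class_set, class_weights = class_weights,
                 rotation_scheme = rot, phenology = phenology,
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 label_noise_rate = label_noise_rate,
                 noise_mode = noise_mode, seed = as.integer(seed)),
            class = "scene_config")
}

rotate_class <- function(class, rotation) {
  key <- as.character(class)
  out <- class
  hit <- key %in% names(rotation)
  out[hit] <- rotation[key[hit]]
  out
}

#' Generate a synthetic multi-year scene
#'
#' Produces, for every year: a noise-free label raster, a label raster with
#' injected label noise (the analogue of an imperfect historical product), a
#' monthly spectral cube driven by the true labels, and the boolean mask of
#' mislabeled pixels. Deterministic given the config seed.
#'
#' @param config A [scene_config()].
#' @return An object of class `crop_scene` with fields `config`, `meta`,
#'   `years`, `field_id`, `true_labels`, `noisy_labels`, `cubes`,
#'   `noise_masks` (lists keyed by year).
#' @examples
#' sc <- generate_scene(scene_config(grid_rows = 20, grid_cols = 20,
#'                                   n_years = 2, field_size_px = 10))
#' sc$true_labels[["2017"]]
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  cfg <- config
  meta <- grid_meta(cfg$grid_rows, cfg$grid_cols)
  fs <- cfg$field_size_px
  fr <- cfg$grid_rows %/% fs
  fc <- cfg$grid_cols %/% fs
  n_fields <- fr * fc
  field_id <- matrix(0L, cfg$grid_rows, cfg$grid_cols)
  for (i in seq_len(fr)) for (j in seq_len(fc))
    field_id[(i - 1) * fs + 1:fs, (j - 1) * fs + 1:fs] <- (i - 1) * fc + j

  base_class <- with_seed(cfg$seed, {
    cls <- sample(cfg$class_set, n_fields, replace = TRUE,
                  prob = cfg$class_weights[as.character(cfg$class_set)])
    # guarantee every class at least one field where possible
    missing <- setdiff(cfg$class_set, unique(cls))
    if (length(missing) && n_fields >= length(cfg$class_set)) {
      slots <- sample(seq_len(n_fields), length(missing))
      cls[slots] <- missing
    }
    cls
  })

  years <- cfg$start_year + seq_len(cfg$n_years) - 1L
  npix <- cfg$grid_rows * cfg$grid_cols
  nm <- length(cfg$months)
  true_labels <- noisy_labels <- cubes <- noise_masks <-
    stats::setNames(vector("list", cfg$n_years), as.character(years))
  K <- length(cfg$class_set)

  cls_y <- base_class
  for (yi in seq_along(years)) {
    if (yi > 1) cls_y <- rotate_class(cls_y, cfg$rotation_scheme)
    truth <- matrix(cls_y[field_id], cfg$grid_rows, cfg$grid_cols)
    true_labels[[yi]] <- label_raster(truth, meta, years[yi], cfg$class_set)

    with_seed(year_subseed(cfg$seed, yi), {
      # --- label noise ---
      noisy <- truth
      mask <- matrix(FALSE, cfg$grid_rows, cfg$grid_cols)
      if (cfg$label_noise_rate > 0) {
        if (cfg$noise_mode == "pixel") {
          hit <- which(stats::runif(npix) < cfg$label_noise_rate)
        } else {
          bad_fields <- which(stats::runif(n_fields) < cfg$label_noise_rate)
          hit <- which(field_id %in% bad_fields)
        }
        if (length(hit)) {
          shift <- if (cfg$noise_mode == "pixel")
            sample(K - 1L, length(hit), replace = TRUE)
          else {
            per_field <- stats::setNames(sample(K - 1L, length(unique(field_id[hit])),
                                                replace = TRUE),
                                         unique(field_id[hit]))
            per_field[as.character(field_id[hit])]
          }
          old_idx <- match(noisy[hit], cfg$class_set)
          noisy[hit] <- cfg$class_set[((old_idx - 1L + shift) %% K) + 1L]
          mask[hit] <- TRUE
        }
      }
      noisy_labels[[yi]] <- label_raster(noisy, meta, years[yi], cfg$class_set)
      noise_masks[[yi]] <- mask

      # --- spectral cube driven by the true labels ---
      vals <- array(NA_real_, c(cfg$grid_rows, cfg$grid_cols, cfg$bands, nm))
      ci <- match(truth, cfg$class_set)
      for (mi in seq_len(nm)) for (b in seq_len(cfg$bands)) {
        mu <- cfg$phenology[ci, b, mi]
        x <- if (cfg$noise_sd > 0) mu + stats::rnorm(npix, 0, cfg$noise_sd) else mu
        vals[, , b, mi] <- pmin(pmax(x, 0), 1)
      }
      valid <- array(TRUE, c(cfg$grid_rows, cfg$grid_cols, nm))
      if (cfg$missing_rate > 0) {
        valid[stats::runif(npix * nm) < cfg$missing_rate] <- FALSE
        vmask <- aperm(array(valid, c(dim(valid), cfg$bands)), c(1, 2, 4, 3))
        vals[!vmask] <- NA_real_
      }
      cubes[[yi]] <- monthly_cube(vals, valid, meta, years[yi], cfg$months)
    })
  }

  structure(list(config = cfg, meta = meta, years = years,
                 field_id = field_id, true_labels = true_labels,
                 noisy_labels = noisy_labels, cubes = cubes,
                 noise_masks = noise_masks),
            class = "crop_scene")
}

#' @export
print.crop_scene <- function(x, ...) {
  cat(sprintf("<crop_scene> %d x %d px, years %s, %d band(s), months %s\n",
              x$meta$rows, x$meta$cols,
              paste(range(x$years), collapse = "-"),
              x$config$bands, paste(x$config$months, collapse = ",")))
  invisible(x)
}

#' Locate the fields of a class
#'
#' Returns the pixel extents of every field whose true label equals `class`
#' in the given year. Useful for carving out blocks (e.g. a wetland field to
#' perturb with [inject_flood_signal()]).
#'
#' @param scene A [generate_scene()] result.
#' @param class Class code to look for.
#' @param year Year (defaults to the first).
#' @return data.frame with columns `field_id`, `row0`, `row1`, `col0`, `col1`.
#' @export
locate_fields <- function(scene, class, year = scene$years[1]) {
  truth <- scene$true_labels[[as.character(year)]]$values
  fs <- scene$config$field_size_px
  ids <- sort(unique(scene$field_id[truth == class]))
  fc <- scene$meta$cols %/% fs
  i <- (ids - 1L) %/% fc
  j <- (ids - 1L) %% fc
  data.frame(field_id = ids,
             row0 = i * fs + 1L, row1 = (i + 1L) * fs,
             col0 = j * fs + 1L, col1 = (j + 1L) * fs)
}

#' Overwrite a block's spectra with another class's signature
#'
#' Emulates transient surface conditions -- typically early/late-season
#' inundation of a wetland after heavy precipitation -- by replacing the
#' reflectance of a pixel block, in the given months only, with the
#' phenology mean of a donor class (default rice) plus noise. Labels are
#' untouched, so the block becomes a known source of spectral confusion
#' with the donor class for any model applied to the modified cube.
#'
#' @param scene A [generate_scene()] result.
#' @param rows,cols Integer index vectors delimiting the block.
#' @param years Years to perturb (default: all).
#' @param months Months to overwrite (default `c(5, 10)`: the season edges,
#'   leaving June--September untouched).
#' @param donor_class Class whose phenology is imprinted (default 3, rice).
#' @param seed Seed for the perturbation noise.
#' @return The modified `crop_scene`.
#' @export
inject_flood_signal <- function(scene, rows, cols, years = scene$years,
                                months = c(5, 10), donor_class = 3,
                                seed = scene$config$seed + 77) {
  cfg <- scene$config
  di <- match(donor_class, cfg$class_set)
  if (is.na(di)) stopf("donor_class %s not in class_set", donor_class)
  mi_all <- match(months, cfg$months)
  if (anyNA(mi_all)) stopf("months %s not in the scene",
                           paste(months[is.na(mi_all)], collapse = ","))
  with_seed(seed, {
    for (yr in as.character(years)) {
      cube <- scene$cubes[[yr]]
      for (mi in mi_all) for (b in seq_len(cfg$bands)) {
        mu <- cfg$phenology[di, b, mi]
        blk <- mu + stats::rnorm(length(rows) * length(cols), 0, cfg$noise_sd)
        old <- cube$values[rows, cols, b, mi]
        blk <- pmin(pmax(blk, 0), 1)
        blk[is.na(old)] <- NA_real_  # keep missing cells missing
        cube$values[rows, cols, b, mi] <- blk
      }
      scene$cubes[[yr]] <- cube
    }
  })
  scene
}

#' Emit dated acquisitions from a scene year
#'
#' Expands one year's cube into `per_month` dated acquisitions per month,
#' each an independent noisy copy of the cube slice with its own random
#' cloud mask covering about `cloud_rate` of pixels (on top of the scene's
#' own missing cells). This is the raw input that [build_cube()] composites
#' back into a monthly cube.
#'
#' @param scene A [generate_scene()] result.
#' @param year Year to expand (defaults to the first).
#' @param per_month Acquisitions per month (>= 1).
#' @param cloud_rate Fraction of pixels clouded per acquisition.
#' @param noise_sd Extra per-acquisition noise SD (default 0: copies equal
#'   the cube slices exactly).
#' @param seed Seed (defaults to a deterministic function of the scene seed).
#' @return List of [acquisition()] objects.
#' @export
make_acquisitions <- function(scene, year = scene$years[1], per_month = 1,
                              cloud_rate = 0, noise_sd = 0,
                              seed = scene$config$seed + 31 * as.integer(year) %% 100000) {
  stopifnot(is_count(per_month), is_fraction(cloud_rate))
  cube <- scene$cubes[[as.character(year)]]
  if (is.null(cube)) stopf("year %s not in scene", year)
  npix <- cube$meta$rows * cube$meta$cols
  out <- list()
  with_seed(seed, {
    for (mi in seq_along(cube$months)) {
      for (k in seq_len(per_month)) {
        vals <- cube$values[, , , mi, drop = FALSE]
        dim(vals) <- dim(cube$values)[1:3]
        if (noise_sd > 0)
          vals <- pmin(pmax(vals + stats::rnorm(length(vals), 0, noise_sd), 0), 1)
        valid <- cube$valid[, , mi]
        if (cloud_rate > 0) {
          cloud <- matrix(stats::runif(npix) < cloud_rate,
                          cube$meta$rows, cube$meta$cols)
          valid <- valid & !cloud
        }
        vmask <- array(valid, dim = dim(vals))
        vals[!vmask] <- NA_real_
        out[[length(out) + 1L]] <- acquisition(
          vals, valid, year = cube$year, month = cube$months[mi],
          ordinal = k, meta = cube$meta)
      }
    }
  })
  out
}
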