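# Core raster containers: categorical label rasters and monthly spectral cubes.

LABEL_NODATA <- 0L

#' Categorical label raster
#'
#' One year of per-pixel crop/land-cover codes on a shared grid. Codes follow
#' the reclassified 10-class scheme (1 Corn, 2 Soybeans, 3 Rice, 4 Water,
#' 5 Developed, 6 Forest, 7 Grassland, 8 Wetlands, 9 Shrubland, 10 Other);
#' 0 is the nodata sentinel, matching the CDL convention of 0 as background.
#'
#' @param values Integer matrix of class codes (0 = nodata).
#' @param meta A [grid_meta()]; defaults to a bare grid of the matrix shape.
#' @param year Integer year the labels refer to.
#' @param class_set Permitted class codes (default `1:10`).
#' @return An object of class `label_raster`.
#' @examples
#' label_raster(matrix(1L, 4, 4), year = 2019)
#' @export
label_raster <- function(values, meta = NULL, year = NA_integer_,
                         class_set = 1:10) {
  if (!is.matrix(values)) stopf("values must be a matrix")
  storage.mode(values) <- "integer"
  if (is.null(meta)) meta <- grid_meta(nrow(values), ncol(values))
  if (nrow(values) != meta$rows || ncol(values) != meta$cols)
    stopf("grid alignment error: values are %d x %d but meta says %d x %d",
          nrow(values), ncol(values), meta$rows, meta$cols)
  bad <- setdiff(unique(values[!is.na(values)]), c(LABEL_NODATA, class_set))
  if (length(bad))
    stopf("validation error: unknown class code(s): %s",
          paste(sort(bad), collapse = ", "))
  values[is.na(values)] <- LABEL_NODATA
  structure(list(meta = meta, year = as.integer(year), values = values,
                 class_set = as.integer(class_set)),
            class = "label_raster")
}

#' @export
print.label_raster <- function(x, ...) {
  nd <- sum(x$values == LABEL_NODATA)
  cat(sprintf("<label_raster> year %s, %d x %d px, %d nodata cell(s)\n",
              ifelse(is.na(x$year), "?", x$year), x$meta$rows, x$meta$cols, nd))
  tab <- table(x$values[x$values != LABEL_NODATA])
  if (length(tab)) {
    cat("  classes:",
        paste(sprintf("%s:%d", names(tab), as.integer(tab)), collapse = " "),
        "\n")
  }
  invisible(x)
}

#' Monthly spectral cube
#'
#' Per-pixel, per-month, per-band reflectance for one year's growing season
#' (months default to May--October), with a per-pixel/month validity mask.
#' Values are reflectances in \[0, 1\]; cells flagged invalid carry `NA`.
#'
#' @param values Numeric 4-d array with dims `(rows, cols, bands, months)`.
#' @param valid Logical 3-d array with dims `(rows, cols, months)`; defaults
#'   to all-valid.
#' @param meta A [grid_meta()]; defaults to the array's shape.
#' @param year Integer year.
#' @param months Ordered integer month indices, length `dim(values)[4]`.
#' @return An object of class `monthly_cube`.
#' @export
monthly_cube <- function(values, valid = NULL, meta = NULL,
                         year = NA_integer_, months = NULL) {
  if (!is.array(values) || length(dim(values)) != 4L)
    stopf("values must be a 4-d array (rows, cols, bands, months)")
  d <- dim(values)
  if (is.null(months)) months <- seq(5L, length.out = d[4])
  months <- as.integer(months)
  if (length(months) != d[4])
    stopf("months has length %d but values has %d month slices",
          length(months), d[4])
  if (is.null(meta)) meta <- grid_meta(d[1], d[2])
  if (d[1] != meta$rows || d[2] != meta$cols)
    stopf("grid alignment error: cube is %d x %d but meta says %d x %d",
          d[1], d[2], meta$rows, meta$cols)
  if (is.null(valid)) valid <- array(TRUE, dim = d[c(1, 2, 4)])
  if (!identical(dim(valid), d[c(1, 2, 4)]))
    stopf("valid mask dims must be (rows, cols, months)")
  # values must be finite wherever valid
  vmask <- aperm(array(valid, dim = c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  if (any(!is.finite(values[vmask])))
    stopf("validation error: non-finite reflectance at cells flagged valid")
  rng <- range(values[vmask], na.rm = TRUE)
  if (length(rng) == 2 && is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1))
    stopf("validation error: reflectance outside [0, 1]")
  structure(list(meta = meta, year = as.integer(year), months = months,
                 bands = d[3], values = values, valid = valid),
            class = "monthly_cube")
}

#' @export
print.monthly_cube <- function(x, ...) {
  cat(sprintf(
    "<monthly_cube> year %s, %d x %d px, %d band(s), months %s, %.1f%% valid\n",
    ifelse(is.na(x$year), "?", x$year), x$meta$rows, x$meta$cols, x$bands,
    paste(x$months, collapse = ","), 100 * mean(x$valid)))
  invisible(x)
}

# Pixels usable for sampling/mapping: valid (possibly gap-filled) in every
# month. build_cube() marks unusable pixels invalid across all months.
usable_pixels <- function(cube) {
  apply(cube$valid, c(1, 2), all)
}
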