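# Raster I/O.
#
# Rasters are stored as baseline TIFF (via the tiff package) plus a JSON
# sidecar (<path>.json) carrying the grid metadata that plain TIFF cannot:
# pixel size, origin, CRS label, year, month list and nodata convention.
# Label rasters are 8-bit (exact for codes 0..255, nodata = 0). Reflectance
# is stored as 16-bit scaled integers -- the scaled-DN convention of
# distributed satellite reflectance products -- so written values are
# quantized to multiples of 1/65535 (~1.5e-5 reflectance); values already on
# that grid round-trip exactly. Validity masks are stored as an extra 0/1
# TIFF page per month, since TIFF has no NaN-safe nodata for integer samples.

RFL_SCALE <- 65535

meta_to_list <- function(meta) {
  list(rows = meta$rows, cols = meta$cols, pixel_size = meta$pixel_size,
       origin = meta$origin, crs_label = meta$crs_label)
}

meta_from_list <- function(x) {
  grid_meta(x$rows, x$cols, x$pixel_size, unlist(x$origin), x$crs_label)
}

write_sidecar <- function(path, payload) {
  jsonlite::write_json(payload, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
}

read_sidecar <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stopf("missing metadata sidecar: %s", side)
  jsonlite::read_json(side, simplifyVector = TRUE)
}

#' Write / read a label raster
#'
#' `write_label_raster()` stores the class codes as an 8-bit TIFF with a JSON
#' metadata sidecar; `read_label_raster()` restores it. The round trip is
#' exact (codes are small integers). Unknown class codes are rejected at read
#' time so corrupt files fail loudly rather than propagating.
#'
#' @param raster A [label_raster()].
#' @param path Output TIFF path (a `<path>.json` sidecar is written next to it).
#' @return `read_label_raster()` returns a [label_raster()];
#'   `write_label_raster()` returns `path` invisibly.
#' @export
write_label_raster <- function(raster, path) {
  stopifnot(inherits(raster, "label_raster"))
  tiff::writeTIFF(raster$values / 255, path, bits.per.sample = 8L,
                  compression = "none")
  write_sidecar(path, c(meta_to_list(raster$meta),
                        list(kind = "label_raster", year = raster$year,
                             nodata = LABEL_NODATA,
                             class_set = raster$class_set)))
  invisible(path)
}

#' @rdname write_label_raster
#' @export
read_label_raster <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  side <- read_sidecar(path)
  if (!identical(side$kind, "label_raster"))
    stopf("%s is not a label raster (kind '%s')", path, side$kind %||% "?")
  vals <- round(tiff::readTIFF(path) * 255)
  storage.mode(vals) <- "integer"
  label_raster(vals, meta = meta_from_list(side),
               year = side$year %||% NA_integer_,
               class_set = as.integer(side$class_set %||% 1:10))
}

cube_month_file <- function(dir, month) {
  file.path(dir, sprintf("month_%02d.tif", month))
}

#' Write / read a monthly spectral cube
#'
#' One multi-page TIFF per month (`month_MM.tif`: pages 1..B are the spectral
#' bands, page B+1 is the 0/1 validity mask) plus a `cube.json` sidecar with
#' the grid metadata. Reflectance is quantized to 16-bit (step 1/65535);
#' invalid cells are stored as 0 and restored to `NA`.
#'
#' @param cube A [monthly_cube()].
#' @param dir Output directory (created if needed).
#' @param paths_by_month For `read_monthly_cube()`: a directory written by
#'   `write_monthly_cube()`, or a named list/vector of month TIFF paths with
#'   month indices as names (gaps between months are allowed).
#' @return `read_monthly_cube()` returns a [monthly_cube()];
#'   `write_monthly_cube()` returns `dir` invisibly.
#' @export
write_monthly_cube <- function(cube, dir) {
  stopifnot(inherits(cube, "monthly_cube"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (mi in seq_along(cube$months)) {
    pages <- vector("list", cube$bands + 1L)
    msk <- cube$valid[, , mi]
    for (b in seq_len(cube$bands)) {
      v <- cube$values[, , b, mi]
      v[!msk] <- 0
      pages[[b]] <- v
    }
    pages[[cube$bands + 1L]] <- msk * 1
    tiff::writeTIFF(pages, cube_month_file(dir, cube$months[mi]),
                    bits.per.sample = 16L, compression = "none")
  }
  write_sidecar(file.path(dir, "cube"),
                c(meta_to_list(cube$meta),
                  list(kind = "monthly_cube", year = cube$year,
                       months = cube$months, bands = cube$bands)))
  invisible(dir)
}

#' @rdname write_monthly_cube
#' @export
read_monthly_cube <- function(paths_by_month) {
  if (length(paths_by_month) == 1L && dir.exists(paths_by_month[[1]])) {
    dir <- paths_by_month[[1]]
    side <- read_sidecar(file.path(dir, "cube"))
    months <- as.integer(unlist(side$months))
    paths <- stats::setNames(cube_month_file(dir, months), months)
  } else {
    paths <- unlist(paths_by_month)
    if (is.null(names(paths)) || any(!nzchar(names(paths))))
      stopf("paths_by_month must be named by month index")
    months <- as.integer(names(paths))
    side <- read_sidecar(file.path(dirname(paths[[1]]), "cube"))
  }
  if (!identical(side$kind, "monthly_cube"))
    stopf("not a monthly cube (kind '%s')", side$kind %||% "?")
  meta <- meta_from_list(side)
  bands <- as.integer(side$bands)
  nm <- length(months)
  values <- array(NA_real_, dim = c(meta$rows, meta$cols, bands, nm))
  valid <- array(FALSE, dim = c(meta$rows, meta$cols, nm))
  for (mi in seq_len(nm)) {
    pages <- tiff::readTIFF(paths[[mi]], all = TRUE)
    if (length(pages) != bands + 1L)
      stopf("validation error: %s has %d band page(s), expected %d",
            paths[[mi]], length(pages) - 1L, bands)
    if (nrow(pages[[1]]) != meta$rows || ncol(pages[[1]]) != meta$cols)
      stopf("grid alignment error: %s is %d x %d, expected %d x %d",
            paths[[mi]], nrow(pages[[1]]), ncol(pages[[1]]),
            meta$rows, meta$cols)
    msk <- pages[[bands + 1L]] > 0.5
    for (b in seq_len(bands)) {
      v <- pages[[b]]
      v[!msk] <- NA_real_
      values[, , b, mi] <- v
    }
    valid[, , mi] <- msk
  }
  monthly_cube(values, valid, meta = meta,
               year = side$year %||% NA_integer_, months = months)
}

#' Class reclassification table
#'
#' The mapping from raw CDL-style crop codes to the condensed 10-class
#' scheme used throughout the pipeline. The default table (shipped as
#' `extdata/cdl_class_map.csv`) collapses the raw codes into 1 Corn,
#' 2 Soybeans, 3 Rice, 4 Water, 5 Developed, 6 Forest, 7 Grassland,
#' 8 Wetlands, 9 Shrubland; any raw code not listed falls through to
#' 10 Other. The mapping is data, not code: pass `path` to use an edited CSV
#' (columns `raw_code`, `new_code`, `name`).
#'
#' @param path Optional CSV path overriding the shipped default.
#' @return A data.frame with columns `raw_code`, `new_code`, `name`.
#' @export
default_class_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cdl_class_map.csv", package = "cropsift")
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("raw_code", "new_code", "name")
  if (!all(need %in% names(map)))
    stopf("class map must have columns: %s", paste(need, collapse = ", "))
  map$raw_code <- as.integer(map$raw_code)
  map$new_code <- as.integer(map$new_code)
  map
}

#' Reclassify raw label codes into the condensed class scheme
#'
#' Applies a raw-code to new-code lookup; raw codes absent from the table
#' map to the catch-all class 10 ("Other"), so the function is total over
#' integer inputs. Nodata (0) is preserved. Note that reclassification is
#' idempotent on already-condensed grids only if the map contains identity
#' entries for codes 1..10 (the shipped default does not: raw code 1 is Corn
#' but raw codes 2, 4, 6..10 are unlisted and therefore become Other).
#'
#' @param raw Integer matrix of raw codes, or a [label_raster()].
#' @param class_map Reclassification table as from [default_class_map()].
#' @param year,meta Passed through to the resulting [label_raster()] when
#'   `raw` is a bare matrix.
#' @return A [label_raster()] with codes in 1..10 (0 = nodata).
#' @examples
#' reclassify(matrix(c(5L, 12L, 999L, 0L), 2, 2))
#' @export
reclassify <- function(raw, class_map = default_class_map(),
                       year = NA_integer_, meta = NULL) {
  if (inherits(raw, "label_raster")) {
    meta <- raw$meta; year <- raw$year; raw <- raw$values
  }
  stopifnot(is.matrix(raw))
  lut <- stats::setNames(class_map$new_code, class_map$raw_code)
  out <- matrix(10L, nrow(raw), ncol(raw))
  hit <- match(as.vector(raw), class_map$raw_code)
  out[!is.na(hit)] <- class_map$new_code[hit[!is.na(hit)]]
  out[raw == LABEL_NODATA] <- LABEL_NODATA
  label_raster(out, meta = meta, year = year)
}
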