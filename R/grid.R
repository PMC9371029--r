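#' Grid metadata
#'
#' Describes the pixel grid that all rasters in one pipeline run must share:
#' dimensions, pixel size (metres; the pipeline targets a common 30 m grid so
#' that image time series and historical label rasters align), origin of the
#' upper-left corner, and an opaque CRS label. Rasters are combined only after
#' an explicit grid-identity check; nothing is ever silently resampled.
#'
#' @param rows,cols Positive integer grid dimensions.
#' @param pixel_size Positive pixel edge length in metres (default 30).
#' @param origin Numeric length-2 (x, y) of the grid origin.
#' @param crs_label Opaque coordinate-system label carried through I/O.
#' @return An object of class `grid_meta`.
#' @examples
#' grid_meta(100, 100)
#' @export
grid_meta <- function(rows, cols, pixel_size = 30, origin = c(0, 0),
                      crs_label = "local") {
  if (!is_count(rows) || !is_count(cols))
    stopf("grid dimensions must be positive integers")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stopf("pixel_size must be a positive real")
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         pixel_size = as.numeric(pixel_size),
         origin = as.numeric(origin[1:2]),
         crs_label = as.character(crs_label)),
    class = "grid_meta")
}

#' @export
print.grid_meta <- function(x, ...) {
  cat(sprintf("<grid_meta> %d x %d px @ %g m, origin (%g, %g), crs '%s'\n",
              x$rows, x$cols, x$pixel_size, x$origin[1], x$origin[2],
              x$crs_label))
  invisible(x)
}

#' Test whether two rasters share the same grid
#'
#' @param a,b `grid_meta` objects (or objects with a `$meta` field).
#' @return Logical scalar.
#' @export
same_grid <- function(a, b) {
  ma <- if (inherits(a, "grid_meta")) a else a$meta
  mb <- if (inherits(b, "grid_meta")) b else b$meta
  isTRUE(ma$rows == mb$rows) && isTRUE(ma$cols == mb$cols) &&
    isTRUE(all.equal(ma$pixel_size, mb$pixel_size)) &&
    isTRUE(all.equal(ma$origin, mb$origin)) &&
    identical(ma$crs_label, mb$crs_label)
}

check_same_grid <- function(a, b, what = "rasters") {
  if (!same_grid(a, b))
    stopf("grid alignment error: %s do not share the same grid", what)
  invisible(TRUE)
}
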