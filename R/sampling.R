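# Spatiotemporal training-sample selection from label rasters + cubes.

#' 5x5 label-homogeneity mask
#'
#' A cell is eligible only if the full `window` x `window` neighbourhood
#' centred on it lies inside the grid, contains no nodata, and carries the
#' same label throughout -- pixels well inside larger fields. This excludes
#' mixed pixels at field boundaries, whose spectra blend several cover
#' types and would contaminate the training set.
#'
#' @param labels A [label_raster()].
#' @param window Odd window size >= 3 (default 5).
#' @return Logical matrix of the grid shape.
#' @export
homogeneous_mask <- function(labels, window = 5L) {
  stopifnot(inherits(labels, "label_raster"))
  if (window %% 2L != 1L || window < 3L) stopf("window must be odd and >= 3")
  v <- labels$values
  nr <- nrow(v); nc <- ncol(v)
  h <- (window - 1L) %/% 2L
  ok <- matrix(FALSE, nr, nc)
  if (nr < window || nc < window) return(ok)
  core_r <- (h + 1L):(nr - h)
  core_c <- (h + 1L):(nc - h)
  agree <- matrix(TRUE, length(core_r), length(core_c))
  centre <- v[core_r, core_c]
  for (dr in -h:h) for (dc in -h:h) {
    nb <- v[core_r + dr, core_c + dc]
    agree <- agree & (nb == centre) & (nb != LABEL_NODATA)
  }
  ok[core_r, core_c] <- agree
  ok
}

#' Rotation-parity label-stability mask
#'
#' Under a two-year crop rotation, a pixel's crop class recurs in years of
#' the same parity (even/odd). The mask marks cells whose label in `year`
#' matches their label in every other available year of the same parity --
#' the reading of "keep the same areas in even and odd years respectively"
#' that exploits the rotation cycle. With no other same-parity year
#' available the rule is vacuous: the mask is all-true and a warning is
#' issued. Non-crop covers are constant across years, so they pass for
#' every year automatically.
#'
#' @param labels_by_year Named list (names = years) of [label_raster()].
#' @param year The year being sampled.
#' @return Logical matrix of the grid shape.
#' @export
parity_stable_mask <- function(labels_by_year, year) {
  yrs <- as.integer(names(labels_by_year))
  year <- as.integer(year)
  if (!year %in% yrs) stopf("year %d not present in labels_by_year", year)
  ref <- labels_by_year[[as.character(year)]]
  peers <- yrs[yrs != year & (yrs %% 2L) == (year %% 2L)]
  if (length(peers) == 0L) {
    warnf("no other year with the parity of %d: parity rule is vacuous", year)
    return(matrix(TRUE, ref$meta$rows, ref$meta$cols))
  }
  ok <- matrix(TRUE, ref$meta$rows, ref$meta$cols)
  for (p in peers) {
    other <- labels_by_year[[as.character(p)]]
    check_same_grid(ref, other, "label rasters across years")
    ok <- ok & (other$values == ref$values)
  }
  ok
}

feature_names <- function(n_months, n_bands) {
  sprintf("f_%d", seq_len(n_months * n_bands) - 1L)
}

#' Extract per-pixel feature matrices from a cube
#'
#' Concatenates the cube's monthly band values month-major, band-minor:
#' feature `f_{m*B + b}` (0-based) is band `b` of the `m`-th requested
#' month. A single month therefore yields `n_bands` features and the full
#' May--October series `6 * n_bands`.
#'
#' @param cube A [monthly_cube()].
#' @param months_subset Months to include (default: all cube months). A
#'   requested month absent from the cube is an error naming the month.
#' @param bands_subset Bands to include (default: all).
#' @param points Optional data.frame/matrix with columns `row`, `col`; when
#'   omitted, all pixels are returned in column-major pixel order.
#' @return Numeric matrix, one row per point/pixel, with `f_*` column names.
#' @export
build_features <- function(cube, months_subset = NULL, bands_subset = NULL,
                           points = NULL) {
  stopifnot(inherits(cube, "monthly_cube"))
  months_subset <- months_subset %||% cube$months
  miss <- setdiff(months_subset, cube$months)
  if (length(miss))
    stopf("month(s) %s not present in cube", paste(miss, collapse = ", "))
  bands_subset <- bands_subset %||% seq_len(cube$bands)
  mi <- match(months_subset, cube$months)
  npix <- cube$meta$rows * cube$meta$cols
  if (is.null(points)) {
    idx <- seq_len(npix)
  } else {
    points <- as.data.frame(points)
    idx <- (points$col - 1L) * cube$meta$rows + points$row
  }
  out <- matrix(NA_real_, length(idx),
                length(months_subset) * length(bands_subset))
  k <- 0L
  for (m in mi) for (b in bands_subset) {
    k <- k + 1L
    plane <- cube$values[, , b, m]
    out[, k] <- plane[idx]
  }
  colnames(out) <- feature_names(length(months_subset), length(bands_subset))
  out
}

#' Draw candidate training samples
#'
#' Uniform random sampling without replacement over the eligible cells of
#' one year, retaining points per class until each class target is reached
#' or the cycle budget is exhausted (each inspected random point costs one
#' cycle, mirroring "repeat until a number of cycles or a number of points
#' is reached"). Eligibility is supplied by the caller -- typically
#' `homogeneous_mask(...) & parity_stable_mask(...)` -- and is always
#' intersected with the cube's usable pixels. Features are extracted from
#' the cube at the drawn points. Deterministic given `seed`.
#'
#' @param labels A [label_raster()] for the year (candidate labels, i.e.
#'   the historical product's possibly-wrong codes).
#' @param cube The matching [monthly_cube()] (gap-filled).
#' @param eligibility Logical matrix; default all-true.
#' @param n_target Per-class sample target: a single number applied to all
#'   classes, or a named vector keyed by class code. `Inf` = exhaust.
#' @param max_cycles Cycle budget (default `Inf`).
#' @param seed Integer seed.
#' @return A `sample_table` data.frame with columns `row`, `col`, `year`,
#'   `label`, `f_*`, `provenance`, `discard_reason`. Classes with zero
#'   eligible cells are reported with a warning.
#' @export
draw_candidates <- function(labels, cube, eligibility = NULL,
                            n_target = Inf, max_cycles = Inf, seed = 1) {
  stopifnot(inherits(labels, "label_raster"), inherits(cube, "monthly_cube"))
  check_same_grid(labels, cube, "labels and cube")
  elig <- eligibility %||% matrix(TRUE, labels$meta$rows, labels$meta$cols)
  elig <- elig & usable_pixels(cube) & (labels$values != LABEL_NODATA)
  classes <- labels$class_set
  if (is.null(names(n_target))) {
    target <- stats::setNames(rep(n_target[1], length(classes)),
                              as.character(classes))
  } else {
    target <- stats::setNames(rep(0, length(classes)), as.character(classes))
    target[names(n_target)] <- unlist(n_target)
  }
  cells <- which(elig)
  taken <- integer(0)
  if (length(cells)) {
    order <- with_seed(seed, sample(cells, length(cells)))
    got <- stats::setNames(rep(0L, length(classes)), as.character(classes))
    cycles <- 0
    for (cell in order) {
      if (cycles >= max_cycles || all(got >= target)) break
      cycles <- cycles + 1
      lab <- as.character(labels$values[cell])
      if (got[lab] < target[lab]) {
        got[lab] <- got[lab] + 1L
        taken <- c(taken, cell)
      }
    }
  }
  present <- unique(labels$values[cells])
  empty <- setdiff(as.character(classes), as.character(present))
  want <- names(target)[target > 0]
  if (length(intersect(empty, want)))
    warnf("class(es) %s have no eligible cells in year %s",
          paste(intersect(empty, want), collapse = ", "), labels$year)
  rows <- ((taken - 1L) %% labels$meta$rows) + 1L
  cols <- ((taken - 1L) %/% labels$meta$rows) + 1L
  feats <- build_features(cube, points = data.frame(row = rows, col = cols))
  out <- data.frame(row = rows, col = cols,
                    year = rep(labels$year, length(taken)),
                    label = labels$values[taken])
  out <- cbind(out, as.data.frame(feats))
  out$provenance <- rep("candidate", nrow(out))
  out$discard_reason <- rep(NA_character_, nrow(out))
  class(out) <- c("sample_table", "data.frame")
  attr(out, "months") <- cube$months
  attr(out, "bands") <- cube$bands
  out
}

sample_features <- function(samples) {
  fcols <- grep("^f_", names(samples), value = TRUE)
  as.matrix(samples[, fcols, drop = FALSE])
}

#' Write / read a sample table as CSV
#'
#' Plain CSV with columns `row, col, year, label, f_0..f_{MB-1}, provenance,
#' discard_reason`. Feature values are formatted with 17 significant digits
#' so doubles round-trip exactly.
#'
#' @param samples A sample table data.frame.
#' @param path CSV path.
#' @return `read_samples()` returns the data.frame; `write_samples()`
#'   returns `path` invisibly.
#' @export
write_samples <- function(samples, path) {
  df <- as.data.frame(samples)
  fcols <- grep("^f_", names(df), value = TRUE)
  for (cn in fcols) df[[cn]] <- sprintf("%.17g", df[[cn]])
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = character(0))
  fcols <- grep("^f_", names(df), value = TRUE)
  for (cn in fcols) df[[cn]] <- as.numeric(df[[cn]])
  df$discard_reason[df$discard_reason == ""] <- NA_character_
  class(df) <- c("sample_table", "data.frame")
  df
}
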