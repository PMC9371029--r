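# Monthly time-series preparation: cloud filtering, median compositing,
# gap interpolation, Savitzky-Golay smoothing.

#' Single-date acquisition
#'
#' One dated raster observation of the scene: per-band reflectance plus a
#' per-pixel validity mask (quality/cloud mask already applied). The cloud
#' fraction is defined as `1 - mean(valid)` and recomputed on construction.
#'
#' @param values Numeric 3-d array `(rows, cols, bands)`; `NA` where invalid.
#' @param valid Logical matrix `(rows, cols)`; defaults to complete cases.
#' @param year,month,ordinal Date of the acquisition (`ordinal` distinguishes
#'   repeat passes within a month).
#' @param meta A [grid_meta()].
#' @return An object of class `acquisition`.
#' @export
acquisition <- function(values, valid = NULL, year = NA_integer_,
                        month = NA_integer_, ordinal = 1L, meta = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  d <- dim(values)
  if (is.null(valid)) valid <- apply(is.finite(values), c(1, 2), all)
  stopifnot(identical(dim(valid), d[1:2]))
  if (is.null(meta)) meta <- grid_meta(d[1], d[2])
  structure(list(meta = meta, year = as.integer(year),
                 month = as.integer(month), ordinal = as.integer(ordinal),
                 values = values, valid = valid,
                 cloud_fraction = 1 - mean(valid)),
            class = "acquisition")
}

#' Select acquisitions below a cloud-cover threshold
#'
#' Keeps acquisitions whose cloud fraction is strictly less than `max_cloud`
#' (default 0.5, i.e. "less than 50% cloud"), preserving order. An empty
#' result is allowed: the month simply becomes a gap to be interpolated.
#'
#' @param acqs List of [acquisition()] objects.
#' @param max_cloud Fraction in \[0, 1\]; strict upper bound.
#' @return The retained sublist.
#' @export
filter_acquisitions <- function(acqs, max_cloud = 0.5) {
  stopifnot(is_fraction(max_cloud))
  acqs[vapply(acqs, function(a) a$cloud_fraction < max_cloud, logical(1))]
}

#' Median-composite the acquisitions of one month
#'
#' Per pixel and band, the median over the acquisitions in which that pixel
#' is valid; a pixel invalid in every acquisition is invalid in the
#' composite. The median is permutation-invariant, so acquisition order does
#' not matter.
#'
#' @param acqs Non-empty list of [acquisition()] objects of one month.
#' @return List with `values` (rows x cols x bands, `NA` where invalid) and
#'   `valid` (rows x cols).
#' @export
composite_month <- function(acqs) {
  if (length(acqs) == 0L) stopf("composite_month needs at least 1 acquisition")
  meta <- acqs[[1]]$meta
  for (a in acqs) check_same_grid(meta, a, "acquisitions of one month")
  d <- dim(acqs[[1]]$values)
  n <- length(acqs)
  valid_stack <- vapply(acqs, function(a) a$valid, acqs[[1]]$valid)
  dim(valid_stack) <- c(d[1] * d[2], n)
  valid_out <- rowSums(valid_stack) > 0
  values <- array(NA_real_, d)
  for (b in seq_len(d[3])) {
    stack <- vapply(acqs, function(a) {
      v <- a$values[, , b]
      v[!a$valid] <- NA_real_
      v
    }, acqs[[1]]$values[, , 1])
    dim(stack) <- c(d[1] * d[2], n)
    med <- apply(stack, 1, stats::median, na.rm = TRUE)
    med[!valid_out] <- NA_real_
    values[, , b] <- med
  }
  dim(valid_out) <- d[1:2]
  list(values = values, valid = valid_out)
}

#' Fill gaps in a monthly series
#'
#' An invalid interior month is replaced by the mean of the nearest valid
#' earlier and nearest valid later months ("the average of the phases before
#' and after"); nearest valid values -- not strictly adjacent months -- are
#' used so that runs of consecutive gaps are still defined. Leading/trailing
#' gaps take the nearest valid value. A series with fewer than two valid
#' entries cannot be filled and is an error; at cube level such pixels are
#' flagged unusable instead.
#'
#' @param values Numeric vector, one entry per month.
#' @param valid Logical vector of the same length; defaults to `!is.na(values)`.
#' @return Fully valid numeric vector of the same length.
#' @examples
#' interpolate_gaps(c(0.2, NA, 0.4))                    # -> 0.2 0.3 0.4
#' interpolate_gaps(c(NA, 0.5, NA, NA, 0.9, 0.7))       # -> 0.5 0.5 0.7 0.7 0.9 0.7
#' @export
interpolate_gaps <- function(values, valid = NULL) {
  if (is.null(valid)) valid <- !is.na(values)
  stopifnot(length(valid) == length(values))
  if (sum(valid) < 2L)
    stopf("cannot interpolate: fewer than 2 valid entries")
  fill_series_matrix(matrix(values, nrow = 1), matrix(valid, nrow = 1))[1, ]
}

# Vectorized nearest-valid-neighbour mean fill over a matrix of series
# (rows = pixels, cols = months). Rows must have >= 2 valid entries.
fill_series_matrix <- function(X, V) {
  L <- ncol(X)
  prev <- matrix(NA_real_, nrow(X), L)  # nearest valid value at or before m
  nxt <- matrix(NA_real_, nrow(X), L)
  run <- rep(NA_real_, nrow(X))
  for (m in seq_len(L)) {
    run[V[, m]] <- X[V[, m], m]
    prev[, m] <- run
  }
  run <- rep(NA_real_, nrow(X))
  for (m in rev(seq_len(L))) {
    run[V[, m]] <- X[V[, m], m]
    nxt[, m] <- run
  }
  both <- !is.na(prev) & !is.na(nxt)
  fill <- ifelse(both, (prev + nxt) / 2, ifelse(is.na(prev), nxt, prev))
  out <- X
  out[!V] <- fill[!V]
  out
}

#' Savitzky-Golay smoothing of a monthly series
#'
#' Least-squares local polynomial smoothing (via [signal::sgolayfilt()]) to
#' damp residual noise after compositing and gap filling. Length is
#' preserved; polynomials up to `polyorder` (including constants) are
#' reproduced exactly up to floating point. Series shorter than the window
#' are returned unchanged with a warning rather than failing, since a short
#' season is a data property, not a caller bug.
#'
#' @param values Fully valid numeric vector.
#' @param window Odd window length (default 5, the shortest standard window
#'   usable on a 6-month series).
#' @param polyorder Polynomial degree `< window` (default 2).
#' @return Smoothed numeric vector of the same length.
#' @export
smooth_series <- function(values, window = 5L, polyorder = 2L) {
  if (window %% 2L != 1L || window < 3L) stopf("window must be odd and >= 3")
  if (polyorder >= window) stopf("polyorder must be < window")
  if (anyNA(values)) stopf("smooth_series requires a fully valid series")
  if (length(values) < window) {
    warnf("series length %d < window %d: smoothing skipped",
          length(values), window)
    return(values)
  }
  signal::sgolayfilt(values, p = polyorder, n = window)
}

# L x L linear operator equivalent to sgolayfilt on length-L series
# (sgolayfilt is linear, so columns are its action on the identity basis).
# Used to smooth all pixels of a cube with one matrix product.
sg_operator <- function(L, window, polyorder) {
  S <- vapply(seq_len(L), function(j) {
    e <- numeric(L); e[j] <- 1
    signal::sgolayfilt(e, p = polyorder, n = window)
  }, numeric(L))
  S  # out = S %*% series  (column j = response to basis vector j)
}

#' Build a monthly cube from dated acquisitions
#'
#' The full per-pixel preparation chain: drop acquisitions at or above the
#' cloud threshold, median-composite each month, fill remaining gaps with
#' the nearest-valid-neighbour mean, then Savitzky-Golay smooth each
#' pixel/band series. Months with no usable acquisition become gaps and are
#' interpolated like any other. Pixels with fewer than two valid months are
#' flagged unusable (invalid in every month of the result) and are excluded
#' from sampling and mapping downstream. Smoothed values are clipped to
#' \[0, 1\].
#'
#' @param acqs List of [acquisition()] objects (any months, any order).
#' @param months Ordered month indices of the output cube (default 5:10).
#' @param max_cloud Cloud-fraction threshold for [filter_acquisitions()].
#' @param window,polyorder Savitzky-Golay parameters; smoothing is skipped
#'   (with a warning) when `length(months) < window`.
#' @param year Year tag of the output cube.
#' @return A [monthly_cube()]; the attribute `"observed"` records the
#'   pre-interpolation validity (which cells were actually observed).
#' @export
build_cube <- function(acqs, months = 5:10, max_cloud = 0.5,
                       window = 5L, polyorder = 2L, year = NA_integer_) {
  stopifnot(length(acqs) > 0)
  acqs <- filter_acquisitions(acqs, max_cloud)
  if (length(acqs) == 0L) stopf("no acquisitions below the cloud threshold")
  meta <- acqs[[1]]$meta
  bands <- dim(acqs[[1]]$values)[3]
  nm <- length(months)
  values <- array(NA_real_, c(meta$rows, meta$cols, bands, nm))
  observed <- array(FALSE, c(meta$rows, meta$cols, nm))
  for (mi in seq_len(nm)) {
    of_month <- acqs[vapply(acqs, function(a) isTRUE(a$month == months[mi]),
                            logical(1))]
    if (length(of_month) == 0L) next
    comp <- composite_month(of_month)
    if (dim(comp$values)[3] != bands)
      stopf("validation error: band-count mismatch in month %d", months[mi])
    values[, , , mi] <- comp$values
    observed[, , mi] <- comp$valid
  }
  npix <- meta$rows * meta$cols
  V <- matrix(observed, npix, nm)
  usable <- rowSums(V) >= 2L
  if (!any(usable)) stopf("no usable pixels (all have < 2 valid months)")
  smooth_ok <- nm >= window
  if (!smooth_ok)
    warnf("cube has %d months < window %d: smoothing skipped", nm, window)
  S <- if (smooth_ok) sg_operator(nm, window, polyorder) else diag(nm)
  for (b in seq_len(bands)) {
    X <- matrix(values[, , b, ], npix, nm)
    X[usable, ] <- fill_series_matrix(X[usable, , drop = FALSE],
                                      V[usable, , drop = FALSE])
    X[usable, ] <- pmin(pmax(X[usable, , drop = FALSE] %*% t(S), 0), 1)
    X[!usable, ] <- NA_real_
    values[, , b, ] <- array(X, c(meta$rows, meta$cols, nm))
  }
  valid <- array(usable, c(meta$rows, meta$cols, nm))
  out <- monthly_cube(values, valid, meta = meta, year = year, months = months)
  attr(out, "observed") <- observed
  out
}
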