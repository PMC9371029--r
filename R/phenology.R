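# Default per-class spectral phenology for the synthetic scene generator.

#' Default class phenology table
#'
#' Monthly mean reflectance for each of the 10 classes in four broad bands
#' (1 green, 2 red, 3 NIR, 4 SWIR), over the May--October growing season.
#' The crop curves are unimodal NIR peaks offset in time (corn peaking
#' early August, soybeans mid-August with later emergence, rice with a
#' flooded -- water-like -- signature in May and October around a summer
#' canopy peak). Land-cover classes are flat (water, developed) or broad
#' bumps (forest green-up from May, grassland early summer, shrubland
#' intermediate, "other" a late bare-to-vegetated transition). The curves
#' are designed so that classes are well separated over the full series but
#' overlap pairwise in single months (e.g. soybeans and forest are nearly
#' coincident in all four bands in August), which is what makes single-month
#' classification measurably harder than the full time series.
#'
#' @param months Month indices at which to evaluate the curves (default 5:10).
#' @param n_bands Number of bands, up to 4 (default 4).
#' @param classes Class codes (default 1:10).
#' @return Numeric array `(class, band, month)` with dimnames.
#' @export
default_phenology <- function(months = 5:10, n_bands = 4, classes = 1:10) {
  stopifnot(n_bands >= 1, n_bands <= 4)
  g <- function(m, peak, width) exp(-0.5 * ((m - peak) / width)^2)
  m <- as.numeric(months)
  # band order: green, red, nir, swir; one row per band
  curves <- list(
    `1` = { gg <- g(m, 8.0, 1.4)               # corn
      rbind(0.26 - 0.08 * gg, 0.30 - 0.20 * gg,
            0.22 + 0.44 * gg, 0.32 - 0.14 * gg) },
    `2` = { gg <- g(m, 8.4, 1.1)               # soybeans
      rbind(0.27 - 0.09 * gg, 0.31 - 0.21 * gg,
            0.20 + 0.42 * gg, 0.34 - 0.16 * gg) },
    `3` = {                                    # rice: flooded May/October
      interp <- function(v) stats::approx(5:10, v, xout = pmin(pmax(m, 5), 10))$y
      rbind(interp(c(0.09, 0.22, 0.18, 0.16, 0.20, 0.11)),
            interp(c(0.07, 0.22, 0.14, 0.12, 0.18, 0.09)),
            interp(c(0.08, 0.30, 0.52, 0.60, 0.38, 0.12)),
            interp(c(0.04, 0.18, 0.16, 0.15, 0.20, 0.06))) },
    `4` = rbind(rep(0.07, length(m)), rep(0.05, length(m)),  # water
                rep(0.04, length(m)), rep(0.02, length(m))),
    `5` = rbind(rep(0.28, length(m)), rep(0.30, length(m)),  # developed
                rep(0.32, length(m)), rep(0.36, length(m))),
    `6` = { gg <- g(m, 7.2, 2.6)               # forest
      rbind(0.22 - 0.06 * gg, 0.22 - 0.12 * gg,
            0.30 + 0.30 * gg, 0.24 - 0.08 * gg) },
    `7` = { gg <- g(m, 6.4, 1.7)               # grassland
      rbind(0.25 - 0.07 * gg, 0.26 - 0.14 * gg,
            0.26 + 0.26 * gg, 0.30 - 0.10 * gg) },
    `8` = {                                    # wetlands: moist soil + veg
      interp <- function(v) stats::approx(5:10, v, xout = pmin(pmax(m, 5), 10))$y
      rbind(interp(c(0.18, 0.17, 0.16, 0.15, 0.17, 0.18)),
            interp(c(0.18, 0.15, 0.13, 0.12, 0.15, 0.18)),
            interp(c(0.22, 0.34, 0.44, 0.48, 0.36, 0.24)),
            interp(c(0.10, 0.12, 0.13, 0.13, 0.12, 0.10))) },
    `9` = { gg <- g(m, 7.6, 2.2)               # shrubland
      rbind(0.23 - 0.06 * gg, 0.24 - 0.11 * gg,
            0.27 + 0.24 * gg, 0.27 - 0.09 * gg) },
    `10` = { gg <- g(m, 9.2, 1.3)              # other: late transition
      rbind(0.25 - 0.06 * gg, 0.28 - 0.12 * gg,
            0.24 + 0.22 * gg, 0.30 - 0.10 * gg) })
  phen <- array(NA_real_,
                dim = c(length(classes), n_bands, length(months)),
                dimnames = list(class = as.character(classes),
                                band = c("green", "red", "nir", "swir")[1:n_bands],
                                month = as.character(months)))
  for (k in seq_along(classes)) {
    key <- as.character(classes[k])
    if (!key %in% names(curves))
      stopf("no default phenology for class %s", key)
    phen[k, , ] <- curves[[key]][1:n_bands, , drop = FALSE]
  }
  phen
}
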