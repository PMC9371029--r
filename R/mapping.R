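# Per-pixel mapping and the dual-length rice/wetland correction.

#' Map a scene with a trained model
#'
#' Applies the model to every usable pixel of the cube (optionally on a
#' month subset matching the model's feature layout) and records both the
#' argmax class map and the full per-class probability planes. Pixels
#' without a full valid series are nodata.
#'
#' @param model A [train_model()] result.
#' @param cube A gap-filled [monthly_cube()].
#' @param months_subset Months to feed the model (default: all cube
#'   months); must multiply out to the model's feature width.
#' @param chunk Pixels per prediction block (memory knob).
#' @return An object of class `class_proba_maps` with fields `class_map`
#'   (a [label_raster()]), `proba` (rows x cols x classes array),
#'   `class_list`, `months`.
#' @export
map_scene <- function(model, cube, months_subset = NULL, chunk = 20000L) {
  stopifnot(inherits(model, "crop_model"), inherits(cube, "monthly_cube"))
  months_subset <- months_subset %||% cube$months
  width <- length(months_subset) * cube$bands
  if (width != model$n_features)
    stopf("months mismatch: %d month(s) x %d band(s) = %d features, model expects %d",
          length(months_subset), cube$bands, width, model$n_features)
  usable <- usable_pixels(cube)
  idx <- which(usable)
  rows <- ((idx - 1L) %% cube$meta$rows) + 1L
  cols <- ((idx - 1L) %/% cube$meta$rows) + 1L
  feats <- build_features(cube, months_subset,
                          points = data.frame(row = rows, col = cols))
  K <- length(model$class_list)
  proba <- array(NA_real_, c(cube$meta$rows, cube$meta$cols, K),
                 dimnames = list(NULL, NULL, as.character(model$class_list)))
  cls <- matrix(LABEL_NODATA, cube$meta$rows, cube$meta$cols)
  for (start in seq(1, length(idx), by = chunk)) {
    sel <- start:min(start + chunk - 1, length(idx))
    p <- predict_proba(model, feats[sel, , drop = FALSE])
    cls[idx[sel]] <- model$class_list[max.col(p, ties.method = "first")]
    for (k in seq_len(K)) {
      plane <- proba[, , k]
      plane[idx[sel]] <- p[, k]
      proba[, , k] <- plane
    }
  }
  structure(list(meta = cube$meta, year = cube$year,
                 months = as.integer(months_subset),
                 class_list = model$class_list,
                 class_map = label_raster(cls, cube$meta, cube$year,
                                          class_set = model$class_list),
                 proba = proba),
            class = "class_proba_maps")
}

#' @export
print.class_proba_maps <- function(x, ...) {
  cat(sprintf("<class_proba_maps> year %s, months %s, %d classes\n",
              ifelse(is.na(x$year), "?", x$year),
              paste(x$months, collapse = ","), length(x$class_list)))
  print(x$class_map)
  invisible(x)
}

map_classes <- function(x) {
  if (inherits(x, "class_proba_maps")) x$class_map else x
}

#' Dual-length time-series correction of rice
#'
#' Wetlands inundated early (or late) in the season mimic the flooded
#' spectral signature of rice, so a full-season classification can call
#' them rice even though the mid-season (June--September) window separates
#' the two. The correction merges the two classifications: wherever the
#' full-season map says rice but the short-window map does not, the pixel
#' takes the short-window class; every other pixel -- in particular every
#' non-rice pixel of the full map -- is left bit-identical. The operation
#' is idempotent and can only decrease the rice area.
#'
#' With `prob_margin` set (both inputs must then be [map_scene()] results),
#' replacement additionally requires that the short window's best non-rice
#' probability exceed its rice probability by at least the margin --
#' a conservative variant for borderline pixels.
#'
#' @param full Full-season map: a [map_scene()] result or [label_raster()].
#' @param short Short-window map on the same grid.
#' @param target_class Class being corrected (default 3, rice).
#' @param prob_margin Optional probability margin (default `NULL`: plain
#'   class-level merge).
#' @return A [label_raster()] with the corrected classes.
#' @export
correct_rice <- function(full, short, target_class = 3, prob_margin = NULL) {
  fmap <- map_classes(full)
  smap <- map_classes(short)
  check_same_grid(fmap, smap, "full and short maps")
  out <- fmap$values
  swap <- fmap$values == target_class & smap$values != target_class &
    smap$values != LABEL_NODATA
  if (!is.null(prob_margin)) {
    if (!inherits(short, "class_proba_maps"))
      stopf("prob_margin requires probability maps for 'short'")
    tc <- as.character(target_class)
    if (!tc %in% dimnames(short$proba)[[3]])
      stopf("target class %s not among the short map's classes", tc)
    p_rice <- short$proba[, , tc]
    p_best_other <- apply(short$proba[, , dimnames(short$proba)[[3]] != tc,
                                      drop = FALSE], c(1, 2), max)
    swap <- swap & (p_best_other - p_rice >= prob_margin)
  }
  out[swap] <- smap$values[swap]
  label_raster(out, fmap$meta, fmap$year,
               class_set = sort(unique(c(fmap$class_set, smap$class_set))))
}
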