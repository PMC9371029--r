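# Memoised heavyweight fixtures shared across test files: the filtering
# scenes are expensive (five MLP fits each), so each seed's experiment runs
# once per session.

.bundle_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .bundle_cache))
    assign(key, expr, envir = .bundle_cache)
  get(key, envir = .bundle_cache)
}

get_enrichment <- function(seed) {
  memo(sprintf("enr_%d", seed), enrichment_experiment(seed = seed))
}

get_downstream <- function(seed) {
  memo(sprintf("dwn_%d", seed), downstream_experiment(get_enrichment(seed)))
}

get_small_scene <- function() {
  memo("small_scene", {
    scene <- generate_scene(scene_config(
      grid_rows = 40, grid_cols = 40, n_years = 3, field_size_px = 10,
      label_noise_rate = 0, missing_rate = 0, seed = 42))
    cubes <- stats::setNames(
      lapply(scene$years, function(y)
        prepare_year_cube(scene, y, per_month = 1, cloud_rate = 0)),
      as.character(scene$years))
    list(scene = scene, cubes = cubes)
  })
}
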