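# Exhaustive hyperparameter grid search with stratified k-fold CV.

#' Default search grids per family
#'
#' The searchable values for each family: SVM `C` in \{0.01, 0.1, 1, 5, 10,
#' 50, 100, 500\}; tree criterion \{gini, entropy\}, `max_depth` \{10, 50,
#' 100, 200\}, `min_samples_leaf` \{10, 50, 100, 200\},
#' `min_impurity_split` \{0.001, 0.01, 0.1\}; forest `n_estimators` \{50,
#' 100, 200\} plus the tree settings; MLP `learning_rate` \{0.001, 0.01,
#' 0.1\}, optimizer \{SGD, Adam\}, activation \{relu, tanh\}, `layers`
#' \{5, 7, 8\}, `batch` \{1000, 4000, 8000\}.
#'
#' @param family Model family.
#' @return Named list of value vectors.
#' @export
default_grid <- function(family = c("svm", "dt", "rf", "mlp")) {
  family <- match.arg(family)
  switch(family,
    svm = list(C = c(0.01, 0.1, 1, 5, 10, 50, 100, 500)),
    dt = list(criterion = c("gini", "entropy"),
              max_depth = c(10, 50, 100, 200),
              min_samples_leaf = c(10, 50, 100, 200),
              min_impurity_split = c(0.001, 0.01, 0.1)),
    rf = list(n_estimators = c(50, 100, 200),
              max_depth = c(10, 50, 100, 200),
              min_samples_leaf = c(10, 50, 100, 200),
              min_impurity_split = c(0.001, 0.01, 0.1)),
    mlp = list(learning_rate = c(0.001, 0.01, 0.1),
               optimizer = c("SGD", "Adam"),
               activation = c("relu", "tanh"),
               layers = c(5, 7, 8),
               batch = c(1000, 4000, 8000)))
}

stratified_folds <- function(y, folds, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold
  })
}

#' Exhaustive grid search with stratified cross-validation
#'
#' Evaluates every combination of the supplied hyperparameter value lists
#' by k-fold stratified cross-validation, scoring with mean overall
#' accuracy across folds, and returns the winning [model_spec()]. Ties go
#' to the first grid point in enumeration order (the order of
#' `expand.grid` over the value lists), so results are deterministic.
#'
#' @param family Model family.
#' @param samples Sample table (or data.frame with `label` + `f_*`).
#' @param grid Named list of value vectors (default [default_grid()]).
#' @param folds Number of CV folds (default 5); must not exceed the
#'   smallest class count.
#' @param seed Seed controlling fold assignment and model fits.
#' @return List of class `grid_search_result` with `best_spec`, `best_score`
#'   and `scores` (one row per grid point, in enumeration order).
#' @export
grid_search <- function(family, samples, grid = default_grid(family),
                        folds = 5, seed = 1) {
  if (length(grid) == 0L) stopf("grid must be non-empty")
  y <- samples$label
  min_class <- min(table(y))
  if (folds > min_class)
    stopf("folds (%d) exceed smallest class count (%d)", folds, min_class)
  pts <- expand.grid(grid, stringsAsFactors = FALSE)
  fold <- stratified_folds(y, folds, seed)
  x <- sample_features(samples)
  scores <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    hp <- as.list(pts[i, , drop = FALSE])
    names(hp) <- names(pts)
    spec <- model_spec(family, hp, seed = seed)
    acc <- vapply(seq_len(folds), function(k) {
      tr <- fold != k
      m <- train_model(spec, x = x[tr, , drop = FALSE], y = y[tr])
      mean(predict(m, x[!tr, , drop = FALSE]) == y[!tr])
    }, numeric(1))
    scores[i] <- mean(acc)
  }
  best <- which.max(scores)  # first maximum wins ties
  out <- list(best_spec = model_spec(family, stats::setNames(
                as.list(pts[best, , drop = FALSE]), names(pts)), seed = seed),
              best_score = scores[best],
              scores = cbind(pts, mean_oa = scores))
  class(out) <- "grid_search_result"
  out
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("<grid_search_result> %d point(s), best mean OA %.4f\n",
              nrow(x$scores), x$best_score))
  print(x$best_spec)
  invisible(x)
}
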