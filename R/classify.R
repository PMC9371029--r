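# Classifier families: SVM, decision tree, random forest, and the
# fixed-topology multilayer perceptron. One train/predict surface for all.

MLP_WIDTHS <- c(16L, 16L, 32L, 32L, 64L, 32L, 32L, 10L)

HYPER_NAMES <- list(
  svm = "C",
  dt  = c("criterion", "max_depth", "min_samples_leaf", "min_impurity_split"),
  rf  = c("n_estimators", "max_depth", "min_samples_leaf",
          "min_impurity_split"),
  mlp = c("learning_rate", "optimizer", "activation", "layers", "batch",
          "dropout", "epochs", "patience"))

#' Model specification
#'
#' Family plus hyperparameters plus seed. Defaults per family are the
#' grid-search winners of the reference configuration: SVM `C = 500` (RBF
#' kernel); decision tree gini / `max_depth = 50` / `min_samples_leaf = 10`
#' / `min_impurity_split = 0.001`; random forest `n_estimators = 100` plus
#' the tree settings; MLP hidden widths 16, 16, 32, 32, 64, 32, 32 with a
#' 10-unit softmax output, batch normalization before each layer, dropout
#' 0.2 after each hidden layer, tanh activations, Adam at learning rate
#' 0.001, batch size 8000. Notes on backend mapping: the tree backend
#' (rpart) caps depth at 30, so larger `max_depth` values are clamped;
#' `min_impurity_split` maps to rpart's complexity/impurity-decrease
#' threshold `cp` for trees and is recorded but inert for the forest
#' backend (ranger), which has no equivalent stopping rule.
#'
#' @param family One of `"svm"`, `"dt"`, `"rf"`, `"mlp"`.
#' @param hyperparameters Named list; names restricted to the family's
#'   searchable set (plus, for the MLP, `dropout`, `epochs`, `patience`).
#' @param seed Integer seed used by [train_model()].
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("mlp", "svm", "dt", "rf"),
                       hyperparameters = list(), seed = 1) {
  family <- match.arg(family)
  bad <- setdiff(names(hyperparameters), HYPER_NAMES[[family]])
  if (length(bad))
    stopf("unknown hyperparameter(s) for %s: %s", family,
          paste(bad, collapse = ", "))
  defaults <- switch(family,
    svm = list(C = 500),
    dt  = list(criterion = "gini", max_depth = 50, min_samples_leaf = 10,
               min_impurity_split = 0.001),
    rf  = list(n_estimators = 100, max_depth = 100, min_samples_leaf = 10,
               min_impurity_split = 0.001),
    mlp = list(learning_rate = 0.001, optimizer = "Adam",
               activation = "tanh", layers = 8, batch = 8000,
               dropout = 0.2, epochs = 300, patience = 10))
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(list(family = family, hyperparameters = hp,
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  hp <- paste(names(x$hyperparameters),
              vapply(x$hyperparameters, format, character(1)),
              sep = "=", collapse = ", ")
  cat(sprintf("<model_spec> %s (%s), seed %d\n", x$family, hp, x$seed))
  invisible(x)
}

# Hidden-layer widths for an MLP with `layers` total layers: the last
# `layers` entries of the full width list, with the output width replaced
# by the number of classes.
mlp_widths <- function(layers, n_classes) {
  layers <- as.integer(layers)
  if (layers < 2 || layers > length(MLP_WIDTHS))
    stopf("mlp layers must be in 2..%d", length(MLP_WIDTHS))
  w <- MLP_WIDTHS[(length(MLP_WIDTHS) - layers + 1L):length(MLP_WIDTHS)]
  w[length(w)] <- n_classes
  w
}

#' Train a classifier on a sample table
#'
#' Fits the family named in `spec` to the samples' feature columns.
#' Features are standardized per column using training statistics only
#' (stored in the model and re-applied at prediction). Training is
#' deterministic given `spec$seed`. At least two classes must be present;
#' non-finite features are a validation error.
#'
#' For the MLP, when all labels lie in 1..10 the class list is padded to
#' the full 1..10 so the network keeps its 10-unit output; other families
#' predict over the classes present.
#'
#' @param spec A [model_spec()].
#' @param samples A sample table (from [draw_candidates()]), or any
#'   data.frame with a `label` column and `f_*` feature columns.
#' @param x,y Alternatively, a feature matrix and label vector.
#' @return An object of class `crop_model`.
#' @export
train_model <- function(spec, samples = NULL, x = NULL, y = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (!is.null(samples)) {
    x <- sample_features(samples)
    y <- samples$label
  }
  x <- as.matrix(x)
  if (any(!is.finite(x))) stopf("validation error: non-finite features")
  y <- as.integer(y)
  classes <- sort(unique(y))
  if (length(classes) < 2L)
    stopf("training requires >= 2 classes (got %d)", length(classes))
  if (spec$family == "mlp" && all(y %in% 1:10)) classes <- 1:10
  centre <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  xs <- sweep(sweep(x, 2, centre), 2, scale, "/")
  hp <- spec$hyperparameters
  fit <- with_seed(spec$seed, switch(spec$family,
    svm = e1071::svm(xs, factor(y, levels = classes), scale = FALSE,
                     cost = hp$C, probability = TRUE),
    dt = {
      df <- data.frame(.label = factor(y, levels = classes), xs)
      rpart::rpart(.label ~ ., df, method = "class",
                   parms = list(split = if (hp$criterion == "entropy")
                     "information" else "gini"),
                   control = rpart::rpart.control(
                     maxdepth = min(hp$max_depth, 30),
                     minbucket = hp$min_samples_leaf,
                     minsplit = hp$min_samples_leaf,
                     cp = hp$min_impurity_split, xval = 0))
    },
    rf = ranger::ranger(
      x = xs, y = factor(y, levels = classes), probability = TRUE,
      num.trees = hp$n_estimators, max.depth = hp$max_depth,
      min.node.size = hp$min_samples_leaf, seed = spec$seed,
      num.threads = 1),
    mlp = fit_mlp(xs, match(y, classes), n_classes = length(classes),
                  widths = mlp_widths(hp$layers, length(classes)),
                  activation = hp$activation, optimizer = hp$optimizer,
                  lr = hp$learning_rate, batch_size = hp$batch,
                  dropout = hp$dropout, epochs = hp$epochs,
                  patience = hp$patience, seed = spec$seed)))
  structure(list(spec = spec, class_list = classes, n_features = ncol(x),
                 feature_names = colnames(x), centre = centre, scale = scale,
                 fit = fit),
            class = "crop_model")
}

#' @export
print.crop_model <- function(x, ...) {
  cat(sprintf("<crop_model> %s, %d feature(s), classes %s\n",
              x$spec$family, x$n_features,
              paste(x$class_list, collapse = ",")))
  invisible(x)
}

#' Class-probability predictions
#'
#' Returns one probability row per input row over the model's class list;
#' rows sum to 1 (within 1e-6 before the defensive renormalization applied
#' here). [predict.crop_model()] with `type = "class"` takes the row-wise
#' argmax, breaking ties in favour of the lowest class code.
#'
#' @param model A [train_model()] result.
#' @param x Feature matrix with the training feature width.
#' @return Numeric matrix `nrow(x)` x `length(model$class_list)` with class
#'   codes as column names.
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "crop_model"))
  x <- as.matrix(x)
  if (ncol(x) != model$n_features)
    stopf("validation error: %d feature column(s), model expects %d",
          ncol(x), model$n_features)
  xs <- sweep(sweep(x, 2, model$centre), 2, model$scale, "/")
  # backends that match by name need the training column names
  if (!is.null(model$feature_names)) colnames(xs) <- model$feature_names
  K <- length(model$class_list)
  p <- switch(model$spec$family,
    svm = {
      pr <- stats::predict(model$fit, xs, probability = TRUE)
      pm <- attr(pr, "probabilities")
      pm[, match(as.character(model$class_list), colnames(pm)), drop = FALSE]
    },
    dt = {
      pm <- stats::predict(model$fit, data.frame(xs), type = "prob")
      pm[, match(as.character(model$class_list), colnames(pm)), drop = FALSE]
    },
    rf = {
      pm <- stats::predict(model$fit, data = xs, num.threads = 1)$predictions
      pm[, match(as.character(model$class_list), colnames(pm)), drop = FALSE]
    },
    mlp = predict_mlp(model$fit, xs),
    fixed = {
      # internal deterministic stub used in tests of voting/argmax logic
      if (!is.null(model$fit$proba)) {
        model$fit$proba(xs)
      } else {
        pm <- matrix(0, nrow(xs), K)
        pm[cbind(seq_len(nrow(xs)),
                 model$fit$predict(xs, model$class_list))] <- 1
        pm
      }
    })
  p <- matrix(p, nrow(xs), K)
  p <- p / pmax(rowSums(p), .Machine$double.eps)
  colnames(p) <- as.character(model$class_list)
  p
}

#' Predict classes or probabilities
#'
#' @param object A `crop_model`.
#' @param newdata Feature matrix (or sample table).
#' @param type `"class"` (default) for argmax class codes, `"prob"` for the
#'   probability matrix.
#' @param ... Unused.
#' @return Integer class codes or a probability matrix.
#' @export
predict.crop_model <- function(object, newdata, type = c("class", "prob"),
                               ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata) && any(grepl("^f_", names(newdata))))
    newdata <- sample_features(newdata)
  p <- predict_proba(object, newdata)
  if (type == "prob") return(p)
  # ties resolve to the first (lowest) class code: max.col "first"
  object$class_list[max.col(p, ties.method = "first")]
}
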