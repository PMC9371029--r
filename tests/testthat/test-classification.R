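test_that("every family separates two well-separated blobs", {
  d <- blob_data(n_per = 60, sep = 6, seed = 41)
  specs <- list(
    model_spec("svm", seed = 2),
    model_spec("dt", seed = 2),
    model_spec("rf", seed = 2),
    model_spec("mlp", list(batch = 32, epochs = 200, dropout = 0), seed = 2))
  for (spec in specs) {
    m <- train_model(spec, x = d$x, y = d$y)
    acc <- mean(predict(m, d$x) == d$y)
    expect_gte(acc, 0.99)
    # probability rows sum to 1
    p <- predict_proba(m, d$x[1:10, ])
    expect_equal(rowSums(p), rep(1, 10), tolerance = 1e-6)
    # determinism: same spec + data => identical predictions
    m2 <- train_model(spec, x = d$x, y = d$y)
    expect_identical(predict(m, d$x), predict(m2, d$x))
  }
})

test_that("degenerate training inputs are rejected", {
  d <- blob_data(seed = 42)
  expect_error(train_model(model_spec("rf"), x = d$x, y = rep(1, nrow(d$x))),
               ">= 2 classes")
  xbad <- d$x; xbad[3, 2] <- NaN
  expect_error(train_model(model_spec("rf"), x = xbad, y = d$y),
               "non-finite")
  m <- train_model(model_spec("dt"), x = d$x, y = d$y)
  expect_error(predict_proba(m, d$x[, 1:2]), "feature")
  expect_error(model_spec("svm", list(gamma = 1)), "unknown hyperparameter")
})

test_that("argmax prediction breaks ties toward the lowest class code", {
  # probability row [0.1, 0.7, 0.2] -> middle class
  m <- fixed_model(c(2L, 5L, 9L), 1,
                   proba_fun = function(xs)
                     matrix(c(0.1, 0.7, 0.2), nrow(xs), 3, byrow = TRUE))
  expect_equal(predict(m, matrix(0, 3, 1)), rep(5L, 3))
  # exact tie -> first (lowest) code
  tie <- fixed_model(c(3L, 8L), 1,
                     proba_fun = function(xs)
                       matrix(0.5, nrow(xs), 2))
  expect_equal(predict(tie, matrix(0, 4, 1)), rep(3L, 4))
})

test_that("the MLP's analytic gradients match finite differences", {
  set.seed(55)
  X <- matrix(rnorm(8 * 5), 8, 5)
  y <- sample(1:3, 8, replace = TRUE)
  act <- cropsift:::act_fun("tanh")
  layers <- cropsift:::mlp_init(5, c(6, 4, 3), seed = 9)
  loss_of <- function(layers) {
    fw <- cropsift:::mlp_forward(layers, X, act, train = TRUE)
    cropsift:::mlp_loss(fw$probs, y)
  }
  fw <- cropsift:::mlp_forward(layers, X, act, train = TRUE)
  grads <- cropsift:::mlp_backward(layers, fw, y, act)
  eps <- 1e-6
  for (l in seq_along(layers)) for (nm in c("W", "b", "gamma", "beta")) {
    p <- layers[[l]][[nm]]
    for (idx in sample(length(p), min(4, length(p)))) {
      up <- layers; up[[l]][[nm]][idx] <- up[[l]][[nm]][idx] + eps
      dn <- layers; dn[[l]][[nm]][idx] <- dn[[l]][[nm]][idx] - eps
      num <- (loss_of(up) - loss_of(dn)) / (2 * eps)
      expect_equal(grads[[l]][[nm]][idx], num, tolerance = 1e-4)
    }
  }
})

test_that("the padded MLP class list keeps the 10-unit output head", {
  d <- blob_data(n_per = 40, sep = 8, seed = 43, labels = c(2L, 7L))
  m <- train_model(model_spec("mlp", list(batch = 32, epochs = 150,
                                          dropout = 0), seed = 1),
                   x = d$x, y = d$y)
  expect_equal(m$class_list, 1:10)
  p <- predict_proba(m, d$x[1:5, ])
  expect_equal(ncol(p), 10)
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
  expect_gte(mean(predict(m, d$x) == d$y), 0.99)
  # labels outside 1..10: class list stays as-present
  m2 <- train_model(model_spec("mlp", list(batch = 32, epochs = 50,
                                           dropout = 0), seed = 1),
                    x = d$x, y = ifelse(d$y == 2, 11L, 7L))
  expect_equal(m2$class_list, c(7L, 11L))
})

test_that("grid search is exhaustive, deterministic and picks the separator", {
  d <- blob_data(n_per = 40, sep = 6, seed = 44)
  df <- data.frame(label = d$y, d$x)
  names(df)[-1] <- colnames(d$x)

  one <- grid_search("rf", df, grid = list(n_estimators = 50), folds = 5,
                     seed = 3)
  expect_equal(nrow(one$scores), 1)
  expect_equal(one$best_spec$hyperparameters$n_estimators, 50)

  # exhaustiveness: one row per grid point, winner's score is the maximum
  gs <- grid_search("dt", df,
                    grid = list(criterion = c("gini", "entropy"),
                                max_depth = c(5, 10),
                                min_samples_leaf = c(5, 80)),
                    folds = 5, seed = 3)
  expect_equal(nrow(gs$scores), 8)
  expect_true(all(gs$best_score >= gs$scores$mean_oa))

  # a leaf size forcing a root-only (majority) tree cannot beat one that
  # lets the tree split
  expect_lt(gs$best_spec$hyperparameters$min_samples_leaf, 80)

  expect_error(grid_search("dt", df, grid = list(max_depth = 5), folds = 50),
               "smallest class")
})
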