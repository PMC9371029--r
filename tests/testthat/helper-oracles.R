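# Independent brute-force oracles, deliberately written with plain loops so
# they share no code path with the implementations they check.

oracle_stats <- function(counts) {
  r <- nrow(counts)
  N <- 0
  for (i in 1:r) for (j in 1:r) N <- N + counts[i, j]
  diag_sum <- 0
  for (i in 1:r) diag_sum <- diag_sum + counts[i, i]
  rowtot <- numeric(r); coltot <- numeric(r)
  for (i in 1:r) for (j in 1:r) {
    rowtot[i] <- rowtot[i] + counts[i, j]
    coltot[j] <- coltot[j] + counts[i, j]
  }
  chance <- 0
  for (i in 1:r) chance <- chance + rowtot[i] * coltot[i]
  kappa <- (N * diag_sum - chance) / (N^2 - chance)
  pa <- rep(NA_real_, r); ua <- rep(NA_real_, r)
  for (i in 1:r) {
    if (rowtot[i] > 0) pa[i] <- counts[i, i] / rowtot[i]
    if (coltot[i] > 0) ua[i] <- counts[i, i] / coltot[i]
  }
  list(kappa = kappa, oa = diag_sum / N, pa = pa, ua = ua)
}

rand_confusion_counts <- function(r, max_count = 1e4) {
  matrix(sample(0:max_count, r * r, replace = TRUE), r, r)
}

counts_to_vectors <- function(counts, classes = seq_len(nrow(counts))) {
  truth <- integer(0); pred <- integer(0)
  for (i in seq_len(nrow(counts))) for (j in seq_len(ncol(counts))) {
    k <- counts[i, j]
    truth <- c(truth, rep(classes[i], k))
    pred <- c(pred, rep(classes[j], k))
  }
  list(truth = truth, pred = pred)
}

oracle_homogeneous <- function(values, window) {
  h <- (window - 1) %/% 2
  nr <- nrow(values); nc <- ncol(values)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (i - h < 1 || i + h > nr || j - h < 1 || j + h > nc) next
    nb <- values[(i - h):(i + h), (j - h):(j + h)]
    out[i, j] <- all(nb == values[i, j]) && all(nb != 0)
  }
  out
}

# Per-point least-squares polynomial fit, with the standard edge handling:
# the first/last half-windows are evaluated from the polynomial fitted to
# the first/last full window.
oracle_sgolay <- function(x, window, polyorder) {
  L <- length(x)
  h <- (window - 1) %/% 2
  out <- numeric(L)
  for (i in seq_len(L)) {
    if (i <= h) win <- 1:window
    else if (i > L - h) win <- (L - window + 1):L
    else win <- (i - h):(i + h)
    fit <- stats::lm.fit(outer(win, 0:polyorder, `^`), x[win])
    out[i] <- sum(fit$coefficients * i^(0:polyorder))
  }
  out
}

# Acquisition with an exact cloud fraction on an r x c grid.
make_acq <- function(cloud_fraction, rows = 4, cols = 5, bands = 2,
                     month = 6, year = 2019, ordinal = 1, seed = 1) {
  set.seed(seed)
  vals <- array(runif(rows * cols * bands), c(rows, cols, bands))
  n_cloud <- round(cloud_fraction * rows * cols)
  valid <- matrix(TRUE, rows, cols)
  if (n_cloud > 0) valid[sample(rows * cols, n_cloud)] <- FALSE
  vmask <- array(valid, dim(vals))
  vals[!vmask] <- NA_real_
  acquisition(vals, valid, year = year, month = month, ordinal = ordinal)
}

# A crop_model stub with fully controlled predictions (internal family
# "fixed"): `predict_fun(xs, class_list)` returns indices into class_list,
# or `proba_fun(xs)` returns a probability matrix.
fixed_model <- function(class_list, n_features, predict_fun = NULL,
                        proba_fun = NULL) {
  structure(list(spec = list(family = "fixed"), class_list = class_list,
                 n_features = n_features, feature_names = NULL,
                 centre = rep(0, n_features), scale = rep(1, n_features),
                 fit = list(predict = predict_fun, proba = proba_fun)),
            class = "crop_model")
}

# Two well-separated Gaussian blobs for classifier smoke tests.
blob_data <- function(n_per = 60, d = 4, sep = 6, seed = 1,
                      labels = c(1L, 2L)) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * d), n_per, d),
             matrix(rnorm(n_per * d, mean = sep), n_per, d))
  colnames(x) <- sprintf("f_%d", seq_len(d) - 1L)
  list(x = x, y = rep(labels, each = n_per))
}
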