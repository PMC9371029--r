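# Multilayer perceptron with batch normalization before every layer,
# dropout after every hidden activation, tanh/relu activations, and
# Adam/SGD optimization -- the deep base learner used for sample filtering
# and mapping. Pure-R analytic backpropagation (gradient-checked in the
# test suite); at the feature widths involved (tens of inputs, hidden
# widths <= 64) dense matrix products in R are more than fast enough.

BN_EPS <- 1e-5

act_fun <- function(name) {
  switch(name,
    tanh = list(f = tanh, grad = function(s, h) 1 - h^2),
    relu = list(f = function(s) pmax(s, 0),
                grad = function(s, h) (s > 0) * 1),
    stopf("unknown activation '%s'", name))
}

mlp_init <- function(D, widths, seed) {
  with_seed(seed, {
    L <- length(widths)
    layers <- vector("list", L)
    d_in <- D
    for (l in seq_len(L)) {
      d_out <- widths[l]
      sd <- sqrt(2 / (d_in + d_out))  # Xavier/Glorot, suits tanh
      layers[[l]] <- list(
        W = matrix(stats::rnorm(d_in * d_out, 0, sd), d_in, d_out),
        b = numeric(d_out),
        gamma = rep(1, d_in), beta = numeric(d_in),
        run_mean = numeric(d_in), run_var = rep(1, d_in))
      d_in <- d_out
    }
    layers
  })
}

# One forward pass. train = TRUE uses batch statistics (and the supplied
# dropout masks); train = FALSE uses running statistics and no dropout.
mlp_forward <- function(layers, X, act, train = FALSE, masks = NULL,
                        dropout = 0) {
  L <- length(layers)
  n <- nrow(X)
  cache <- vector("list", L)
  a <- X
  for (l in seq_len(L)) {
    ly <- layers[[l]]
    if (train) {
      mu <- colMeans(a)
      v <- colMeans(a^2) - mu^2
      v[v < 0] <- 0
    } else {
      mu <- ly$run_mean
      v <- ly$run_var
    }
    inv <- 1 / sqrt(v + BN_EPS)
    xhat <- sweep(sweep(a, 2, mu), 2, inv, "*")
    u <- sweep(sweep(xhat, 2, ly$gamma, "*"), 2, ly$beta, "+")
    s <- u %*% ly$W + matrix(ly$b, n, length(ly$b), byrow = TRUE)
    if (l < L) {
      h <- act$f(s)
      a_next <- h
      if (train && dropout > 0 && !is.null(masks)) {
        a_next <- h * masks[[l]] / (1 - dropout)
      }
    } else {
      sm <- s - apply(s, 1, max)
      es <- exp(sm)
      a_next <- es / rowSums(es)
      h <- NULL
    }
    cache[[l]] <- list(a_in = a, xhat = xhat, inv = inv, u = u, s = s, h = h,
                       mu = mu, v = v)
    a <- a_next
  }
  list(probs = a, cache = cache)
}

mlp_loss <- function(probs, y_idx) {
  -mean(log(pmax(probs[cbind(seq_along(y_idx), y_idx)], 1e-12)))
}

# Analytic gradients for one batch (batch-statistics mode).
mlp_backward <- function(layers, fw, y_idx, act, masks = NULL, dropout = 0) {
  L <- length(layers)
  n <- length(y_idx)
  grads <- vector("list", L)
  P <- fw$probs
  dS <- P / n
  dS[cbind(seq_len(n), y_idx)] <- dS[cbind(seq_len(n), y_idx)] - 1 / n
  for (l in rev(seq_len(L))) {
    cc <- fw$cache[[l]]
    ly <- layers[[l]]
    dW <- crossprod(cc$u, dS)
    db <- colSums(dS)
    dU <- tcrossprod(dS, ly$W)
    dgamma <- colSums(dU * cc$xhat)
    dbeta <- colSums(dU)
    dxhat <- sweep(dU, 2, ly$gamma, "*")
    mean_dx <- colMeans(dxhat)
    mean_dxx <- colMeans(dxhat * cc$xhat)
    dA <- sweep(dxhat - matrix(mean_dx, n, length(mean_dx), byrow = TRUE) -
                  cc$xhat * matrix(mean_dxx, n, length(mean_dxx), byrow = TRUE),
                2, cc$inv, "*")
    grads[[l]] <- list(W = dW, b = db, gamma = dgamma, beta = dbeta)
    if (l > 1) {
      prev <- fw$cache[[l - 1]]
      dH <- dA
      if (dropout > 0 && !is.null(masks))
        dH <- dH * masks[[l - 1]] / (1 - dropout)
      dS <- dH * act$grad(prev$s, prev$h)
    }
  }
  grads
}

adam_state <- function(layers) {
  lapply(layers, function(ly)
    lapply(ly[c("W", "b", "gamma", "beta")], function(p) {
      z <- p; z[] <- 0; list(m = z, v = z)
    }))
}

apply_update <- function(layers, grads, state, lr, optimizer, t) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (l in seq_along(layers)) {
    for (nm in c("W", "b", "gamma", "beta")) {
      g <- grads[[l]][[nm]]
      if (optimizer == "Adam") {
        st <- state[[l]][[nm]]
        st$m <- b1 * st$m + (1 - b1) * g
        st$v <- b2 * st$v + (1 - b2) * g^2
        mhat <- st$m / (1 - b1^t)
        vhat <- st$v / (1 - b2^t)
        layers[[l]][[nm]] <- layers[[l]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
        state[[l]][[nm]] <- st
      } else {
        layers[[l]][[nm]] <- layers[[l]][[nm]] - lr * g
      }
    }
  }
  list(layers = layers, state = state)
}

# Fit the network. X must already be standardized; y_idx in 1..n_classes.
fit_mlp <- function(X, y_idx, n_classes, widths, activation = "tanh",
                    optimizer = "Adam", lr = 0.001, batch_size = 8000,
                    dropout = 0.2, epochs = 300, patience = 10,
                    val_fraction = 0.1, seed = 1) {
  stopifnot(widths[length(widths)] == n_classes)
  act <- act_fun(tolower(activation))
  n <- nrow(X)
  layers <- mlp_init(ncol(X), widths, seed)
  state <- adam_state(layers)
  with_seed(seed + 1L, {
    # held-out split for early stopping; keep every class in training
    val_idx <- integer(0)
    if (val_fraction > 0 && n >= 50) {
      cand <- sample(n, floor(val_fraction * n))
      keep <- tabulate(y_idx[-cand], n_classes)
      present <- tabulate(y_idx, n_classes) > 0
      if (all(keep[present] > 0)) val_idx <- cand
    }
    tr_idx <- setdiff(seq_len(n), val_idx)
    Xt <- X[tr_idx, , drop = FALSE]; yt <- y_idx[tr_idx]
    Xv <- X[val_idx, , drop = FALSE]; yv <- y_idx[val_idx]
    bs <- min(batch_size, length(tr_idx))
    best <- list(loss = Inf, layers = layers, epoch = 0L)
    bad <- 0L
    t <- 0
    for (ep in seq_len(epochs)) {
      ord <- sample(length(tr_idx))
      for (start in seq(1, length(tr_idx), by = bs)) {
        bi <- ord[start:min(start + bs - 1, length(tr_idx))]
        if (length(bi) < 2) next  # batch stats need >= 2 rows
        Xb <- Xt[bi, , drop = FALSE]
        masks <- NULL
        if (dropout > 0)
          masks <- lapply(widths[-length(widths)], function(w)
            matrix(stats::runif(length(bi) * w) > dropout, length(bi), w))
        fw <- mlp_forward(layers, Xb, act, train = TRUE, masks = masks,
                          dropout = dropout)
        # running statistics for inference (momentum 0.9)
        for (l in seq_along(layers)) {
          layers[[l]]$run_mean <- 0.9 * layers[[l]]$run_mean +
            0.1 * fw$cache[[l]]$mu
          layers[[l]]$run_var <- 0.9 * layers[[l]]$run_var +
            0.1 * fw$cache[[l]]$v
        }
        gr <- mlp_backward(layers, fw, yt[bi], act, masks, dropout)
        t <- t + 1
        upd <- apply_update(layers, gr, state, lr, optimizer, t)
        layers <- upd$layers; state <- upd$state
      }
      if (length(val_idx)) {
        pv <- mlp_forward(layers, Xv, act, train = FALSE)$probs
        vl <- mlp_loss(pv, yv)
        if (vl < best$loss - 1e-6) {
          best <- list(loss = vl, layers = layers, epoch = ep)
          bad <- 0L
        } else {
          bad <- bad + 1L
          if (bad >= patience) break
        }
      }
    }
    if (length(val_idx) && is.finite(best$loss)) layers <- best$layers
  })
  list(layers = layers, activation = tolower(activation), widths = widths,
       n_classes = n_classes)
}

predict_mlp <- function(fit, X) {
  act <- act_fun(fit$activation)
  mlp_forward(fit$layers, as.matrix(X), act, train = FALSE)$probs
}
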