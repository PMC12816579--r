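# Independent oracles used to cross-check the package implementations.

# Brute-force Meinshausen weighted-CDF quantiles, computed point by point
# directly from the definition (no shared code with the Rcpp kernel).
oracle_forest_quantiles <- function(model, X, levels) {
  tl <- model$train_leaf
  ib <- model$inbag
  y <- model$y
  ql <- uamtox:::.query_leaves(model, X)
  n_tree <- ncol(tl)
  n <- length(y)
  m <- nrow(ql)
  Q <- matrix(NA_real_, m, length(levels))
  for (i in seq_len(m)) {
    w <- numeric(n)
    for (t in seq_len(n_tree)) {
      same <- tl[, t] == ql[i, t]
      ls <- sum(ib[same, t])
      if (ls > 0) w[same] <- w[same] + ib[same, t] / (ls * n_tree)
    }
    ord <- order(y)
    cw <- cumsum(w[ord])
    for (l in seq_along(levels)) {
      Q[i, l] <- y[ord][which(cw >= levels[l] * sum(w) - 1e-9)[1]]
    }
  }
  Q
}

# Brute-force per-tree quantiles from each tree's own leaf values.
oracle_tree_quantiles <- function(model, X, level) {
  tl <- model$train_leaf
  ib <- model$inbag
  y <- model$y
  ql <- uamtox:::.query_leaves(model, X)
  n_tree <- ncol(tl)
  out <- matrix(NA_real_, nrow(ql), n_tree)
  for (i in seq_len(nrow(ql))) {
    for (t in seq_len(n_tree)) {
      same <- tl[, t] == ql[i, t] & ib[, t] > 0
      vals <- rep(y[same], times = ib[same, t])
      vals <- sort(vals)
      cw <- seq_along(vals) / length(vals)
      out[i, t] <- vals[which(cw >= level - 1e-9)[1]]
    }
  }
  out
}

# Naive re-implementation of the regression metrics.
oracle_metrics <- function(y, y_hat) {
  e <- y - y_hat
  list(mae = sum(abs(e)) / length(e),
       mdae = median(abs(e)),
       rmse = sqrt(sum(e^2) / length(e)),
       r2 = 1 - sum(e^2) / sum((y - mean(y))^2))
}

# Small deterministic regression problem for forest tests.
make_step_data <- function(n = 200, seed = 1) {
  set.seed(seed)
  x <- matrix(runif(n, -2, 2), ncol = 1)
  colnames(x) <- "x"
  list(x = x, y = as.numeric(x[, 1] >= 0))
}
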