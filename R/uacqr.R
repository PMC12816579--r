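# Uncertainty-aware conformalized quantile regression (UACQR) with a
# quantile-regression-forest core.
#
# The forest is grown with ranger; leaves retain the raw training targets
# of their bootstrap (inbag) members. Conditional quantiles follow
# Meinshausen's weighted empirical CDF, with the left-continuous inverse
# inf{y : F(y) >= q} used everywhere (trees and ensemble). The conformal
# layer rescales nonconformity scores by the per-query standard deviation
# of per-tree median predictions -- the ensemble's epistemic spread -- so
# intervals widen where the forest disagrees with itself, while retaining
# the finite-sample marginal coverage guarantee of split conformal
# prediction. Setting the spread to 1 recovers plain conformalized
# quantile regression (CQR).

.as_plain_matrix <- function(X) {
  if (inherits(X, "feature_matrix")) X <- .fm_values(X)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  X
}

#' Fit a quantile regression forest
#'
#' Grows a random forest on bootstrap samples whose leaves retain raw
#' training target values, enabling conditional-quantile estimation.
#' Fitting is deterministic given `seed`.
#'
#' @param X Feature matrix (rows = chemicals) or [feature_matrix()].
#' @param y Numeric targets, internally log10(mol/kg-d).
#' @param n_trees Number of trees (default 500).
#' @param leaf_min Minimal terminal-node size (default 5).
#' @param mtry Features tried per split (default: ranger's default,
#'   floor(sqrt(p))).
#' @param seed Integer RNG seed.
#' @return An object of class `quantile_forest`.
#' @export
fit_quantile_forest <- function(X, y, n_trees = 500, leaf_min = 5,
                                mtry = NULL, seed = 1) {
  X <- .as_plain_matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X rows and y length differ")
  if (length(y) < 2L) stop("need at least 2 training points")
  if (length(y) < leaf_min) stop("fewer training points than leaf_min")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  df <- data.frame(..y = y, X, check.names = FALSE)
  rf <- ranger::ranger(
    dependent.variable.name = "..y", data = df,
    num.trees = n_trees, min.node.size = leaf_min,
    mtry = if (is.null(mtry)) NULL else mtry,
    keep.inbag = TRUE, seed = seed, num.threads = 1
  )
  train_leaf <- predict(rf, df, type = "terminalNodes",
                        num.threads = 1)$predictions
  inbag <- matrix(as.integer(unlist(rf$inbag.counts)), nrow = length(y))
  structure(list(
    rf = rf, y = y, train_leaf = train_leaf, inbag = inbag,
    feature_names = colnames(X),
    config = list(n_trees = n_trees, leaf_min = leaf_min, mtry = mtry,
                  rng_seed = seed)
  ), class = "quantile_forest")
}

#' @export
print.quantile_forest <- function(x, ...) {
  cat(sprintf("<quantile_forest> %d trees, leaf_min=%d, n_train=%d, seed=%d\n",
              x$config$n_trees, x$config$leaf_min, length(x$y),
              x$config$rng_seed))
  invisible(x)
}

.query_leaves <- function(model, X) {
  X <- .as_plain_matrix(X)
  if (!all(model$feature_names %in% colnames(X))) {
    if (ncol(X) == length(model$feature_names) && is.null(colnames(X))) {
      colnames(X) <- model$feature_names
    } else {
      stop("query features do not match the training features")
    }
  }
  X <- X[, model$feature_names, drop = FALSE]
  predict(model$rf, data.frame(X, check.names = FALSE),
          type = "terminalNodes", num.threads = 1)$predictions
}

#' Conditional quantiles from a quantile regression forest
#'
#' Ensemble quantiles use Meinshausen's weighted empirical CDF: training
#' point i receives the average over trees of
#' (inbag count in the query's leaf) / (leaf size), and the level-q
#' estimate is the left-continuous inverse inf\{y : F(y) >= q\}. With
#' `per_tree = TRUE` the same rule is applied within each tree's own leaf,
#' yielding per-tree quantile estimates (the ensemble spread used by the
#' conformal layer).
#'
#' @param model A [fit_quantile_forest()] model.
#' @param X Query feature matrix.
#' @param levels Quantile levels, all strictly inside (0, 1).
#' @param per_tree Also return per-tree quantiles (array n x trees x levels).
#' @return List with `quantiles` (n x length(levels) matrix, nondecreasing
#'   across levels) and, when requested, `per_tree`.
#' @export
forest_quantiles <- function(model, X, levels = c(0.025, 0.5, 0.975),
                             per_tree = FALSE) {
  stopifnot(inherits(model, "quantile_forest"))
  levels <- as.numeric(levels)
  if (length(levels) == 0L) stop("levels must be nonempty")
  if (any(levels <= 0 | levels >= 1)) stop("levels must lie in (0, 1)")
  test_leaf <- .query_leaves(model, X)
  out <- qrf_quantiles_cpp(model$train_leaf, test_leaf, model$inbag,
                           model$y, levels, per_tree)
  colnames(out$quantiles) <- sprintf("q%g", levels)
  out
}

# Epistemic spread: SD across trees of the per-tree median prediction,
# floored to avoid division by zero on unanimous forests.
.tree_spread <- function(model, X, eps) {
  fq <- forest_quantiles(model, X, levels = 0.5, per_tree = TRUE)
  tm <- fq$per_tree
  dim(tm) <- dim(tm)[1:2]
  pmax(apply(tm, 1, sd), eps)
}

# Conformal rank: k-th smallest calibration score, k = ceil(level*(n+1)),
# capped at n.
.conformal_chat <- function(scores, level) {
  n <- length(scores)
  k <- min(ceiling(level * (n + 1)), n)
  sort(scores)[k]
}

.uacqr_scores <- function(model, X_cal, y_cal, level, s_cal) {
  a <- (1 - level) / 2
  fq <- forest_quantiles(model, X_cal, levels = c(a, 1 - a))
  q_lo <- fq$quantiles[, 1]
  q_hi <- fq$quantiles[, 2]
  pmax((q_lo - y_cal) / s_cal, (y_cal - q_hi) / s_cal)
}

#' Conformal calibration of a quantile regression forest
#'
#' Computes nonconformity scores on a calibration set that must be disjoint
#' from the training set. For each calibration point the score is the
#' exceedance of the target beyond the forest's central interval, scaled by
#' the epistemic spread s(x) (SD of per-tree median predictions, floored at
#' `eps`); the conformal quantile `c_hat` is the k-th smallest score with
#' k = ceil(level * (n_cal + 1)), capped at n_cal. `variant = "cqr"` fixes
#' s(x) = 1, i.e. plain conformalized quantile regression.
#'
#' @param model A [fit_quantile_forest()] model.
#' @param X_cal,y_cal Calibration features and targets.
#' @param level Nominal coverage level (default 0.95).
#' @param variant `"uacqr"` (spread-scaled scores, default) or `"cqr"`.
#' @param eps Floor for the epistemic spread (default 1e-6).
#' @return An object of class `conformal_adjustment`.
#' @export
conformal_calibrate <- function(model, X_cal, y_cal, level = 0.95,
                                variant = c("uacqr", "cqr"), eps = 1e-6) {
  variant <- match.arg(variant)
  stopifnot(inherits(model, "quantile_forest"))
  y_cal <- as.numeric(y_cal)
  if (length(y_cal) < 1L) stop("calibration set is empty")
  X_cal <- .as_plain_matrix(X_cal)
  if (nrow(X_cal) != length(y_cal)) stop("X_cal rows and y_cal length differ")
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  s_cal <- if (variant == "uacqr") .tree_spread(model, X_cal, eps)
           else rep(1, length(y_cal))
  scores <- .uacqr_scores(model, X_cal, y_cal, level, s_cal)
  structure(list(
    level = level, c_hat = .conformal_chat(scores, level), scores = scores,
    n_cal = length(y_cal), variant = variant, eps = eps,
    s_cal = s_cal, X_cal = X_cal, y_cal = y_cal
  ), class = "conformal_adjustment")
}

#' @export
print.conformal_adjustment <- function(x, ...) {
  cat(sprintf("<conformal_adjustment> %s, level=%.2f, n_cal=%d, c_hat=%.4g\n",
              x$variant, x$level, x$n_cal, x$c_hat))
  invisible(x)
}

#' Gaussian-equivalent sigma of an interval width
#'
#' Converts a central interval width at a given confidence level into the
#' standard deviation of the Gaussian with the same central interval:
#' `width / (2 * z_(1-(1-level)/2))` (width/3.92 at 95%).
#'
#' @param width Interval width (upper - lower).
#' @param level Confidence level.
#' @return Gaussian-equivalent SD.
#' @export
interval_sigma <- function(width, level = 0.95) {
  width / (2 * qnorm(1 - (1 - level) / 2))
}

#' Conformalized prediction intervals
#'
#' Produces per-chemical medians and calibrated intervals:
#' lower = q_lo(x) - c_hat * s(x), upper = q_hi(x) + c_hat * s(x), with the
#' ensemble median as point estimate (clipped so lower <= median <= upper).
#' When `levels` requests other confidence levels, the conformal quantile
#' is recomputed per level from the stored calibration set.
#'
#' @param model A [fit_quantile_forest()] model.
#' @param adj A [conformal_calibrate()] adjustment.
#' @param X Query feature matrix.
#' @param levels Confidence levels (default: the calibration level).
#' @return A data.frame with columns `chem_id`, `median`, `lower`, `upper`,
#'   `level`, `width` and Gaussian-equivalent `sigma`, one row per query
#'   per level. Units follow the training targets (log10 mol/kg-d).
#' @export
predict_intervals <- function(model, adj, X, levels = NULL) {
  stopifnot(inherits(model, "quantile_forest"))
  if (!inherits(adj, "conformal_adjustment")) {
    stop("adj must be a fitted conformal_adjustment")
  }
  if (is.null(levels)) levels <- adj$level
  if (any(levels <= 0 | levels >= 1)) stop("levels must lie in (0, 1)")
  Xm <- .as_plain_matrix(X)
  ids <- if (!is.null(rownames(Xm))) rownames(Xm)
         else sprintf("x%d", seq_len(nrow(Xm)))
  alphas <- (1 - levels) / 2
  qlev <- sort(unique(c(alphas, 0.5, 1 - alphas)))
  fq <- forest_quantiles(model, Xm, levels = qlev)
  med <- fq$quantiles[, match(0.5, qlev), drop = TRUE]
  s_x <- if (adj$variant == "uacqr") .tree_spread(model, Xm, adj$eps)
         else rep(1, nrow(Xm))
  out <- vector("list", length(levels))
  for (i in seq_along(levels)) {
    lev <- levels[i]
    c_hat <- if (isTRUE(all.equal(lev, adj$level))) adj$c_hat else {
      sc <- .uacqr_scores(model, adj$X_cal, adj$y_cal, lev, adj$s_cal)
      .conformal_chat(sc, lev)
    }
    q_lo <- fq$quantiles[, match(alphas[i], qlev), drop = TRUE]
    q_hi <- fq$quantiles[, match(1 - alphas[i], qlev), drop = TRUE]
    lower <- pmin(q_lo - c_hat * s_x, med)
    upper <- pmax(q_hi + c_hat * s_x, med)
    out[[i]] <- data.frame(
      chem_id = ids, median = med, lower = lower, upper = upper,
      level = lev, width = upper - lower,
      sigma = interval_sigma(upper - lower, lev),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  do.call(rbind, out)
}

#' Train a UACQR model with an internal calibration split
#'
#' Splits the data into a training part and a stratified internal
#' calibration part (default 20%), fits the quantile forest on the
#' training part and conformalizes on the calibration part. This is the
#' protocol used both inside cross-validation folds and when retraining a
#' final model on all available data before library screening.
#'
#' @param X Feature matrix.
#' @param y Numeric targets.
#' @param level Nominal coverage (default 0.95).
#' @param cal_frac Fraction held out for calibration (default 0.2).
#' @param n_bins Stratification bins for the split (default 10).
#' @param seed Integer RNG seed (controls split and forest).
#' @param variant `"uacqr"` or `"cqr"`.
#' @param ... Passed to [fit_quantile_forest()] (`n_trees`, `leaf_min`,
#'   `mtry`).
#' @return An object of class `uacqr_model` with elements `forest`,
#'   `adjustment` and `level`.
#' @export
train_uacqr <- function(X, y, level = 0.95, cal_frac = 0.2, n_bins = 10,
                        seed = 1, variant = c("uacqr", "cqr"), ...) {
  variant <- match.arg(variant)
  X <- .as_plain_matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), cal_frac > 0, cal_frac < 1)
  k <- max(2L, round(1 / cal_frac))
  folds <- stratified_fold_assignment(y, k = k, n_bins = n_bins, seed = seed)
  cal <- folds == 1L
  forest <- fit_quantile_forest(X[!cal, , drop = FALSE], y[!cal],
                                seed = seed, ...)
  adj <- conformal_calibrate(forest, X[cal, , drop = FALSE], y[cal],
                             level = level, variant = variant)
  structure(list(forest = forest, adjustment = adj, level = level,
                 seed = seed),
            class = "uacqr_model")
}

#' Predict with a trained UACQR model
#'
#' @param object A [train_uacqr()] model.
#' @param X Query feature matrix.
#' @param levels Confidence levels (default: training level).
#' @param ... Unused.
#' @return Interval prediction data.frame (see [predict_intervals()]).
#' @export
predict.uacqr_model <- function(object, X, levels = NULL, ...) {
  predict_intervals(object$forest, object$adjustment, X, levels = levels)
}

#' @export
print.uacqr_model <- function(x, ...) {
  cat(sprintf("<uacqr_model> level=%.2f (%s), n_train=%d, n_cal=%d\n",
              x$level, x$adjustment$variant, length(x$forest$y),
              x$adjustment$n_cal))
  invisible(x)
}
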