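# Cross-validation orchestration, regression metrics, paired significance
# testing and consensus baselines.

#' Cross-validation scheme
#'
#' @param outer_folds Outer folds for generalization error (default 10).
#' @param inner_folds Inner folds for hyperparameter selection (default 5;
#'   used only by estimators that expose a grid).
#' @param repeats Number of repeated CV rounds (default 1).
#' @param n_strat_bins Target-quantile bins for stratified fold assignment
#'   (default 10).
#' @param seed Integer RNG seed.
#' @return A list of class `cv_scheme`.
#' @export
cv_scheme <- function(outer_folds = 10, inner_folds = 5, repeats = 1,
                      n_strat_bins = 10, seed = 1) {
  stopifnot(outer_folds >= 2, inner_folds >= 2, repeats >= 1,
            n_strat_bins >= 2)
  structure(list(outer_folds = outer_folds, inner_folds = inner_folds,
                 repeats = repeats, n_strat_bins = n_strat_bins,
                 seed = seed),
            class = "cv_scheme")
}

#' Stratified fold assignment by target value
#'
#' Bins targets by empirical quantiles, shuffles within each bin (seeded)
#' and deals items round-robin to folds, carrying the dealing position
#' across bins so fold sizes differ by at most one. This compensates the
#' impact of imbalanced target distributions on fold composition.
#'
#' @param y Numeric targets.
#' @param k Number of folds.
#' @param n_bins Number of quantile bins (default 10).
#' @param seed Integer RNG seed.
#' @return Integer vector of fold labels in 1..k.
#' @export
stratified_fold_assignment <- function(y, k, n_bins = 10, seed = 1) {
  y <- as.numeric(y)
  n <- length(y)
  if (k > n) stop("more folds than observations")
  stopifnot(k >= 2, n_bins >= 1)
  set.seed(seed)
  breaks <- unique(quantile(y, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- if (length(breaks) > 2) {
    cut(y, breaks, include.lowest = TRUE, labels = FALSE)
  } else rep(1L, n)
  fold <- integer(n)
  pos <- 0L
  for (b in sort(unique(bin))) {
    idx <- which(bin == b)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((pos + seq_along(idx) - 1L) %% k) + 1L
    pos <- pos + length(idx)
  }
  fold
}

#' Regression performance metrics
#'
#' MAE, median absolute error, RMSE, coefficient of determination
#' (1 - SSres/SStot about the mean of `y`), adjusted R2 (when the number
#' of features is supplied), and Pearson/Spearman correlations. R2 is
#' reported as `NA` when `y` has zero variance.
#'
#' @param y Observed targets.
#' @param y_hat Predicted values.
#' @param n_features Number of model features, for adjusted R2 (optional).
#' @return A one-row data.frame: `mae`, `mdae`, `rmse`, `r2`, `r2_adj`,
#'   `pearson`, `spearman`.
#' @export
regression_metrics <- function(y, y_hat, n_features = NA) {
  y <- as.numeric(y); y_hat <- as.numeric(y_hat)
  n <- length(y)
  if (n == 0L || n != length(y_hat)) {
    stop("y and y_hat must have equal, nonzero length")
  }
  e <- y - y_hat
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - sum(e^2) / ss_tot
  r2_adj <- if (!is.na(r2) && !is.na(n_features) && n - n_features - 1 > 0) {
    1 - (1 - r2) * (n - 1) / (n - n_features - 1)
  } else NA_real_
  pe <- if (sd(y) == 0 || sd(y_hat) == 0) NA_real_ else cor(y, y_hat)
  sp <- if (sd(y) == 0 || sd(y_hat) == 0) NA_real_ else
    cor(y, y_hat, method = "spearman")
  data.frame(mae = mean(abs(e)), mdae = median(abs(e)),
             rmse = sqrt(mean(e^2)), r2 = r2, r2_adj = r2_adj,
             pearson = pe, spearman = sp)
}

#' Paired test on model errors
#'
#' Two modes:
#' * `per_chemical`: classic paired two-sided t-test on per-unit error
#'   differences, df = n - 1;
#' * `repeated_cv_corrected`: paired t-test on per-repeat scores with the
#'   Nadeau-Bengio variance correction
#'   (variance multiplied by 1/J + test/train ratio), df = J - 1 --
#'   the appropriate test when scores come from repeated cross-validation
#'   on overlapping training sets.
#'
#' Cohen's d is mean(diff)/SD(diff); the 95% CI of the mean difference
#' uses the t distribution with the mode's df and standard error.
#' Identical inputs give t = 0, p = 1; constant nonzero differences are
#' degenerate and flagged with a warning.
#'
#' @param err_a,err_b Per-unit errors (e.g. squared errors) or per-repeat
#'   scores (e.g. RMSEs), equal length >= 2.
#' @param mode `"per_chemical"` or `"repeated_cv_corrected"`.
#' @param test_train_ratio n_test/n_train per fold for the corrected mode
#'   (default 1/9, i.e. 10-fold CV).
#' @return A list of class `paired_test`: `t_stat`, `df`, `p_value`
#'   (two-sided), `cohens_d`, `ci95`, `mean_diff`, `mode`.
#' @export
paired_error_test <- function(err_a, err_b,
                              mode = c("per_chemical",
                                       "repeated_cv_corrected"),
                              test_train_ratio = 1 / 9) {
  mode <- match.arg(mode)
  err_a <- as.numeric(err_a); err_b <- as.numeric(err_b)
  if (length(err_a) != length(err_b) || length(err_a) < 2L) {
    stop("err_a and err_b must have equal length >= 2")
  }
  d <- err_a - err_b
  n <- length(d)
  m <- mean(d); s <- sd(d)
  df <- n - 1
  if (s == 0) {
    if (m == 0) {
      res <- list(t_stat = 0, df = df, p_value = 1, cohens_d = 0,
                  ci95 = c(0, 0), mean_diff = 0, mode = mode)
      class(res) <- "paired_test"
      return(res)
    }
    warning("zero-variance differences with nonzero mean: t undefined")
    res <- list(t_stat = sign(m) * Inf, df = df, p_value = 0,
                cohens_d = NA_real_, ci95 = c(m, m), mean_diff = m,
                mode = mode)
    class(res) <- "paired_test"
    return(res)
  }
  se <- if (mode == "per_chemical") {
    s / sqrt(n)
  } else {
    s * sqrt(1 / n + test_train_ratio)
  }
  t_stat <- m / se
  p <- 2 * pt(-abs(t_stat), df)
  ci <- m + c(-1, 1) * qt(0.975, df) * se
  structure(list(t_stat = t_stat, df = df, p_value = p,
                 cohens_d = m / s, ci95 = ci, mean_diff = m, mode = mode),
            class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf(
    "<paired_test> t(%d) = %.3f, p = %.4g, Cohen's d = %.3f, 95%% CI [%.3f, %.3f]\n",
    x$df, x$t_stat, x$p_value, x$cohens_d, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Define an estimator for cross-validation
#'
#' An estimator bundles a `fit(X, y, params)` function, a
#' `predict(model, X)` function returning either a numeric vector (point
#' predictions) or an interval data.frame with `median`/`lower`/`upper`/
#' `sigma` columns, and an optional hyperparameter `grid` (list of params
#' lists) searched by inner cross-validation.
#'
#' @param name Estimator label.
#' @param fit Function `(X, y, params)` returning a fitted model.
#' @param predict Function `(model, X)` returning predictions.
#' @param grid Optional list of candidate `params` lists.
#' @return A list of class `uamtox_estimator`.
#' @export
new_estimator <- function(name, fit, predict, grid = NULL) {
  stopifnot(is.character(name), is.function(fit), is.function(predict))
  structure(list(name = name, fit = fit, predict = predict, grid = grid),
            class = "uamtox_estimator")
}

#' UACQR estimator for cross-validation
#'
#' Inside each training fold the estimator performs its own internal
#' stratified calibration split, so conformal calibration never sees the
#' test fold.
#'
#' @param level Nominal coverage (default 0.95).
#' @param cal_frac Internal calibration fraction (default 0.2).
#' @param n_trees,leaf_min Forest settings.
#' @param variant `"uacqr"` or `"cqr"`.
#' @param seed Integer RNG seed for the internal split and forest.
#' @return An `uamtox_estimator`.
#' @export
estimator_uacqr <- function(level = 0.95, cal_frac = 0.2, n_trees = 500,
                            leaf_min = 5, variant = "uacqr", seed = 1) {
  new_estimator(
    name = "uacqr",
    fit = function(X, y, params = NULL) {
      train_uacqr(X, y, level = level, cal_frac = cal_frac,
                  n_trees = n_trees, leaf_min = leaf_min,
                  variant = variant, seed = seed)
    },
    predict = function(model, X) predict(model, X)
  )
}

#' BNN estimator for cross-validation
#'
#' @param config A [bnn_config()].
#' @param n_draws Predictive draws per chemical (default: config value).
#' @return An `uamtox_estimator`.
#' @export
estimator_bnn <- function(config = bnn_config(), n_draws = NULL) {
  new_estimator(
    name = "bnn",
    fit = function(X, y, params = NULL) fit_bnn(X, y, config),
    predict = function(model, X) {
      draws <- sample_predictions(model, X, n_draws = n_draws,
                                  seed = config$seed)
      summarize_predictive(draws)
    }
  )
}

#' Conventional baseline estimators
#'
#' Plug-in wrappers around standard regression learners used purely as
#' benchmarks: `linear` (ordinary least squares), `ridge` (glmnet),
#' `knn` (caret::knnreg), `svm` (e1071 radial SVR), `rf` (ranger random
#' forest), `xgboost` (gradient boosting) and `nnet` (single-hidden-layer
#' feed-forward network). Each returns point predictions only.
#'
#' @param name Baseline name.
#' @param params Default hyperparameters passed to the learner.
#' @param grid Optional hyperparameter grid (list of params lists) for
#'   inner-CV selection.
#' @return An `uamtox_estimator`.
#' @export
baseline_estimator <- function(name = c("linear", "ridge", "knn", "svm",
                                        "rf", "xgboost", "nnet"),
                               params = list(), grid = NULL) {
  name <- match.arg(name)
  need <- function(pkg) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      stop("baseline '", name, "' needs the ", pkg, " package")
    }
  }
  fit <- switch(name,
    linear = function(X, y, params = NULL) {
      stats::lm(y ~ ., data = data.frame(y = y, X, check.names = FALSE))
    },
    ridge = function(X, y, params = NULL) {
      need("glmnet")
      glmnet::cv.glmnet(.as_plain_matrix(X), y, alpha = 0, nfolds = 5)
    },
    knn = function(X, y, params = NULL) {
      k <- if (!is.null(params$k)) params$k else 5
      caret::knnreg(.as_plain_matrix(X), y, k = k)
    },
    svm = function(X, y, params = NULL) {
      need("e1071")
      do.call(e1071::svm,
              c(list(x = .as_plain_matrix(X), y = y), params))
    },
    rf = function(X, y, params = NULL) {
      do.call(ranger::ranger,
              c(list(x = .as_plain_matrix(X), y = y, num.threads = 1,
                     seed = 1), params))
    },
    xgboost = function(X, y, params = NULL) {
      need("xgboost")
      nrounds <- if (!is.null(params$nrounds)) params$nrounds else 100
      params$nrounds <- NULL
      xgboost::xgboost(data = .as_plain_matrix(X), label = y,
                       nrounds = nrounds, verbose = 0, nthread = 1,
                       params = params)
    },
    nnet = function(X, y, params = NULL) {
      need("nnet")
      size <- if (!is.null(params$size)) params$size else 8
      decay <- if (!is.null(params$decay)) params$decay else 0.01
      set.seed(1)
      nnet::nnet(.as_plain_matrix(X), y, size = size, decay = decay,
                 linout = TRUE, maxit = 300, trace = FALSE)
    })
  pred <- switch(name,
    linear = function(model, X) {
      unname(predict(model, data.frame(X, check.names = FALSE)))
    },
    ridge = function(model, X) {
      as.numeric(predict(model, .as_plain_matrix(X), s = "lambda.min"))
    },
    rf = function(model, X) {
      predict(model, .as_plain_matrix(X), num.threads = 1)$predictions
    },
    function(model, X) as.numeric(predict(model, .as_plain_matrix(X))))
  est <- new_estimator(name = name, fit = fit, predict = pred, grid = grid)
  est$default_params <- params
  est
}

.inner_select <- function(estimator, X, y, inner_folds, n_bins, seed) {
  if (is.null(estimator$grid) || length(estimator$grid) < 2L) {
    return(estimator$grid[[1]] %||% estimator$default_params)
  }
  folds <- stratified_fold_assignment(y, k = inner_folds, n_bins = n_bins,
                                      seed = seed)
  score <- vapply(estimator$grid, function(params) {
    errs <- vapply(seq_len(inner_folds), function(f) {
      tr <- folds != f
      model <- estimator$fit(X[tr, , drop = FALSE], y[tr], params)
      p <- estimator$predict(model, X[!tr, , drop = FALSE])
      if (is.data.frame(p)) p <- p$median
      sqrt(mean((y[!tr] - p)^2))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  estimator$grid[[which.min(score)]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run (repeated, nested) cross-validation
#'
#' Splits the data into `outer_folds` stratified folds per repeat, fits
#' the feature pipeline and the estimator strictly inside each training
#' fold (including any inner-CV hyperparameter selection and, for the
#' conformal estimator, its internal calibration split), and collects
#' out-of-fold predictions and per-fold metrics. Every chemical appears in
#' exactly one test fold per repeat.
#'
#' @param estimator An `uamtox_estimator`.
#' @param X A [feature_matrix()] of raw (pre-pipeline) features.
#' @param y Numeric targets.
#' @param scheme A [cv_scheme()].
#' @param chem_ids Identifiers (default: row names of `X`).
#' @param corr_threshold Correlation threshold for the per-fold pipeline.
#' @param keep_pipelines Keep the fitted per-fold pipelines in the result
#'   (for leakage audits).
#' @return An object of class `cv_result` with `predictions` (data.frame:
#'   `chem_id`, `repeat_idx`, `fold`, `y`, point or interval columns),
#'   `fold_metrics`, `repeat_metrics` and `pooled` metrics.
#' @export
run_cross_validation <- function(estimator, X, y, scheme = cv_scheme(),
                                 chem_ids = NULL, corr_threshold = 0.9,
                                 keep_pipelines = FALSE) {
  stopifnot(inherits(estimator, "uamtox_estimator"),
            inherits(scheme, "cv_scheme"))
  y <- as.numeric(y)
  if (is.null(chem_ids)) {
    chem_ids <- if (!is.null(rownames(X))) rownames(X)
                else sprintf("x%d", seq_along(y))
  }
  has_pipeline <- inherits(X, "feature_matrix")
  preds <- list(); fold_metrics <- list(); pipelines <- list()
  for (r in seq_len(scheme$repeats)) {
    rseed <- scheme$seed + 101L * (r - 1L)
    folds <- stratified_fold_assignment(y, k = scheme$outer_folds,
                                        n_bins = scheme$n_strat_bins,
                                        seed = rseed)
    for (f in seq_len(scheme$outer_folds)) {
      tr <- folds != f
      res <- tryCatch({
        if (has_pipeline) {
          pipe <- fit_feature_pipeline(X[tr, , drop = FALSE],
                                       corr_threshold = corr_threshold)
          Xtr <- apply_feature_pipeline(pipe, X[tr, , drop = FALSE])
          Xte <- apply_feature_pipeline(pipe, X[!tr, , drop = FALSE])
        } else {
          pipe <- NULL
          Xtr <- X[tr, , drop = FALSE]
          Xte <- X[!tr, , drop = FALSE]
        }
        params <- .inner_select(estimator, Xtr, y[tr], scheme$inner_folds,
                                scheme$n_strat_bins, rseed)
        model <- estimator$fit(Xtr, y[tr], params)
        p <- estimator$predict(model, Xte)
        list(p = p, pipe = pipe)
      }, error = function(e) {
        stop("estimator '", estimator$name, "' failed in repeat ", r,
             ", fold ", f, ": ", conditionMessage(e))
      })
      p <- res$p
      base <- data.frame(chem_id = chem_ids[!tr], repeat_idx = r, fold = f,
                         y = y[!tr], stringsAsFactors = FALSE)
      if (is.data.frame(p)) {
        base$pred <- p$median
        base$lower <- p$lower; base$upper <- p$upper; base$sigma <- p$sigma
        base$width <- p$width
      } else {
        base$pred <- as.numeric(p)
      }
      preds[[length(preds) + 1L]] <- base
      fm <- regression_metrics(base$y, base$pred)
      fm$repeat_idx <- r; fm$fold <- f
      fold_metrics[[length(fold_metrics) + 1L]] <- fm
      if (keep_pipelines) {
        pipelines[[sprintf("r%d_f%d", r, f)]] <- res$pipe
      }
    }
  }
  predictions <- do.call(rbind, preds)
  fold_metrics <- do.call(rbind, fold_metrics)
  repeat_metrics <- do.call(rbind, lapply(seq_len(scheme$repeats),
    function(r) {
      sub <- predictions[predictions$repeat_idx == r, ]
      m <- regression_metrics(sub$y, sub$pred)
      m$repeat_idx <- r
      m
    }))
  structure(list(
    estimator = estimator$name,
    predictions = predictions,
    fold_metrics = fold_metrics,
    repeat_metrics = repeat_metrics,
    pooled = regression_metrics(predictions$y, predictions$pred),
    scheme = scheme,
    pipelines = if (keep_pipelines) pipelines else NULL
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %s: %d repeats x %d folds, pooled RMSE %.3f, R2 %.3f\n",
    x$estimator, x$scheme$repeats, x$scheme$outer_folds,
    x$pooled$rmse, x$pooled$r2))
  invisible(x)
}

#' Build a consensus model from cross-validated candidates
#'
#' The consensus members are the best candidate (lowest mean per-repeat
#' score) plus every candidate not significantly worse than it under a
#' paired corrected t-test (two-sided p >= 0.05,
#' [paired_error_test()] in `repeated_cv_corrected` mode). The consensus
#' prediction is the unweighted mean of the members' predictions per
#' chemical. `rule = "best_only"` instead keeps only the single best
#' candidate.
#'
#' @param predictions Named list of aligned per-chemical prediction
#'   vectors, one per candidate model.
#' @param scores Matrix of per-repeat scores (rows = repeats, columns =
#'   candidates; lower is better), column names matching `predictions`.
#' @param alpha Significance threshold (default 0.05).
#' @param rule `"not_worse_than_best"` (default) or `"best_only"`.
#' @param test_train_ratio Passed to [paired_error_test()].
#' @return List with `members`, `consensus` (numeric vector) and the
#'   per-candidate `tests`.
#' @export
build_consensus <- function(predictions, scores, alpha = 0.05,
                            rule = c("not_worse_than_best", "best_only"),
                            test_train_ratio = 1 / 9) {
  rule <- match.arg(rule)
  stopifnot(is.list(predictions), length(predictions) >= 1)
  nms <- names(predictions)
  if (is.null(nms) || any(!nzchar(nms))) stop("predictions must be named")
  if (length(predictions) == 1L) {
    return(list(members = nms, consensus = predictions[[1]], tests = NULL))
  }
  scores <- as.matrix(scores)
  if (!all(nms %in% colnames(scores))) {
    stop("scores must have one column per candidate")
  }
  if (nrow(scores) < 2L) {
    stop("need >= 2 repeats of scores for significance testing")
  }
  mean_score <- colMeans(scores[, nms, drop = FALSE])
  best <- nms[which.min(mean_score)]
  tests <- list()
  members <- best
  if (rule == "not_worse_than_best") {
    for (m in setdiff(nms, best)) {
      tst <- paired_error_test(scores[, m], scores[, best],
                               mode = "repeated_cv_corrected",
                               test_train_ratio = test_train_ratio)
      tests[[m]] <- tst
      if (identical(predictions[[m]], predictions[[best]]) ||
          tst$p_value >= alpha) {
        members <- c(members, m)
      }
    }
  }
  mat <- do.call(cbind, predictions[members])
  list(members = members, consensus = rowMeans(mat), tests = tests)
}
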