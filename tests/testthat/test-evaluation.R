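test_that("stratified folds are balanced, deterministic and stratified", {
  set.seed(60)
  y <- rexp(100)
  f <- stratified_fold_assignment(y, k = 10, seed = 7)
  expect_equal(as.integer(table(f)), rep(10L, 10))
  expect_identical(f, stratified_fold_assignment(y, k = 10, seed = 7))
  expect_false(identical(f, stratified_fold_assignment(y, k = 10, seed = 8)))
  expect_error(stratified_fold_assignment(y, k = 101), "folds")
  # per-fold target means stay near the global mean on a skewed target
  y2 <- rexp(1000, 0.5)^1.5
  f2 <- stratified_fold_assignment(y2, k = 10, seed = 9)
  fold_means <- tapply(y2, f2, mean)
  expect_true(all(abs(fold_means - mean(y2)) < 0.5 * sd(y2)))
})

test_that("regression metrics match hand computation and the naive oracle", {
  m <- regression_metrics(c(0, 1, 2), c(0, 1, 3))
  expect_equal(m$mae, 1 / 3)
  expect_equal(m$mdae, 0)
  expect_equal(m$rmse, sqrt(1 / 3))
  expect_equal(m$r2, 0.5)
  # identity and null-model limits
  ident <- regression_metrics(1:5, 1:5)
  expect_equal(c(ident$mae, ident$rmse), c(0, 0))
  expect_equal(ident$r2, 1)
  y <- c(2, 4, 6, 8)
  expect_equal(regression_metrics(y, rep(mean(y), 4))$r2, 0)
  # zero-variance targets: R2 undefined
  expect_true(is.na(regression_metrics(rep(1, 5), rnorm(5))$r2))
  # agreement with a naive reimplementation across random vectors
  for (s in 1:20) {
    set.seed(s)
    n <- sample(10:1000, 1)
    yy <- rnorm(n); yh <- yy + rnorm(n, 0, 0.7)
    got <- regression_metrics(yy, yh)
    ora <- oracle_metrics(yy, yh)
    expect_equal(got$mae, ora$mae, tolerance = 1e-10)
    expect_equal(got$mdae, ora$mdae, tolerance = 1e-10)
    expect_equal(got$rmse, ora$rmse, tolerance = 1e-10)
    expect_equal(got$r2, ora$r2, tolerance = 1e-10)
  }
})

test_that("paired error tests cover both df conventions", {
  # identical errors: no difference
  t0 <- paired_error_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(t0$t_stat, 0)
  expect_equal(t0$p_value, 1)
  expect_equal(t0$cohens_d, 0)
  # hand example: diffs (1,2,3), mean 2, SD 1, t = 2 sqrt(3), df = 2
  th <- paired_error_test(c(2, 4, 6), c(1, 2, 3), mode = "per_chemical")
  expect_equal(th$t_stat, 2 / (1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(th$df, 2)
  expect_equal(th$p_value, 2 * pt(-2 * sqrt(3), 2), tolerance = 1e-9)
  expect_equal(th$cohens_d, 2)
  # antisymmetry
  ts <- paired_error_test(c(1, 2, 3), c(2, 4, 6), mode = "per_chemical")
  expect_equal(ts$t_stat, -th$t_stat)
  expect_equal(ts$cohens_d, -th$cohens_d)
  expect_equal(ts$p_value, th$p_value)
  # corrected mode inflates the variance, shrinking |t|
  set.seed(61)
  a <- rnorm(10, 0.5); b <- rnorm(10)
  tc <- paired_error_test(a, b, mode = "repeated_cv_corrected")
  tp <- paired_error_test(a, b, mode = "per_chemical")
  expect_lt(abs(tc$t_stat), abs(tp$t_stat))
  expect_equal(tc$df, 9)
  # degenerate nonzero constant difference is flagged
  expect_warning(paired_error_test(c(2, 3, 4), c(1, 2, 3)), "undefined")
})

test_that("cross-validation partitions data and handles degenerate targets", {
  set.seed(62)
  X <- feature_matrix(matrix(rnorm(300), 60, 5,
                             dimnames = list(sprintf("c%02d", 1:60),
                                             paste0("f", 1:5))),
                      "learned_embedding")
  lin <- baseline_estimator("linear")
  # constant targets: every fold predicts the constant
  cv0 <- run_cross_validation(lin, X, rep(2.5, 60),
                              scheme = cv_scheme(outer_folds = 5, seed = 3))
  expect_equal(cv0$pooled$rmse, 0, tolerance = 1e-12)
  # every chemical appears in exactly one test fold per repeat
  y <- rnorm(60)
  cv <- run_cross_validation(lin, X, y,
                             scheme = cv_scheme(outer_folds = 5,
                                                repeats = 2, seed = 4))
  for (r in 1:2) {
    sub <- cv$predictions[cv$predictions$repeat_idx == r, ]
    expect_equal(sort(sub$chem_id), sort(rownames(X)))
  }
  expect_equal(nrow(cv$repeat_metrics), 2L)
  # errors are attributed to a fold and repeat
  bad <- new_estimator("boom", fit = function(X, y, params) stop("nope"),
                       predict = function(m, X) NULL)
  expect_error(run_cross_validation(bad, X, y,
                                    scheme = cv_scheme(outer_folds = 5)),
               "repeat 1, fold 1")
})

test_that("fold pipelines never see test data (leakage probe)", {
  set.seed(63)
  ids <- sprintf("c%02d", 1:50)
  X <- feature_matrix(matrix(rexp(250), 50, 5,
                             dimnames = list(ids, paste0("f", 1:5))),
                      "physchem_2d")
  y <- rnorm(50)
  sch <- cv_scheme(outer_folds = 5, seed = 11)
  lin <- baseline_estimator("linear")
  cv1 <- run_cross_validation(lin, X, y, scheme = sch, keep_pipelines = TRUE)
  # corrupt each fold's test-fold feature rows; training rows untouched
  folds <- stratified_fold_assignment(y, k = 5, seed = 11)
  for (f in 1:5) {
    Xc <- X
    Xc[folds == f, ] <- Xc[folds == f, ] * 1000 + 77
    Xc <- feature_matrix(unclass(Xc)[, ], "physchem_2d", chem_ids = ids,
                         feature_names = paste0("f", 1:5))
    pipe_corrupt <- fit_feature_pipeline(Xc[folds != f, ])
    expect_identical(serialize(pipe_corrupt, NULL),
                     serialize(cv1$pipelines[[sprintf("r1_f%d", f)]], NULL))
  }
  # per-fold preprocessing parameters differ across folds
  centers <- lapply(cv1$pipelines, `[[`, "center")
  expect_gt(length(unique(vapply(centers, function(ct) ct[1], numeric(1)))),
            1L)
})

test_that("uacqr estimator runs inside cross-validation with intervals", {
  set.seed(64)
  ids <- sprintf("c%03d", 1:120)
  X <- feature_matrix(matrix(rnorm(240), 120, 2,
                             dimnames = list(ids, c("a", "b"))),
                      "learned_embedding")
  y <- X[, 1] + rnorm(120, 0, 0.3)
  cv <- run_cross_validation(estimator_uacqr(n_trees = 40, seed = 5), X, y,
                             scheme = cv_scheme(outer_folds = 4, seed = 6))
  expect_true(all(c("lower", "upper", "sigma") %in% names(cv$predictions)))
  expect_true(all(cv$predictions$lower <= cv$predictions$pred))
  expect_true(all(cv$predictions$pred <= cv$predictions$upper))
})

test_that("consensus keeps statistical peers and drops worse models", {
  set.seed(65)
  n <- 80
  truth <- rnorm(n)
  pred_a <- truth + rnorm(n, 0, 0.3)
  pred_b <- truth + rnorm(n, 0, 0.32)
  pred_c <- truth + rnorm(n, 0, 3)      # grossly worse
  reps <- 10
  score_a <- 0.30 + rnorm(reps, 0, 0.01)
  scores <- cbind(
    a = score_a,
    b = score_a + rnorm(reps, 0, 0.02),   # statistically indistinguishable
    c = 3.00 + rnorm(reps, 0, 0.05))
  cons <- build_consensus(list(a = pred_a, b = pred_b, c = pred_c), scores)
  expect_setequal(cons$members, c("a", "b"))
  expect_equal(cons$consensus, rowMeans(cbind(pred_a, pred_b)),
               tolerance = 1e-12)
  # single candidate: consensus is that model
  solo <- build_consensus(list(only = pred_a), scores[, 1, drop = FALSE])
  expect_equal(solo$members, "only")
  expect_equal(solo$consensus, pred_a)
  # two identical models: consensus equals their shared predictions
  twin <- build_consensus(list(m1 = pred_a, m2 = pred_a),
                          cbind(m1 = scores[, "a"], m2 = scores[, "a"]))
  expect_equal(twin$consensus, pred_a)
  # best-only rule keeps a single member
  best <- build_consensus(list(a = pred_a, b = pred_b, c = pred_c), scores,
                          rule = "best_only")
  expect_equal(best$members, "a")
})

test_that("consensus error never exceeds the worst member error", {
  for (s in 1:20) {
    set.seed(100 + s)
    truth <- rnorm(50)
    preds <- list(a = truth + rnorm(50, 0, 0.4),
                  b = truth + rnorm(50, 0, 0.6))
    scores <- cbind(a = 0.4 + rnorm(5, 0, 0.01),
                    b = 0.6 + rnorm(5, 0, 0.01))
    cons <- build_consensus(preds, scores)
    rmse <- function(p) sqrt(mean((truth - p)^2))
    worst <- max(vapply(preds[cons$members], rmse, numeric(1)))
    expect_lte(rmse(cons$consensus), worst)
  }
})
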