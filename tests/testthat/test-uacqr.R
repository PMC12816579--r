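test_that("degenerate training data predicts the constant at all quantiles", {
  x <- matrix(c(0, 0), ncol = 1, dimnames = list(NULL, "x"))
  qf <- fit_quantile_forest(x, c(3.5, 3.5), n_trees = 10, leaf_min = 1,
                            seed = 1)
  q <- forest_quantiles(qf, matrix(c(-1, 2), ncol = 1),
                        levels = c(0.1, 0.5, 0.9))$quantiles
  expect_true(all(q == 3.5))
})

test_that("forests are deterministic given the seed", {
  set.seed(10)
  x <- matrix(rnorm(60), ncol = 2, dimnames = list(NULL, c("a", "b")))
  y <- rnorm(30)
  qf1 <- fit_quantile_forest(x, y, n_trees = 25, seed = 99)
  qf2 <- fit_quantile_forest(x, y, n_trees = 25, seed = 99)
  q1 <- forest_quantiles(qf1, x, levels = c(0.05, 0.5, 0.95))$quantiles
  q2 <- forest_quantiles(qf2, x, levels = c(0.05, 0.5, 0.95))$quantiles
  expect_identical(q1, q2)
  expect_identical(qf1$train_leaf, qf2$train_leaf)
})

test_that("median tracks a step function away from the jump", {
  d <- make_step_data(n = 200, seed = 2)
  qf <- fit_quantile_forest(d$x, d$y, n_trees = 100, leaf_min = 5, seed = 3)
  q <- forest_quantiles(qf, matrix(c(-1, 1), ncol = 1,
                                   dimnames = list(NULL, "x")),
                        levels = 0.5)$quantiles
  expect_equal(unname(q[1, 1]), 0)
  expect_equal(unname(q[2, 1]), 1)
  # and equals the brute-force weighted-CDF oracle
  probe <- matrix(seq(-2, 2, length.out = 7), ncol = 1,
                  dimnames = list(NULL, "x"))
  expect_equal(
    unname(forest_quantiles(qf, probe, levels = c(0.25, 0.5, 0.75))$quantiles),
    oracle_forest_quantiles(qf, probe, c(0.25, 0.5, 0.75)))
})

test_that("hand-built two-tree example reproduces the weighted CDF", {
  # 4 training targets (1,3,3,5); the query lands in a leaf holding {1,3}
  # in tree 1 and one holding {3,5} in tree 2 -> weights 0.25 each on
  # values 1,3,3,5; the weighted median is 3.
  train_leaf <- cbind(c(1L, 1L, 2L, 2L), c(1L, 1L, 2L, 2L))
  test_leaf <- matrix(c(1L, 2L), nrow = 1)
  inbag <- matrix(1L, 4, 2)
  y <- c(1, 3, 3, 5)
  out <- uamtox:::qrf_quantiles_cpp(train_leaf, test_leaf, inbag, y,
                                    c(0.25, 0.5, 0.9), TRUE)
  expect_equal(unname(out$quantiles[1, ]), c(1, 3, 5))
  # per-tree medians: tree 1 leaf {1,3} -> 1; tree 2 leaf {3,5} -> 3
  expect_equal(as.numeric(out$per_tree[1, , 2]), c(1, 3))
})

test_that("quantiles are nondecreasing in the level", {
  set.seed(11)
  x <- matrix(rnorm(100), ncol = 2, dimnames = list(NULL, c("a", "b")))
  y <- x[, 1] + rnorm(50, 0, 0.3)
  qf <- fit_quantile_forest(x, y, n_trees = 50, seed = 5)
  q <- forest_quantiles(qf, x[1:10, ],
                        levels = c(0.025, 0.25, 0.5, 0.75, 0.975))$quantiles
  expect_true(all(apply(q, 1, function(r) all(diff(r) >= 0))))
})

test_that("a single-tree forest equals that tree's leaf quantiles", {
  set.seed(12)
  x <- matrix(rnorm(40), ncol = 1, dimnames = list(NULL, "x"))
  y <- rnorm(40)
  qf <- fit_quantile_forest(x, y, n_trees = 1, leaf_min = 5, seed = 6)
  probe <- x[1:5, , drop = FALSE]
  ens <- forest_quantiles(qf, probe, levels = 0.5)$quantiles[, 1]
  tree <- oracle_tree_quantiles(qf, probe, 0.5)[, 1]
  expect_equal(unname(ens), unname(tree))
})

test_that("conformal rank formula and CQR reduction hold", {
  set.seed(13)
  x <- matrix(rnorm(300), ncol = 1, dimnames = list(NULL, "x"))
  y <- x[, 1] + rnorm(300, 0, 0.5)
  qf <- fit_quantile_forest(x[1:250, , drop = FALSE], y[1:250],
                            n_trees = 60, seed = 7)
  # n_cal = 19 at level 0.95: k = ceil(0.95 * 20) = 19 -> the max score
  adj19 <- conformal_calibrate(qf, x[251:269, , drop = FALSE], y[251:269],
                               level = 0.95)
  expect_equal(adj19$c_hat, max(adj19$scores))
  expect_equal(adj19$n_cal, 19L)
  # s == 1 reduces UACQR scores to plain CQR scores
  adj_cqr <- conformal_calibrate(qf, x[251:300, , drop = FALSE], y[251:300],
                                 level = 0.9, variant = "cqr")
  a <- 0.05
  fq <- forest_quantiles(qf, x[251:300, , drop = FALSE],
                         levels = c(a, 1 - a))$quantiles
  manual <- pmax(fq[, 1] - y[251:300], y[251:300] - fq[, 2])
  expect_equal(unname(adj_cqr$scores), unname(manual))
  expect_error(conformal_calibrate(qf, x[0, , drop = FALSE], numeric(0)),
               "empty")
})

test_that("intervals respect c_hat, ordering and level monotonicity", {
  set.seed(14)
  x <- matrix(rnorm(400), ncol = 1, dimnames = list(NULL, "x"))
  y <- sin(x[, 1]) + rnorm(400, 0, 0.3)
  qf <- fit_quantile_forest(x[1:300, , drop = FALSE], y[1:300],
                            n_trees = 80, seed = 8)
  adj <- conformal_calibrate(qf, x[301:400, , drop = FALSE], y[301:400])
  probe <- x[1:20, , drop = FALSE]
  iv <- predict_intervals(qf, adj, probe)
  expect_true(all(iv$lower <= iv$median & iv$median <= iv$upper))
  expect_equal(iv$width, iv$upper - iv$lower)
  expect_equal(iv$sigma, iv$width / (2 * qnorm(0.975)))
  # zero conformal correction returns the raw quantile pair
  adj0 <- adj
  adj0$c_hat <- 0
  iv0 <- predict_intervals(qf, adj0, probe)
  fq <- forest_quantiles(qf, probe, levels = c(0.025, 0.975))$quantiles
  expect_equal(iv0$lower, pmin(unname(fq[, 1]), iv0$median))
  expect_equal(iv0$upper, pmax(unname(fq[, 2]), iv0$median))
  # width nondecreasing in the confidence level
  ivs <- predict_intervals(qf, adj, probe, levels = c(0.5, 0.8, 0.95))
  wmat <- matrix(ivs$width, nrow = nrow(probe))
  expect_true(all(apply(wmat, 1, function(r) all(diff(r) >= -1e-9))))
  expect_error(predict_intervals(qf, list(), probe), "conformal_adjustment")
})

test_that("interval width converts to a Gaussian-equivalent sigma", {
  expect_equal(interval_sigma(3.92, 0.95), 1, tolerance = 1e-4)
  expect_equal(interval_sigma(2 * qnorm(0.75), 0.5), 1)
})

test_that("epistemic spread grows outside the training range", {
  set.seed(15)
  x <- matrix(runif(300, -1, 1), ncol = 1, dimnames = list(NULL, "x"))
  y <- x[, 1]^2 + rnorm(300, 0, 0.2)
  qf <- fit_quantile_forest(x, y, n_trees = 100, seed = 9)
  probe_d <- seq(0, 4, length.out = 25)
  probe <- matrix(probe_d, ncol = 1, dimnames = list(NULL, "x"))
  s <- uamtox:::.tree_spread(qf, probe, 1e-6)
  expect_gt(cor(probe_d, s, method = "spearman"), 0)
})

test_that("train_uacqr keeps calibration disjoint and predicts intervals", {
  set.seed(16)
  x <- matrix(rnorm(600), ncol = 2, dimnames = list(NULL, c("a", "b")))
  y <- x[, 1] - x[, 2] + rnorm(300, 0, 0.4)
  m <- train_uacqr(x, y, n_trees = 60, seed = 17)
  expect_equal(length(m$forest$y) + m$adjustment$n_cal, 300L)
  expect_equal(m$adjustment$n_cal, 60L)   # 20% split
  iv <- predict(m, x[1:5, ])
  expect_s3_class(iv, "data.frame")
  expect_true(all(iv$lower <= iv$median & iv$median <= iv$upper))
})
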