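test_that("ECE identities: exact, always-cover and never-cover intervals", {
  y <- 1:100
  levels <- seq(0.01, 0.99, by = 0.01)
  # intervals covering exactly the expected fraction at every level
  exact <- confidence_calibration(y, function(p) {
    data.frame(lower = 0, upper = sort(y)[round(p * 100)])
  }, levels)
  expect_equal(exact$ece, 0)
  # infinite intervals: observed fraction is always 1
  always <- confidence_calibration(y, function(p) {
    data.frame(lower = -Inf, upper = Inf)
  }, levels)
  expect_equal(always$points$observed, rep(1, 99))
  expect_equal(always$ece, mean(1 - levels))
  expect_equal(always$ece, 0.5)
  # zero-width wrong intervals: never cover
  never <- confidence_calibration(y, function(p) {
    data.frame(lower = -2, upper = -2)
  }, levels)
  expect_equal(never$ece, mean(levels))
  expect_equal(never$ece, 0.5)
  expect_error(confidence_calibration(numeric(0), function(p) NULL), "empty")
})

test_that("ECE of perfectly calibrated Gaussian predictions is near zero", {
  set.seed(50)
  n <- 10000
  mu <- rnorm(n, 0, 2)
  s <- runif(n, 0.2, 1.5)
  y <- rnorm(n, mu, s)
  cc <- confidence_calibration(y, function(p) {
    z <- qnorm(1 - (1 - p) / 2)
    data.frame(lower = mu - z * s, upper = mu + z * s)
  })
  expect_lt(abs(cc$ece), 0.02)
  expect_true(all(cc$points$observed >= 0 & cc$points$observed <= 1))
})

test_that("uncertainty batching matches the entropy-based sqrt(n) rule", {
  set.seed(51)
  b100 <- batch_by_uncertainty(runif(100))
  expect_equal(b100$B, 10L)
  expect_equal(b100$sizes, rep(10L, 10))
  # the two study-sized datasets give batches of 42-49 chemicals
  b2357 <- batch_by_uncertainty(runif(2357))
  expect_equal(b2357$B, 49L)
  expect_equal(sort(unique(b2357$sizes)), c(48L, 49L))
  expect_equal(sum(b2357$sizes == 49L), 5L)
  b1845 <- batch_by_uncertainty(runif(1845))
  expect_equal(b1845$B, 43L)
  expect_equal(sort(unique(b1845$sizes)), c(42L, 43L))
  expect_true(all(c(b2357$sizes, b1845$sizes) >= 42 &
                    c(b2357$sizes, b1845$sizes) <= 49))
})

test_that("batches partition the data sorted by uncertainty", {
  set.seed(52)
  sigma <- runif(137)
  b <- batch_by_uncertainty(sigma)
  expect_equal(sum(b$sizes), 137L)
  expect_lte(diff(range(b$sizes)), 1L)
  # remainder goes to the highest-uncertainty batches
  expect_true(all(diff(b$sizes) >= 0))
  # concatenating batches in order restores the sorted order
  ord_from_batches <- unlist(lapply(seq_len(b$B), function(k) {
    idx <- b$order[b$assignment[b$order] == k]
    idx
  }))
  expect_equal(sigma[ord_from_batches], sort(sigma))
  # batch index is nondecreasing along the sorted items
  expect_true(all(diff(b$assignment[b$order]) >= 0))
  expect_error(batch_by_uncertainty(sigma, B = 200), "batches")
})

test_that("ENCE matches hand computation on the four-point example", {
  y_hat <- rep(0, 4)
  y <- c(1, 1, 1, 3)           # absolute errors 1,1,1,3
  sigma <- c(1, 1, 2, 2)
  res <- ence(y, y_hat, sigma, B = 2)
  # batches (1,1) and (2,2): RMU = (1,2), RMSE = (1, sqrt(5))
  expected <- (0 + abs(2 - sqrt(5)) / 2) / 2
  expect_equal(res$ence, expected, tolerance = 1e-10)
  expect_lt(abs(res$ence - 0.0590), 1e-4)
  expect_equal(res$curve$points$rmu, c(1, 2))
  expect_equal(res$curve$points$rmse, c(1, sqrt(5)))
  # doubling sigma with unchanged errors follows the closed form
  res2 <- ence(y, y_hat, 2 * sigma, B = 2)
  rmu <- c(1, 2); rmse <- c(1, sqrt(5))
  expect_equal(res2$ence, mean(abs(2 * rmu - rmse) / (2 * rmu)),
               tolerance = 1e-10)
  expect_error(ence(y, y_hat, c(0, 0, 1, 1), B = 2), "RMU = 0")
})

test_that("ENCE is zero for perfect error calibration and scale-aware", {
  set.seed(53)
  y_hat <- rnorm(60)
  err <- rep(c(0.3, 0.7, 1.1), each = 20) * sample(c(-1, 1), 60, TRUE)
  y <- y_hat + err
  sigma <- abs(err)            # sigma equals each item's absolute error
  expect_equal(ence(y, y_hat, sigma, B = 3)$ence, 0)
  # joint rescaling leaves ENCE unchanged
  set.seed(54)
  y2 <- rnorm(200); yh2 <- y2 + rnorm(200, 0, 0.5)
  s2 <- runif(200, 0.1, 1)
  e1 <- ence(y2, yh2, s2)$ence
  e2 <- ence(3 * y2, 3 * yh2, 3 * s2)$ence
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("ENCE sensitivity sweeps the batch count", {
  set.seed(55)
  yh <- rnorm(300); y <- yh + rnorm(300, 0, 0.4)
  s <- runif(300, 0.2, 0.8)
  tab <- ence_sensitivity(y, yh, s, B_range = c(5, 10))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$B, c(5L, 10L))
  expect_true(all(is.finite(tab$ence)))
  # B = 1 on perfectly calibrated data gives 0
  err <- rnorm(300, 0, 0.5)
  expect_equal(ence_sensitivity(err + yh, yh, abs(err), B_range = 1)$ence, 0)
  expect_error(ence_sensitivity(y, yh, s, B_range = 500), "exceeds")
})

test_that("Jaccard kNN distances match hand computations", {
  train <- rbind(c(1, 1, 1, 0, 0),
                 c(0, 1, 1, 1, 0),
                 c(0, 0, 0, 0, 1))
  # identical to >= k training fingerprints -> 0
  expect_equal(knn_jaccard(c(1, 1, 1, 0, 0), rbind(train[1, ], train[1, ]),
                           k = 2), 0)
  # disjoint from all -> 1
  expect_equal(knn_jaccard(c(0, 0, 0, 0, 1), train[1:2, ], k = 2), 1)
  # bits {1,2,3} vs {2,3,4}: intersection 2, union 4 -> 0.5
  expect_equal(knn_jaccard(train[1, ], train[2, , drop = FALSE], k = 1), 0.5)
  # empty union is defined as distance 0
  expect_equal(knn_jaccard(rep(0, 5), matrix(0, 1, 5), k = 1), 0)
  expect_error(knn_jaccard(train[1, ], train, k = 5), "exceeds")
  # symmetric pairwise kernel, bounded in [0, 1]
  set.seed(56)
  a <- matrix(rbinom(50, 1, 0.4), 10, 5)
  d_ab <- knn_jaccard(a, a, k = 1)
  expect_true(all(d_ab >= 0 & d_ab <= 1))
  expect_equal(d_ab, rep(0, 10))   # self-distance
})

test_that("distance calibration reports monotone association", {
  set.seed(57)
  sigma <- sort(runif(200, 0.1, 1))
  # distances strictly increasing with sigma -> Spearman 1
  dc <- distance_calibration(sigma, sigma * 0.8 + 0.1)
  expect_equal(dc$spearman, 1)
  expect_false(dc$degenerate)
  # constant distances are flagged as degenerate
  dc0 <- distance_calibration(sigma, rep(0.4, 200))
  expect_true(dc0$degenerate)
  expect_true(is.na(dc0$spearman))
})
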