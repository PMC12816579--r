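# Three-part uncertainty-calibration suite: confidence-based (ECE),
# error-based (ENCE over entropy-based batches) and distance-based
# (Jaccard kNN) diagnostics, plus the ENCE batch-sensitivity sweep.

.curve_cor <- function(x, y) {
  if (length(x) < 2L || sd(x) == 0 || sd(y) == 0) {
    return(list(pearson = NA_real_, spearman = NA_real_, degenerate = TRUE))
  }
  list(pearson = cor(x, y, method = "pearson"),
       spearman = cor(x, y, method = "spearman"),
       degenerate = FALSE)
}

#' Confidence-based calibration and expected calibration error
#'
#' Compares nominal confidence levels with the observed fraction of
#' targets falling inside the corresponding prediction interval.
#' ECE is the mean over levels of |level - observed fraction|.
#'
#' @param y Numeric targets.
#' @param interval_fn Function of one confidence level returning a
#'   data.frame (or matrix) with `lower` and `upper` for every target.
#' @param levels Confidence grid (default 1%..99% in 1% steps).
#' @return A `calibration_curve` (kind `"confidence"`) with `points`
#'   (level, observed), `ece`, and Pearson/Spearman correlations.
#' @export
confidence_calibration <- function(y, interval_fn,
                                   levels = seq(0.01, 0.99, by = 0.01)) {
  y <- as.numeric(y)
  if (length(y) == 0L) stop("y is empty")
  stopifnot(is.function(interval_fn), length(levels) >= 1,
            all(levels > 0 & levels < 1))
  observed <- vapply(levels, function(p) {
    iv <- interval_fn(p)
    lo <- if (is.data.frame(iv)) iv$lower else iv[, "lower"]
    hi <- if (is.data.frame(iv)) iv$upper else iv[, "upper"]
    if (length(lo) == 1L) { lo <- rep(lo, length(y)); hi <- rep(hi, length(y)) }
    if (length(lo) != length(y)) {
      stop("interval_fn must return one interval per target")
    }
    mean(y >= lo & y <= hi)
  }, numeric(1))
  cc <- .curve_cor(levels, observed)
  structure(list(
    kind = "confidence",
    points = data.frame(level = levels, observed = observed),
    ece = mean(abs(levels - observed)),
    pearson = cc$pearson, spearman = cc$spearman,
    degenerate = cc$degenerate
  ), class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  s <- switch(x$kind,
    confidence = sprintf("ECE=%.4f", x$ece),
    error = sprintf("ENCE=%.4f", x$ence),
    distance = "")
  cat(sprintf("<calibration_curve> %s  %d points  %s  Spearman=%.3f\n",
              x$kind, nrow(x$points), s,
              ifelse(is.na(x$spearman), NaN, x$spearman)))
  invisible(x)
}

#' Sort items into uncertainty batches
#'
#' Items are sorted by predictive SD (ascending, ties kept in stable input
#' order) and split into `B` near-equal batches. The default number of
#' batches is the entropy-based optimum `round(sqrt(n))`. When n is not a
#' multiple of B, the remainder items are assigned to the
#' highest-uncertainty batches, so batch sizes differ by at most one.
#'
#' @param sigma Per-item predictive SD.
#' @param B Number of batches (default `round(sqrt(n))`).
#' @return An `uncertainty_batches` object: `n`, `B`, `order` (item
#'   indices sorted by sigma), `assignment` (batch id per input item),
#'   `sizes`.
#' @export
batch_by_uncertainty <- function(sigma, B = NULL) {
  sigma <- as.numeric(sigma)
  n <- length(sigma)
  if (n < 2L) stop("need at least 2 items")
  if (is.null(B)) B <- round(sqrt(n))
  B <- as.integer(B)
  if (B < 1L) stop("B must be >= 1")
  if (B > n) stop("more batches than items (B = ", B, ", n = ", n, ")")
  ord <- order(sigma)  # stable: ties keep input order
  base <- n %/% B
  sizes <- rep(base, B)
  rem <- n - base * B
  if (rem > 0) sizes[(B - rem + 1L):B] <- base + 1L
  batch_sorted <- rep(seq_len(B), times = sizes)
  assignment <- integer(n)
  assignment[ord] <- batch_sorted
  structure(list(n = n, B = B, order = ord, assignment = assignment,
                 sizes = sizes),
            class = "uncertainty_batches")
}

#' @export
print.uncertainty_batches <- function(x, ...) {
  cat(sprintf("<uncertainty_batches> n=%d, B=%d, sizes %d-%d\n",
              x$n, x$B, min(x$sizes), max(x$sizes)))
  invisible(x)
}

.batch_rmu_rmse <- function(y, y_hat, sigma, batches) {
  t(vapply(seq_len(batches$B), function(b) {
    idx <- which(batches$assignment == b)
    c(rmu = sqrt(mean(sigma[idx]^2)),
      rmse = sqrt(mean((y[idx] - y_hat[idx])^2)))
  }, numeric(2)))
}

#' Expected normalized calibration error (ENCE)
#'
#' Items are batched by increasing predictive SD; per batch the root mean
#' uncertainty RMU_b = sqrt(mean sigma^2) is compared with the observed
#' RMSE_b, and ENCE = mean_b |RMU_b - RMSE_b| / RMU_b. Well-calibrated
#' uncertainty gives RMU close to RMSE in every batch, hence small ENCE.
#'
#' @param y Targets.
#' @param y_hat Median/point predictions.
#' @param sigma Per-item predictive SD (>= 0).
#' @param B Number of batches (default `round(sqrt(n))`).
#' @return List with `ence` and `curve` (a `calibration_curve` of kind
#'   `"error"` whose points are (RMU_b, RMSE_b) in batch order).
#' @export
ence <- function(y, y_hat, sigma, B = NULL) {
  y <- as.numeric(y); y_hat <- as.numeric(y_hat); sigma <- as.numeric(sigma)
  if (length(y) != length(y_hat) || length(y) != length(sigma)) {
    stop("y, y_hat and sigma must have equal length")
  }
  if (any(sigma < 0)) stop("sigma must be nonnegative")
  batches <- batch_by_uncertainty(sigma, B)
  pts <- .batch_rmu_rmse(y, y_hat, sigma, batches)
  if (any(pts[, "rmu"] == 0)) {
    stop("batch with RMU = 0: normalized calibration error undefined")
  }
  val <- mean(abs(pts[, "rmu"] - pts[, "rmse"]) / pts[, "rmu"])
  cc <- .curve_cor(pts[, "rmu"], pts[, "rmse"])
  curve <- structure(list(
    kind = "error",
    points = data.frame(rmu = pts[, "rmu"], rmse = pts[, "rmse"]),
    ence = val, pearson = cc$pearson, spearman = cc$spearman,
    degenerate = cc$degenerate, batches = batches
  ), class = "calibration_curve")
  list(ence = val, curve = curve)
}

#' ENCE sensitivity to the number of batches
#'
#' Recomputes ENCE over a range of batch counts; ENCE is known to depend
#' on the batching granularity, so this sweep shows whether a reported
#' value is an artefact of one particular B.
#'
#' @inheritParams ence
#' @param B_range Integer batch counts (default 5..200).
#' @return data.frame with columns `B` and `ence`.
#' @export
ence_sensitivity <- function(y, y_hat, sigma, B_range = 5:200) {
  B_range <- as.integer(B_range)
  if (max(B_range) > length(y)) {
    stop("max(B_range) exceeds the number of items")
  }
  data.frame(B = B_range,
             ence = vapply(B_range,
                           function(b) ence(y, y_hat, sigma, B = b)$ence,
                           numeric(1)))
}

#' Mean Jaccard distance to the k nearest training fingerprints
#'
#' Jaccard (Tanimoto) distance d(a, b) = 1 - |a AND b| / |a OR b| between
#' binary fingerprints; a pair with empty union is defined as distance 0.
#' For each query the k smallest distances to the training set are
#' averaged -- the package's applicability-domain diagnostic.
#'
#' @param query_fp Binary fingerprint vector or matrix (queries in rows).
#' @param train_fps Binary fingerprint matrix (training chemicals in rows).
#' @param k Number of nearest neighbours (default 5).
#' @return Numeric vector (one mean distance in \[0, 1\] per query).
#' @export
knn_jaccard <- function(query_fp, train_fps, k = 5) {
  q <- if (is.null(dim(query_fp))) matrix(query_fp, nrow = 1)
       else as.matrix(query_fp)
  tr <- as.matrix(train_fps)
  if (inherits(query_fp, "feature_matrix")) q <- .fm_values(query_fp)
  if (inherits(train_fps, "feature_matrix")) tr <- .fm_values(train_fps)
  if (ncol(q) != ncol(tr)) stop("fingerprint widths differ")
  if (k > nrow(tr)) stop("k exceeds the number of training fingerprints")
  inter <- q %*% t(tr)
  uni <- outer(rowSums(q), rowSums(tr), "+") - inter
  d <- 1 - inter / uni
  d[uni == 0] <- 0
  unname(apply(d, 1, function(row) mean(sort(row, partial = k)[seq_len(k)])))
}

#' Distance-based calibration curve
#'
#' Batches items by increasing predictive SD (as [ence()]) and plots the
#' batch RMU against the batch mean structural dissimilarity (mean kNN
#' Jaccard distance). A positive association shows the model recognizes
#' elevated epistemic uncertainty for chemicals unlike its training data.
#'
#' @param sigma Per-item predictive SD.
#' @param distances Per-item mean kNN Jaccard distance
#'   (see [knn_jaccard()]).
#' @param B Number of batches (default `round(sqrt(n))`).
#' @return A `calibration_curve` of kind `"distance"` with points
#'   (RMU_b, mean distance_b) and Pearson/Spearman correlations
#'   (`degenerate = TRUE` flags constant inputs).
#' @export
distance_calibration <- function(sigma, distances, B = NULL) {
  sigma <- as.numeric(sigma); distances <- as.numeric(distances)
  if (length(sigma) != length(distances)) {
    stop("sigma and distances must have equal length")
  }
  batches <- batch_by_uncertainty(sigma, B)
  pts <- t(vapply(seq_len(batches$B), function(b) {
    idx <- which(batches$assignment == b)
    c(rmu = sqrt(mean(sigma[idx]^2)), dist = mean(distances[idx]))
  }, numeric(2)))
  cc <- .curve_cor(pts[, "rmu"], pts[, "dist"])
  structure(list(
    kind = "distance",
    points = data.frame(rmu = pts[, "rmu"], mean_jaccard = pts[, "dist"]),
    pearson = cc$pearson, spearman = cc$spearman,
    degenerate = cc$degenerate, batches = batches
  ), class = "calibration_curve")
}
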