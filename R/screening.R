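# Library screening: apply fitted models to a chemical library, map the
# chemical space in 2D and rank chemical classes by potency/uncertainty.

#' Predict a chemical library
#'
#' Featurizes a library of chemical records with the training pipeline,
#' predicts log10(mol/kg-d) intervals with a fitted uncertainty-aware
#' model, and back-converts medians and bounds to mg/kg-d for
#' presentation. Chemicals whose featurization fails are flagged
#' (`failed = TRUE`) and kept in the table with missing predictions; they
#' are never dropped silently. Non-standardized chemicals are flagged
#' `provisional` -- predict them only with models trained on an expanded
#' (standardized + non-standardized) dataset.
#'
#' @param model A trained `uacqr_model` or `bnn_posterior`.
#' @param pipeline The [feature_pipeline] fitted on the training data.
#' @param records Library chemical records (see [read_chemical_table()];
#'   run [standardize_records()] first so `mol_weight` is available).
#' @param endpoint `"rd"` or `"nc"` (annotation only).
#' @param level Confidence level (default 0.95).
#' @param embedding Precomputed embedding table when the pipeline kind is
#'   `learned_embedding`.
#' @param fp_bits,fp_radius Fingerprint settings matching the training
#'   featurization.
#' @param n_draws,seed BNN predictive draws and seed (BNN models only).
#' @return A `data.frame` (prediction table): `chem_id`, `endpoint`,
#'   `median`, `lower`, `upper` in mg/kg-d, `median_log10`, `width_log10`,
#'   `sigma`, `standardized`, `provisional`, `failed`, taxonomy columns.
#' @export
predict_library <- function(model, pipeline, records,
                            endpoint = c("rd", "nc"), level = 0.95,
                            embedding = NULL, fp_bits = 1024, fp_radius = 2,
                            n_draws = NULL, seed = 1) {
  endpoint <- match.arg(endpoint)
  stopifnot(inherits(pipeline, "feature_pipeline"), is.data.frame(records))
  n <- nrow(records)
  empty <- data.frame(
    chem_id = character(0), endpoint = character(0), median = numeric(0),
    lower = numeric(0), upper = numeric(0), median_log10 = numeric(0),
    width_log10 = numeric(0), sigma = numeric(0),
    standardized = logical(0), provisional = logical(0),
    failed = logical(0), superclass = character(0), class = character(0),
    subclass = character(0), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  ok <- rep(TRUE, n)
  feats <- vector("list", n)
  # Featurize row-wise so single failures flag rows instead of aborting.
  for (i in seq_len(n)) {
    feats[[i]] <- tryCatch(
      featurize(records[i, , drop = FALSE], kind = pipeline$kind,
                fp_bits = fp_bits, fp_radius = fp_radius,
                embedding = embedding),
      error = function(e) NULL)
    if (is.null(feats[[i]])) ok[i] <- FALSE
  }
  out <- data.frame(
    chem_id = as.character(records$chem_id), endpoint = endpoint,
    median = NA_real_, lower = NA_real_, upper = NA_real_,
    median_log10 = NA_real_, width_log10 = NA_real_, sigma = NA_real_,
    standardized = if ("standardized" %in% names(records))
      records$standardized else NA,
    provisional = if ("standardized" %in% names(records))
      !records$standardized else NA,
    failed = !ok,
    superclass = if ("superclass" %in% names(records))
      as.character(records$superclass) else NA_character_,
    class = if ("class" %in% names(records))
      as.character(records$class) else NA_character_,
    subclass = if ("subclass" %in% names(records))
      as.character(records$subclass) else NA_character_,
    stringsAsFactors = FALSE)
  if (any(ok)) {
    X <- do.call(rbind, feats[ok])
    X <- feature_matrix(X, pipeline$kind,
                        chem_ids = out$chem_id[ok],
                        feature_names = colnames(X))
    Xp <- apply_feature_pipeline(pipeline, X)
    iv <- if (inherits(model, "uacqr_model")) {
      predict(model, Xp, levels = level)
    } else if (inherits(model, "bnn_posterior")) {
      summarize_predictive(sample_predictions(model, Xp, n_draws = n_draws,
                                              seed = seed), level = level)
    } else stop("model must be a uacqr_model or bnn_posterior")
    mw <- if ("mol_weight" %in% names(records)) {
      records$mol_weight[ok]
    } else rep(NA_real_, sum(ok))
    out$median_log10[ok] <- iv$median
    out$width_log10[ok] <- iv$width
    out$sigma[ok] <- iv$sigma
    conv <- !is.na(mw)
    idx <- which(ok)[conv]
    out$median[idx] <- invert_pod_units(iv$median[conv], mw[conv])
    out$lower[idx] <- invert_pod_units(iv$lower[conv], mw[conv])
    out$upper[idx] <- invert_pod_units(iv$upper[conv], mw[conv])
  }
  out
}

# --- exact t-SNE ----------------------------------------------------------

# Per-point Gaussian bandwidths matched to a target perplexity by binary
# search on the precision beta.
.tsne_affinities <- function(D2, perplexity, tol = 1e-5, max_iter = 50) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; bmin <- -Inf; bmax <- Inf
    d <- D2[i, -i]
    for (iter in seq_len(max_iter)) {
      p <- exp(-d * beta)
      sp <- sum(p)
      if (sp == 0) { H <- 0; p <- p * 0 } else {
        H <- log(sp) + beta * sum(d * p) / sp
        p <- p / sp
      }
      if (abs(H - logU) < tol) break
      if (H > logU) { bmin <- beta; beta <- if (is.finite(bmax)) (beta + bmax) / 2 else beta * 2 }
      else { bmax <- beta; beta <- if (is.finite(bmin)) (beta + bmin) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' Embed fingerprints into a 2D chemical-space map
#'
#' Exact (quadratic-cost) t-distributed stochastic neighbour embedding of
#' binary fingerprints, using squared Jaccard distances as input
#' dissimilarities, so structurally similar chemicals land close together.
#' Deterministic given `seed`. Suitable for libraries up to a few thousand
#' chemicals; the cost grows with n^2.
#'
#' @param fps Binary fingerprint matrix (chemicals in rows) or
#'   [feature_matrix()].
#' @param seed Integer RNG seed.
#' @param perplexity Effective neighbourhood size (default 30; reduced
#'   automatically is an error -- supply a smaller value for tiny sets).
#' @param n_iter Gradient-descent iterations (default 400).
#' @param eta Learning rate (default 100).
#' @return n x 2 coordinate matrix (row names = chemical ids).
#' @export
embed_chemical_space <- function(fps, seed = 1, perplexity = 30,
                                 n_iter = 400, eta = 100) {
  X <- if (inherits(fps, "feature_matrix")) .fm_values(fps) else as.matrix(fps)
  n <- nrow(X)
  if (n < 5L) stop("need at least 5 chemicals")
  if (n - 1 < 3 * perplexity) {
    stop("perplexity too large for n = ", n,
         " (need n - 1 >= 3 * perplexity)")
  }
  inter <- X %*% t(X)
  rs <- rowSums(X)
  uni <- outer(rs, rs, "+") - inter
  D <- 1 - inter / uni
  D[uni == 0] <- 0
  diag(D) <- 0
  P <- .tsne_affinities(D^2, perplexity)
  set.seed(seed)
  Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
  G <- matrix(0, n, 2)     # update (momentum) buffer
  gains <- matrix(1, n, 2)
  exaggeration <- 4
  for (iter in seq_len(n_iter)) {
    Pe <- if (iter <= 100) P * exaggeration else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * Y %*% t(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (iter <= 250) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
    gains <- pmax(gains, 0.01)
    G <- mom * G - eta * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  rownames(Y) <- rownames(X)
  colnames(Y) <- c("tsne1", "tsne2")
  Y
}

#' Rank chemical classes by predicted potency
#'
#' Groups a prediction table by each chemical's lowest available taxonomy
#' level (subclass, then class, then superclass), drops classes with fewer
#' than `min_size` members, and ranks the remaining classes by ascending
#' median predicted POD (most potent first). The high-potency fraction of
#' a class is the percentage of its members whose median prediction falls
#' within the library-wide `top_pct`% most potent (lowest) medians for the
#' endpoint.
#'
#' @param table Prediction table from [predict_library()] (one endpoint).
#' @param min_size Minimum class size (default 30).
#' @param top_pct Potency percentile defining "high potency" (default 1,
#'   i.e. the top 1%).
#' @return data.frame ranked by potency: `class_name`, `level`, `n_chems`,
#'   `median_pod` (mg/kg-d), `high_potency_fraction` (%),
#'   `median_ci_width` (log10 units).
#' @export
rank_classes <- function(table, min_size = 30, top_pct = 1.0) {
  stopifnot(is.data.frame(table), min_size >= 1, top_pct > 0, top_pct < 100)
  if (length(unique(table$endpoint)) > 1L) {
    stop("rank_classes expects a single-endpoint prediction table")
  }
  usable <- !is.na(table$median)
  tab <- table[usable, , drop = FALSE]
  has <- function(v) !is.na(v) & nzchar(v)
  lvl <- ifelse(has(tab$subclass), "subclass",
                ifelse(has(tab$class), "class",
                       ifelse(has(tab$superclass), "superclass",
                              NA_character_)))
  nm <- ifelse(lvl == "subclass", tab$subclass,
               ifelse(lvl == "class", tab$class, tab$superclass))
  keep <- !is.na(lvl)
  if (!any(keep)) stop("no chemicals with taxonomy labels")
  tab <- tab[keep, , drop = FALSE]
  lvl <- lvl[keep]; nm <- nm[keep]
  threshold <- quantile(tab$median, probs = top_pct / 100, type = 7,
                        names = FALSE)
  key <- paste(lvl, nm, sep = "\r")
  rows <- lapply(split(seq_len(nrow(tab)), key), function(idx) {
    data.frame(
      class_name = nm[idx[1]], level = lvl[idx[1]],
      n_chems = length(idx),
      median_pod = median(tab$median[idx]),
      high_potency_fraction = 100 * mean(tab$median[idx] <= threshold),
      median_ci_width = median(tab$width_log10[idx]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$n_chems >= min_size, , drop = FALSE]
  out <- out[order(out$median_pod), , drop = FALSE]
  rownames(out) <- NULL
  out
}
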