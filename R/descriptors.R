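# Molecular descriptor families and leakage-free preprocessing pipelines.

.DESCRIPTOR_KINDS <- c("maccs_keys", "morgan_fp", "physchem_2d",
                       "learned_embedding")
.BINARY_KINDS <- c("maccs_keys", "morgan_fp")

#' Construct a feature matrix
#'
#' A feature matrix is a plain numeric matrix with chemical identifiers as
#' row names, unique feature names as column names, and a descriptor-family
#' tag. Binary families (`maccs_keys`, `morgan_fp`) must contain only 0/1.
#'
#' @param values Numeric matrix (chemicals in rows).
#' @param kind Descriptor family, one of `maccs_keys`, `morgan_fp`,
#'   `physchem_2d`, `learned_embedding`.
#' @param chem_ids Row identifiers (default: existing row names).
#' @param feature_names Column names (default: existing column names).
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, kind, chem_ids = rownames(values),
                           feature_names = colnames(values)) {
  kind <- match.arg(kind, .DESCRIPTOR_KINDS)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(chem_ids)) chem_ids <- sprintf("x%d", seq_len(nrow(values)))
  if (length(chem_ids) != nrow(values)) {
    stop("chem_ids must match the number of rows")
  }
  if (is.null(feature_names) || length(feature_names) != ncol(values)) {
    stop("feature_names must match the number of columns")
  }
  if (anyDuplicated(feature_names)) stop("duplicate feature names")
  if (kind %in% .BINARY_KINDS && !all(values %in% c(0, 1))) {
    stop("binary descriptor families must contain only 0/1 values")
  }
  rownames(values) <- as.character(chem_ids)
  colnames(values) <- feature_names
  attr(values, "kind") <- kind
  class(values) <- c("feature_matrix", class(values))
  values
}

#' Subset a feature matrix
#'
#' Standard matrix subsetting that keeps the `feature_matrix` class and
#' descriptor-kind tag whenever the result is still a matrix.
#'
#' @param x A [feature_matrix()].
#' @param i,j Row/column indices.
#' @param ... Unused.
#' @param drop Drop dimensions as for matrices (default TRUE).
#' @return A `feature_matrix` (or vector when a dimension is dropped).
#' @export
`[.feature_matrix` <- function(x, i, j, ..., drop) {
  kind <- attr(x, "kind")
  y <- .fm_values(x)
  n_idx_args <- nargs() - !missing(drop)
  if (n_idx_args <= 2L) {           # x[i]: plain vector extraction
    return(if (missing(i)) y else y[i])
  }
  if (missing(drop)) drop <- TRUE
  out <- if (missing(i) && missing(j)) y[, , drop = drop]
         else if (missing(i)) y[, j, drop = drop]
         else if (missing(j)) y[i, , drop = drop]
         else y[i, j, drop = drop]
  if (is.matrix(out)) {
    attr(out, "kind") <- kind
    class(out) <- c("feature_matrix", class(out))
  }
  out
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> kind=%s  %d chemicals x %d features\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  invisible(x)
}

# Strip the feature_matrix class for plain matrix math.
.fm_values <- function(m) {
  cls <- class(m)
  class(m) <- setdiff(cls, "feature_matrix")
  attr(m, "kind") <- NULL
  m
}

.fm_kind <- function(m) {
  k <- attr(m, "kind")
  if (is.null(k)) stop("not a feature_matrix (missing descriptor kind)")
  k
}

# Parse a vector of SMILES into one SDFset with the given ids, failing with
# a message that lists the offending chem_ids.
.parse_sdfset <- function(smiles, ids) {
  parsed <- lapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NULL)
    tryCatch(suppressWarnings(ChemmineR::smiles2sdf(s)),
             error = function(e) NULL)
  })
  bad <- vapply(parsed, is.null, logical(1))
  if (any(bad)) {
    stop("unparseable structures for chem_id(s): ",
         paste(ids[bad], collapse = ", "))
  }
  sdf <- suppressWarnings(Reduce(c, parsed))  # silence duplicate-cid notes
  suppressWarnings(ChemmineR::cid(sdf) <- as.character(ids))
  sdf
}

# Binary fingerprint matrix from a ChemmineR FPset.
.fpset_matrix <- function(fp) {
  m <- methods::slot(fp, "fpma")
  storage.mode(m) <- "double"
  m
}

# Fold a wide binary fingerprint to `bits` columns by OR-ing congruent bits.
.fold_fp <- function(m, bits) {
  if (ncol(m) <= bits) return(m)
  grp <- ((seq_len(ncol(m)) - 1L) %% bits) + 1L
  folded <- t(rowsum(t(m), group = grp))
  folded <- (folded > 0) * 1
  folded[, order(as.integer(colnames(folded))), drop = FALSE]
}

# 2D physicochemical descriptor block: OpenBabel properties plus simple
# constitutional counts derived from the connection table.
.physchem_block <- function(sdf) {
  p <- suppressWarnings(ChemmineR::propOB(sdf))
  num <- c("MW", "logP", "TPSA", "MR", "HBA1", "HBA2", "HBD", "nF")
  base <- as.matrix(p[, num, drop = FALSE])
  counts <- t(vapply(seq_along(ChemmineR::cid(sdf)), function(i) {
    mol <- sdf[[i]]
    ab <- ChemmineR::atomblock(mol)
    el <- sub("_.*$", "", rownames(ab))
    bb <- tryCatch(ChemmineR::bondblock(mol), error = function(e) NULL)
    nb <- if (is.null(bb)) 0 else nrow(bb)
    heavy <- sum(el != "H")
    c(heavy_atoms = heavy,
      n_C = sum(el == "C"), n_N = sum(el == "N"), n_O = sum(el == "O"),
      n_S = sum(el == "S"), n_P = sum(el == "P"),
      n_halogen = sum(el %in% c("F", "Cl", "Br", "I")),
      n_bonds = nb,
      ring_rank = max(0, nb - length(el) + 1),  # cyclomatic ring count
      hetero_frac = if (heavy > 0) sum(!el %in% c("C", "H")) / heavy else 0)
  }, numeric(10)))
  cbind(base, counts)
}

#' Compute molecular descriptors for chemical records
#'
#' Builds one of the four descriptor families from the records' structures
#' (`smiles_std` when standardized, otherwise `smiles_raw`):
#' * `morgan_fp` -- circular (Morgan-type/ECFP) binary fingerprint with the
#'   requested radius, folded to `fp_bits` bits,
#' * `maccs_keys` -- MACCS structural key fingerprint,
#' * `physchem_2d` -- continuous 2D physicochemical descriptors (molecular
#'   weight, logP, TPSA, molar refractivity, H-bond counts, constitutional
#'   counts, cyclomatic ring count),
#' * `learned_embedding` -- rows looked up from a precomputed embedding
#'   table keyed by `chem_id` (such embeddings come from pretrained neural
#'   models and are ingested, never computed here).
#'
#' Featurization is deterministic and canonicalization-invariant: two
#' SMILES spellings of the same molecule yield identical rows.
#'
#' @param records Chemical record data.frame with `chem_id` and SMILES.
#' @param kind Descriptor family.
#' @param fp_bits Fingerprint width for `morgan_fp` (default 1024).
#' @param fp_radius Circular fingerprint radius for `morgan_fp` (default 2).
#' @param embedding For `learned_embedding`: data.frame whose first column
#'   is `chem_id` and remaining columns are embedding dimensions.
#' @return A [feature_matrix()].
#' @export
featurize <- function(records, kind = c("morgan_fp", "maccs_keys",
                                        "physchem_2d", "learned_embedding"),
                      fp_bits = 1024, fp_radius = 2, embedding = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(records), "chem_id" %in% names(records))
  ids <- as.character(records$chem_id)
  if (kind == "learned_embedding") {
    if (is.null(embedding)) {
      stop("learned_embedding requires a precomputed embedding table")
    }
    key <- as.character(embedding[[1]])
    hit <- match(ids, key)
    if (anyNA(hit)) {
      stop("missing embedding rows for chem_id(s): ",
           paste(ids[is.na(hit)], collapse = ", "))
    }
    vals <- as.matrix(embedding[hit, -1, drop = FALSE])
    return(feature_matrix(vals, kind, chem_ids = ids,
                          feature_names = colnames(embedding)[-1]))
  }
  smi <- ifelse(!is.na(records$smiles_std) & nzchar(records$smiles_std),
                records$smiles_std, records$smiles_raw)
  sdf <- .parse_sdfset(smi, ids)
  if (kind == "morgan_fp") {
    stopifnot(fp_bits >= 8, fp_radius %in% 0:5)
    fp <- .fpset_matrix(ChemmineR::fingerprintOB(sdf,
                                                 paste0("ECFP", 2 * fp_radius)))
    vals <- .fold_fp(fp, fp_bits)
    colnames(vals) <- sprintf("bit_%04d", seq_len(ncol(vals)))
  } else if (kind == "maccs_keys") {
    vals <- .fpset_matrix(ChemmineR::fingerprintOB(sdf, "MACCS"))
    colnames(vals) <- sprintf("maccs_%03d", seq_len(ncol(vals)))
  } else {
    vals <- .physchem_block(sdf)
  }
  feature_matrix(vals, kind, chem_ids = ids, feature_names = colnames(vals))
}

# Greedy correlation filter: walk features in input order and drop the
# later member of any pair whose |Pearson r| exceeds the threshold with an
# earlier kept feature. Deterministic for a given input.
.corr_filter <- function(values, threshold) {
  d <- ncol(values)
  if (d <= 1L) return(rep(TRUE, d))
  C <- suppressWarnings(abs(cor(values)))
  C[is.na(C)] <- 0
  keep <- rep(TRUE, d)
  for (j in 2:d) {
    earlier <- which(keep[seq_len(j - 1L)])
    if (length(earlier) && any(C[j, earlier] > threshold)) keep[j] <- FALSE
  }
  keep
}

# Yeo-Johnson forward transform with a fixed lambda.
.yeo_johnson <- function(x, lambda) {
  out <- numeric(length(x))
  pos <- !is.na(x) & x >= 0
  neg <- !is.na(x) & x < 0
  if (abs(lambda) < 1e-8) {
    out[pos] <- log1p(x[pos])
  } else {
    out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  }
  l2 <- 2 - lambda
  if (abs(l2) < 1e-8) {
    out[neg] <- -log1p(-x[neg])
  } else {
    out[neg] <- -(((-x[neg] + 1)^l2 - 1) / l2)
  }
  out[is.na(x)] <- NA_real_
  out
}

#' Fit a leakage-free feature preprocessing pipeline
#'
#' Learns all preprocessing parameters from a training feature matrix so
#' they can later be applied, frozen, to held-out data
#' ([apply_feature_pipeline()]):
#' * `maccs_keys` and `physchem_2d` (the knowledge-based families): features
#'   correlated above `corr_threshold` (|Pearson r|) are greedily removed --
#'   features are walked in input order and the later member of an
#'   offending pair is dropped;
#' * `physchem_2d` additionally: zero-variance features are dropped with a
#'   warning, per-feature Yeo-Johnson transforms are fitted, and the
#'   transformed features are centred and scaled to zero mean / unit
#'   variance on the training rows;
#' * `morgan_fp` and `learned_embedding` (the structural representations):
#'   identity pipeline -- these are valid representations only as a whole,
#'   so no feature is removed or rescaled.
#'
#' @param train Training [feature_matrix()] with at least 2 rows.
#' @param corr_threshold Pearson correlation threshold above which one of a
#'   feature pair is dropped (default 0.9).
#' @return An object of class `feature_pipeline`.
#' @export
fit_feature_pipeline <- function(train, corr_threshold = 0.9) {
  kind <- .fm_kind(train)
  vals <- .fm_values(train)
  if (nrow(vals) < 2L) stop("need at least 2 training rows")
  feats <- colnames(vals)
  pipe <- list(kind = kind, feature_names = feats, kept = feats,
               lambda = NULL, center = NULL, scale = NULL,
               corr_threshold = corr_threshold)
  if (kind %in% c("morgan_fp", "learned_embedding")) {
    class(pipe) <- "feature_pipeline"
    return(pipe)
  }
  work <- vals
  if (kind == "physchem_2d") {
    sds <- apply(work, 2, sd)
    if (any(sds == 0)) {
      warning("dropping zero-variance physchem feature(s): ",
              paste(colnames(work)[sds == 0], collapse = ", "))
      work <- work[, sds > 0, drop = FALSE]
    }
  }
  keep <- .corr_filter(work, corr_threshold)
  if (!any(keep)) stop("correlation filter removed every feature")
  work <- work[, keep, drop = FALSE]
  pipe$kept <- colnames(work)
  if (kind == "physchem_2d") {
    pp <- caret::preProcess(as.data.frame(work), method = "YeoJohnson")
    lambda <- rep(1, ncol(work))
    names(lambda) <- colnames(work)
    if (!is.null(pp$yj)) lambda[names(pp$yj)] <- as.numeric(pp$yj)
    trans <- vapply(seq_len(ncol(work)),
                    function(j) .yeo_johnson(work[, j], lambda[j]),
                    numeric(nrow(work)))
    trans <- matrix(trans, nrow = nrow(work))
    ctr <- colMeans(trans)
    scl <- apply(trans, 2, sd)
    if (any(scl <= 0)) {
      drop2 <- scl <= 0
      warning("dropping feature(s) degenerate after transform: ",
              paste(pipe$kept[drop2], collapse = ", "))
      pipe$kept <- pipe$kept[!drop2]
      lambda <- lambda[!drop2]; ctr <- ctr[!drop2]; scl <- scl[!drop2]
    }
    pipe$lambda <- lambda
    pipe$center <- stats::setNames(ctr, pipe$kept)
    pipe$scale <- stats::setNames(scl, pipe$kept)
  }
  class(pipe) <- "feature_pipeline"
  pipe
}

#' Apply a fitted feature pipeline to new data
#'
#' Applies the training-fitted feature mask and (for `physchem_2d`) the
#' Yeo-Johnson/centering/scaling parameters to a feature matrix of the same
#' descriptor family. The pipeline itself is never modified, so repeated
#' application to different test sets cannot leak information.
#'
#' @param pipeline A `feature_pipeline` from [fit_feature_pipeline()].
#' @param m A [feature_matrix()] containing all original features.
#' @return The transformed [feature_matrix()].
#' @export
apply_feature_pipeline <- function(pipeline, m) {
  stopifnot(inherits(pipeline, "feature_pipeline"))
  if (.fm_kind(m) != pipeline$kind) {
    stop("descriptor kind mismatch: pipeline is ", pipeline$kind,
         ", data is ", .fm_kind(m))
  }
  vals <- .fm_values(m)
  missing <- setdiff(pipeline$kept, colnames(vals))
  if (length(missing)) {
    stop("feature-name mismatch; missing: ", paste(missing, collapse = ", "))
  }
  out <- vals[, pipeline$kept, drop = FALSE]
  if (pipeline$kind == "physchem_2d" && !is.null(pipeline$lambda)) {
    for (j in seq_len(ncol(out))) {
      nm <- colnames(out)[j]
      out[, j] <- (.yeo_johnson(out[, j], pipeline$lambda[nm]) -
                     pipeline$center[nm]) / pipeline$scale[nm]
    }
  }
  feature_matrix(out, pipeline$kind, chem_ids = rownames(vals),
                 feature_names = colnames(out))
}

#' @export
print.feature_pipeline <- function(x, ...) {
  cat(sprintf("<feature_pipeline> kind=%s  kept %d/%d features%s\n",
              x$kind, length(x$kept), length(x$feature_names),
              if (!is.null(x$lambda)) " (Yeo-Johnson + standardized)" else ""))
  invisible(x)
}
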