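# Chemical table ingestion, structure standardization and POD unit handling.
#
# A "chemical record" is one row of a data.frame with the canonical columns
#   chem_id, cas, smiles_raw, smiles_std, standardized, exclusion_reason,
#   mol_weight, pod_rd, pod_nc, n_rd, n_nc, superclass, class, subclass
# PODs are stored in mg/kg-d on input and modelled internally as
# log10(mol/kg-d).

.CANONICAL_COLS <- c(
  "chem_id", "cas", "smiles_raw", "smiles_std", "standardized",
  "exclusion_reason", "mol_weight", "pod_rd", "pod_nc", "n_rd", "n_nc",
  "superclass", "class", "subclass"
)

# Elements allowed in a standardized (organic) structure. Anything else is
# treated as a metal/metalloid and triggers exclusion.
.ALLOWED_ELEMENTS <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S",
                       "Cl", "Se", "Br", "I")

#' Read a chemical table from CSV/TSV
#'
#' Reads a delimited chemical table and maps its columns onto the canonical
#' record schema used throughout the package. Only `chem_id` and `smiles`
#' are required; all other columns are optional and yield `NA` fields when
#' absent. Row order is preserved.
#'
#' @param path Path to a CSV (`.csv`) or TSV (`.tsv`/`.txt`) file.
#' @param schema Named list mapping canonical names (`chem_id`, `smiles`,
#'   `cas`, `pod_rd`, `pod_nc`, `n_rd`, `n_nc`, `mol_weight`, `superclass`,
#'   `class`, `subclass`) to the column names used in the file. Canonical
#'   names not listed are looked up under their own name.
#' @return A data.frame of chemical records (one per input row).
#' @export
read_chemical_table <- function(path, schema = list()) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE)
  optional <- c("cas", "pod_rd", "pod_nc", "n_rd", "n_nc", "mol_weight",
                "superclass", "class", "subclass")
  col_of <- function(canon) {
    nm <- if (!is.null(schema[[canon]])) schema[[canon]] else canon
    if (nm %in% names(raw)) raw[[nm]] else NULL
  }
  for (req in c("chem_id", "smiles")) {
    nm <- if (!is.null(schema[[req]])) schema[[req]] else req
    if (!nm %in% names(raw)) {
      stop("required column missing from ", path, ": '", nm,
           "' (schema field '", req, "')")
    }
  }
  n <- nrow(raw)
  if (n == 0L) warning("empty chemical table: ", path)
  rec <- data.frame(
    chem_id = as.character(col_of("chem_id")),
    cas = if (is.null(v <- col_of("cas"))) rep(NA_character_, n) else as.character(v),
    smiles_raw = as.character(col_of("smiles")),
    smiles_std = rep(NA_character_, n),
    standardized = rep(FALSE, n),
    exclusion_reason = rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
  for (nm in c("pod_rd", "pod_nc", "mol_weight")) {
    v <- col_of(nm)
    rec[[nm]] <- if (is.null(v)) rep(NA_real_, n) else as.numeric(v)
  }
  for (nm in c("n_rd", "n_nc")) {
    v <- col_of(nm)
    rec[[nm]] <- if (is.null(v)) rep(NA_integer_, n) else as.integer(v)
  }
  for (nm in c("superclass", "class", "subclass")) {
    v <- col_of(nm)
    rec[[nm]] <- if (is.null(v)) rep(NA_character_, n) else {
      v <- as.character(v); v[!is.na(v) & !nzchar(v)] <- NA_character_; v
    }
  }
  rec[rec$smiles_raw == "" & !is.na(rec$smiles_raw), "smiles_raw"] <- NA_character_
  rec$mol_weight <- ifelse(!is.na(rec$mol_weight) & rec$mol_weight <= 0,
                           NA_real_, rec$mol_weight)
  rec[, .CANONICAL_COLS]
}

# Parse one single-component SMILES with OpenBabel. Returns NULL when the
# string cannot be interpreted, otherwise element symbols, molecular weight
# (implicit hydrogens included) and the canonical SMILES.
.ob_parse <- function(smi) {
  if (is.na(smi) || !nzchar(smi)) return(NULL)
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smi)),
    error = function(e) NULL)
  if (is.null(sdf) || length(sdf) == 0L) return(NULL)
  suppressWarnings(ChemmineR::cid(sdf) <- "m")
  ab <- tryCatch(ChemmineR::atomblock(sdf[[1]]), error = function(e) NULL)
  if (is.null(ab) || nrow(ab) == 0L) return(NULL)
  elems <- sub("_.*$", "", rownames(ab))
  mw <- tryCatch(suppressWarnings(ChemmineR::propOB(sdf)$MW[1]),
                 error = function(e) NA_real_)
  can <- tryCatch(
    sub("[ \t\r\n].*$", "", ChemmineOB::convertFormat("SMI", "CAN", smi)),
    error = function(e) NA_character_)
  if (is.na(can) || !nzchar(can)) can <- smi
  list(elements = elems, mw = as.numeric(mw), cansmi = can)
}

#' Standardize chemical structures
#'
#' Applies the package's standardization rule set to raw SMILES strings:
#' multi-component inputs (salts, solvates) keep the largest organic
#' component; compounds without carbon are excluded as `inorganic`;
#' structures whose retained component contains a metal atom are excluded
#' as `organometallic`; retained components heavier than `max_mw` g/mol
#' are excluded as `too_large`; strings OpenBabel cannot interpret are
#' excluded as `unparseable`. Retained structures are canonicalized.
#' Exclusions are encoded in the result, never raised as errors, so that
#' expanded-dataset workflows can keep non-standardized chemicals.
#'
#' The largest organic component is chosen by heavy-atom count, with ties
#' broken by molecular weight and then by canonical-SMILES lexicographic
#' order, making salt stripping deterministic.
#'
#' @param smiles Character vector of SMILES strings.
#' @param max_mw Molecular-weight cutoff in g/mol (default 1000; strictly
#'   greater values are excluded).
#' @return A data.frame with one row per input: `smiles_raw`, `smiles_std`,
#'   `standardized`, `exclusion_reason` (one of `inorganic`,
#'   `organometallic`, `too_large`, `unparseable`, or `NA`), `mol_weight`.
#' @export
standardize_structure <- function(smiles, max_mw = 1000) {
  stopifnot(is.character(smiles))
  one <- function(smi) {
    fail <- function(reason) list(std = NA_character_, reason = reason,
                                  mw = NA_real_)
    if (is.na(smi) || !nzchar(trimws(smi))) return(fail("unparseable"))
    comps <- strsplit(trimws(smi), ".", fixed = TRUE)[[1]]
    comps <- comps[nzchar(comps)]
    parsed <- lapply(comps, .ob_parse)
    ok <- !vapply(parsed, is.null, logical(1))
    if (!any(ok)) return(fail("unparseable"))
    parsed <- parsed[ok]
    has_c <- vapply(parsed, function(p) "C" %in% p$elements, logical(1))
    if (!any(has_c)) return(fail("inorganic"))
    org <- parsed[has_c]
    heavy <- vapply(org, function(p) sum(p$elements != "H"), numeric(1))
    mws <- vapply(org, function(p) ifelse(is.na(p$mw), -Inf, p$mw), numeric(1))
    cans <- vapply(org, function(p) p$cansmi, character(1))
    pick <- order(-heavy, -mws, cans)[1L]
    keep <- org[[pick]]
    if (any(!keep$elements %in% .ALLOWED_ELEMENTS)) return(fail("organometallic"))
    if (!is.na(keep$mw) && keep$mw > max_mw) return(fail("too_large"))
    list(std = keep$cansmi, reason = NA_character_, mw = keep$mw)
  }
  res <- lapply(smiles, one)
  data.frame(
    smiles_raw = smiles,
    smiles_std = vapply(res, `[[`, character(1), "std"),
    standardized = vapply(res, function(r) is.na(r$reason), logical(1)),
    exclusion_reason = vapply(res, `[[`, character(1), "reason"),
    mol_weight = vapply(res, `[[`, numeric(1), "mw"),
    stringsAsFactors = FALSE
  )
}

#' Standardize the structures of a chemical record table
#'
#' Convenience wrapper running [standardize_structure()] on a record table
#' and filling the `smiles_std`, `standardized`, `exclusion_reason` and
#' `mol_weight` columns (existing molecular weights are kept only where
#' standardization could not compute one).
#'
#' @param records Chemical record data.frame (see [read_chemical_table()]).
#' @param max_mw Molecular-weight cutoff in g/mol.
#' @return The record table with standardization columns filled.
#' @export
standardize_records <- function(records, max_mw = 1000) {
  stopifnot(is.data.frame(records), "smiles_raw" %in% names(records))
  out <- standardize_structure(records$smiles_raw, max_mw = max_mw)
  records$smiles_std <- out$smiles_std
  records$standardized <- out$standardized
  records$exclusion_reason <- out$exclusion_reason
  records$mol_weight <- ifelse(is.na(out$mol_weight),
                               records$mol_weight, out$mol_weight)
  records
}

#' Convert a POD from mg/kg-d to log10(mol/kg-d)
#'
#' `log10((pod / 1000) / mol_weight)`: divide by 1000 to convert mg to g,
#' then by the molecular weight (g/mol) to obtain moles.
#'
#' @param pod_mgkgd POD in mg/kg-d (positive).
#' @param mol_weight Molecular weight in g/mol (positive).
#' @return POD in log10(mol/kg-d).
#' @seealso [invert_pod_units()] for the inverse mapping.
#' @export
convert_pod_units <- function(pod_mgkgd, mol_weight) {
  if (any(!is.na(pod_mgkgd) & pod_mgkgd <= 0)) {
    stop("pod_mgkgd must be strictly positive")
  }
  if (any(!is.na(mol_weight) & mol_weight <= 0)) {
    stop("mol_weight must be strictly positive")
  }
  log10((pod_mgkgd / 1000) / mol_weight)
}

#' Convert a POD from log10(mol/kg-d) back to mg/kg-d
#'
#' @param pod_log10 POD in log10(mol/kg-d).
#' @param mol_weight Molecular weight in g/mol (positive).
#' @return POD in mg/kg-d.
#' @export
invert_pod_units <- function(pod_log10, mol_weight) {
  if (any(!is.na(mol_weight) & mol_weight <= 0)) {
    stop("mol_weight must be strictly positive")
  }
  (10^pod_log10) * mol_weight * 1000
}

#' Derive a POD from a toxic equivalency factor
#'
#' Toxic equivalency factors (TEFs) express the potency of a dioxin-like
#' compound relative to an index compound (2,3,7,8-TCDD). A higher relative
#' potency implies a lower POD, so the compound's POD is the index
#' compound's POD divided by the TEF.
#'
#' @param pod_reference POD of the index compound in mg/kg-d (positive).
#' @param tef Dimensionless relative potency (positive).
#' @return POD of the target compound in mg/kg-d.
#' @export
pod_from_tef <- function(pod_reference, tef) {
  if (any(!is.na(pod_reference) & pod_reference <= 0)) {
    stop("pod_reference must be strictly positive")
  }
  if (any(!is.na(tef) & tef <= 0)) stop("tef must be strictly positive")
  pod_reference / tef
}

#' Filter chemical records by experimental support
#'
#' Keeps records whose POD for the given endpoint is present and backed by
#' at least `min_points` underlying experimental data points. Order is
#' preserved; the output is always a subsequence of the input.
#'
#' @param records Chemical record data.frame.
#' @param endpoint `"rd"` (reproductive/developmental) or `"nc"` (general
#'   non-cancer).
#' @param min_points Minimum number of supporting experimental data points
#'   (default 4).
#' @return The filtered record table.
#' @export
filter_by_support <- function(records, endpoint = c("rd", "nc"),
                              min_points = 4) {
  endpoint <- match.arg(endpoint)
  stopifnot(is.data.frame(records), min_points >= 1)
  pod_col <- paste0("pod_", endpoint)
  n_col <- paste0("n_", endpoint)
  stopifnot(all(c(pod_col, n_col) %in% names(records)))
  if (nrow(records) == 0L) return(records)
  keep <- !is.na(records[[pod_col]]) &
    !is.na(records[[n_col]]) & records[[n_col]] >= min_points
  records[keep, , drop = FALSE]
}

#' Write a chemical record table to CSV
#'
#' @param records Chemical record data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_chemical_table <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}
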