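# Drug views 1, 3 and 4: 2D chemical descriptors, MACCS structural keys and
# the binary drug-target vector.  (View 2, the molecular-graph embedding,
# lives in graph_views.R.)

#' Construct a drug view matrix
#'
#' @param view_name One of `descriptor`, `graph`, `fingerprint`, `target`.
#' @param drug_ids Character vector of drug ids (row order).
#' @param matrix Numeric drugs x features matrix.
#' @param feature_names Column names (defaults to `colnames(matrix)`).
#' @param raw Optional pre-normalization matrix (continuous views only).
#' @param norm Optional `tanh_norm` object used to produce `matrix`.
#' @param vocabulary Optional feature vocabulary (target view).
#' @return A list of class `drug_view_matrix`.
#' @export
drug_view_matrix <- function(view_name, drug_ids, matrix,
                             feature_names = colnames(matrix),
                             raw = NULL, norm = NULL, vocabulary = NULL) {
  view_name <- match.arg(view_name, DRUG_VIEW_NAMES)
  matrix <- as.matrix(matrix)
  rownames(matrix) <- drug_ids
  structure(list(view_name = view_name, drug_ids = as.character(drug_ids),
                 matrix = matrix, feature_names = as.character(feature_names),
                 raw = raw, norm = norm, vocabulary = vocabulary),
            class = "drug_view_matrix")
}

#' Compute the chemical-descriptor drug view
#'
#' Evaluates the chemistry engine's full 2D descriptor collection for every
#' drug, then drops (column-wise) every descriptor that is non-numeric for
#' any drug -- missing, failed, infinite or boolean-typed values -- or has
#' zero variance across the drug set, and tanh-normalizes the survivors.
#' No cell-wise imputation is performed.
#'
#' @param drugs List of drug records.
#' @param c Tanh-norm scale constant.
#' @return A `drug_view_matrix` with view name `"descriptor"`.  The
#'   pre-filter descriptor count is stored in the `n_raw_descriptors`
#'   attribute of the matrix.
#' @export
compute_descriptor_view <- function(drugs, c = 0.01) {
  ids <- drug_ids(drugs)
  res <- chem_batch("descriptors", drug_smiles(drugs))
  chem_stop_on_failure(res, drug_smiles(drugs), ids)
  desc_names <- res[[1L]]$descriptor_names
  raw <- t(vapply(res, function(r) {
    vapply(r$values, function(v) if (is.null(v)) NA_real_ else as.numeric(v),
           numeric(1))
  }, numeric(length(desc_names))))
  dimnames(raw) <- list(ids, desc_names)
  numeric_ok <- !apply(raw, 2L, anyNA)
  variance_ok <- numeric_ok &
    apply(raw, 2L, function(x) !anyNA(x) && stats::var(x) > 0)
  keep <- which(variance_ok)
  if (!length(keep)) stop("no informative descriptors across the drug set")
  kept <- raw[, keep, drop = FALSE]
  params <- tanh_norm_fit(kept, c = c)
  out <- drug_view_matrix("descriptor", ids, tanh_norm_apply(params, kept),
                          raw = kept, norm = params)
  attr(out, "n_raw_descriptors") <- ncol(raw)
  out
}

#' Number of raw descriptors the chemistry engine computes
#'
#' The pre-filter width of the descriptor view, i.e. the size of the
#' engine's 2D descriptor catalogue.
#'
#' @return Integer descriptor count.
#' @export
n_raw_descriptors <- function() {
  res <- chem_batch("descriptors", "C")[[1L]]
  length(res$descriptor_names)
}

#' Compute the MACCS fingerprint drug view
#'
#' The 166 MACCS structural keys per drug, each 0/1 for absence/presence of
#' the corresponding substructure pattern.  Binary views are not
#' tanh-normalized.
#'
#' @param drugs List of drug records.
#' @return A `drug_view_matrix` with view name `"fingerprint"` and exactly
#'   166 columns.
#' @export
compute_fingerprint_view <- function(drugs) {
  ids <- drug_ids(drugs)
  res <- chem_batch("maccs", drug_smiles(drugs))
  chem_stop_on_failure(res, drug_smiles(drugs), ids)
  m <- t(vapply(res, function(r) vapply(r$bits, as.numeric, numeric(1)),
                numeric(166L)))
  dimnames(m) <- list(ids, sprintf("maccs%03d", 1:166))
  drug_view_matrix("fingerprint", ids, m)
}

#' Compute the drug-target drug view
#'
#' The target vocabulary is the sorted union of all drugs' target ids; each
#' drug is encoded as a binary membership vector over that vocabulary.  The
#' vocabulary is stored on the result so prediction-time drugs can be encoded
#' against it with [encode_targets()].
#'
#' @param drugs List of drug records; at least one must have a nonempty
#'   target set.
#' @return A `drug_view_matrix` with view name `"target"`.
#' @export
compute_target_view <- function(drugs) {
  vocab <- sort(unique(unlist(lapply(drugs, `[[`, "target_ids"))))
  if (!length(vocab)) stop("empty target vocabulary: no drug has targets")
  encode_targets(drugs, vocab)
}

#' Encode drugs against a fixed target vocabulary
#'
#' @param drugs List of drug records.
#' @param vocabulary Character vector of target ids (order preserved).
#' @return A `drug_view_matrix` with view name `"target"`; drugs with no
#'   targets in the vocabulary get all-zero rows.
#' @export
encode_targets <- function(drugs, vocabulary) {
  ids <- drug_ids(drugs)
  m <- t(vapply(drugs, function(d) as.numeric(vocabulary %in% d$target_ids),
                numeric(length(vocabulary))))
  dimnames(m) <- list(ids, vocabulary)
  drug_view_matrix("target", ids, m, vocabulary = vocabulary)
}

#' Compute all four drug views
#'
#' @param drugs List of drug records.
#' @param graph_cfg A [graph_view_config()].
#' @param c Tanh-norm scale constant for the continuous views.
#' @return Named list of four `drug_view_matrix` objects
#'   (`descriptor`, `graph`, `fingerprint`, `target`).
#' @export
compute_drug_views <- function(drugs, graph_cfg = graph_view_config(), c = 0.01) {
  list(descriptor = compute_descriptor_view(drugs, c = c),
       graph = compute_graph_view(drugs, cfg = graph_cfg, c = c),
       fingerprint = compute_fingerprint_view(drugs),
       target = compute_target_view(drugs))
}
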