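# Domain types and shared plumbing: table ingestion, tanh normalization,
# synergy labeling and drug-pair-disjoint fold construction.

SYNERGY_CLASSES <- c("antagonistic", "additive", "synergistic")

CELL_VIEW_NAMES <- c("expression", "copy_number", "mutation", "proteomics")
DRUG_VIEW_NAMES <- c("descriptor", "graph", "fingerprint", "target")

# Delimiter-autodetected CSV/TSV reader; header row required.
read_delim_auto <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first)) stop("empty file: ", path)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "", quote = "\"")
}

#' Read a drug table
#'
#' Reads a delimited text file with header columns `drug_id`, `smiles` and
#' `targets` (semicolon-separated target identifiers, possibly empty) and
#' returns one drug record per row.  Every SMILES is validated against the
#' chemistry engine; duplicate drug ids are an error.
#'
#' @param path Path to a CSV or TSV file (delimiter autodetected).
#' @return A list of drug records, each a list with elements `drug_id`
#'   (string), `smiles` (string) and `target_ids` (character vector, possibly
#'   empty).
#' @export
read_drug_table <- function(path) {
  df <- read_delim_auto(path)
  need <- c("drug_id", "smiles", "targets")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("drug table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  ids <- as.character(df$drug_id)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate drug_id: ", paste(unique(dup), collapse = ", "))
  parsed <- chem_batch("graphs", as.character(df$smiles))
  bad <- which(vapply(parsed, function(r) !isTRUE(r$ok), logical(1)))
  if (length(bad)) {
    stop("unparseable SMILES in row ", bad[1], " (drug_id ",
         sQuote(ids[bad[1]]), "): ", sQuote(df$smiles[bad[1]]))
  }
  lapply(seq_len(nrow(df)), function(i) {
    raw <- df$targets[i]
    tg <- if (is.na(raw) || !nzchar(raw)) character(0) else
      unique(strsplit(as.character(raw), ";", fixed = TRUE)[[1]])
    tg <- tg[nzchar(tg)]
    drug_record(ids[i], as.character(df$smiles[i]), tg)
  })
}

#' Construct a drug record
#'
#' @param drug_id Unique drug identifier.
#' @param smiles SMILES line notation for the drug.
#' @param target_ids Character vector of target identifiers (a set; de-duplicated).
#' @return A list with class `drug_record`.
#' @export
drug_record <- function(drug_id, smiles, target_ids = character(0)) {
  structure(list(drug_id = as.character(drug_id),
                 smiles = as.character(smiles),
                 target_ids = unique(as.character(target_ids))),
            class = "drug_record")
}

drug_ids <- function(drugs) vapply(drugs, `[[`, character(1), "drug_id")
drug_smiles <- function(drugs) vapply(drugs, `[[`, character(1), "smiles")

#' Read an omics matrix
#'
#' Reads a delimited text file whose first column holds cell-line ids and
#' whose remaining columns are numeric features (genes or proteins).
#'
#' @param path Path to a CSV/TSV file.
#' @param view_name Name of the omics view (one of `expression`,
#'   `copy_number`, `mutation`, `proteomics`); stored on the result.
#' @return A list with elements `cell_ids`, `feature_names` and `matrix`
#'   (cells x features), class `cell_view_matrix`.
#' @export
read_omics_matrix <- function(path, view_name) {
  df <- read_delim_auto(path)
  if (ncol(df) < 2L) stop("omics matrix needs a cell-id column plus >=1 feature")
  cell_ids <- as.character(df[[1L]])
  dup <- cell_ids[duplicated(cell_ids)]
  if (length(dup)) stop("duplicate cell id: ", paste(unique(dup), collapse = ", "))
  feat <- df[-1L]
  for (j in seq_along(feat)) {
    if (!is.numeric(feat[[j]])) {
      stop("non-numeric entries in column ", sQuote(names(feat)[j]))
    }
  }
  m <- as.matrix(feat)
  if (anyNA(m)) stop("NA cells in omics matrix ", path)
  cell_view_matrix(view_name, cell_ids, m, colnames(m))
}

#' Construct a cell-line view matrix
#'
#' @param view_name View label.
#' @param cell_ids Character vector of cell-line ids (rows).
#' @param matrix Numeric cells x features matrix.
#' @param feature_names Column names.
#' @return A list with class `cell_view_matrix`.
#' @export
cell_view_matrix <- function(view_name, cell_ids, matrix, feature_names = colnames(matrix)) {
  matrix <- as.matrix(matrix)
  rownames(matrix) <- cell_ids
  colnames(matrix) <- feature_names
  structure(list(view_name = view_name, cell_ids = as.character(cell_ids),
                 matrix = matrix, feature_names = as.character(feature_names)),
            class = "cell_view_matrix")
}

#' Read a drug-combination table
#'
#' Columns `drug_a`, `drug_b`, `cell_id`, `loewe_score`.  The three-class
#' synergy label is derived from the score via [label_from_score()].
#'
#' @param path Path to a CSV/TSV file.
#' @return A data.frame with columns drug_a, drug_b, cell_id, loewe_score,
#'   label (factor).
#' @export
read_combination_table <- function(path) {
  df <- read_delim_auto(path)
  need <- c("drug_a", "drug_b", "cell_id", "loewe_score")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("combination table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  combination_table(df$drug_a, df$drug_b, df$cell_id, df$loewe_score)
}

#' Construct a combination table
#'
#' @param drug_a,drug_b Drug identifiers (must differ row-wise).
#' @param cell_id Cell-line identifiers.
#' @param loewe_score Loewe additivity synergy scores.
#' @return data.frame with derived `label` column.
#' @export
combination_table <- function(drug_a, drug_b, cell_id, loewe_score) {
  drug_a <- as.character(drug_a); drug_b <- as.character(drug_b)
  if (any(drug_a == drug_b)) stop("drug_a == drug_b in combination table")
  data.frame(drug_a = drug_a, drug_b = drug_b,
             cell_id = as.character(cell_id),
             loewe_score = as.numeric(loewe_score),
             label = label_from_score(as.numeric(loewe_score)),
             stringsAsFactors = FALSE)
}

#' Fit tanh normalization parameters
#'
#' The tanh estimator maps each feature into (0,1) via
#' `0.5 * (tanh(c * (x - mean) / sd) + 1)` with per-feature mean and sd
#' estimated from the training rows only.  Features with zero sd map to 0.5.
#'
#' @param matrix Numeric training matrix (rows x features).
#' @param c Scale constant of the tanh estimator (default 0.01).
#' @return An object of class `tanh_norm` with per-feature `mean`, `sd`, `c`.
#' @export
tanh_norm_fit <- function(matrix, c = 0.01) {
  matrix <- as.matrix(matrix)
  if (!is.numeric(matrix)) stop("tanh_norm_fit needs a numeric matrix")
  mu <- colMeans(matrix)
  sdv <- apply(matrix, 2L, stats::sd)
  if (nrow(matrix) == 1L) sdv[] <- 0  # single row: no spread information
  structure(list(mean = mu, sd = sdv, c = c, n_features = ncol(matrix)),
            class = "tanh_norm")
}

#' Apply tanh normalization
#'
#' @param params A `tanh_norm` object from [tanh_norm_fit()].
#' @param matrix Matrix with the same feature count as the fit.
#' @return Matrix of the same shape with entries in (0,1); constant (sd = 0)
#'   features map identically to 0.5.
#' @export
tanh_norm_apply <- function(params, matrix) {
  if (!inherits(params, "tanh_norm")) {
    stop("apply before fit: `params` must be a tanh_norm object")
  }
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != params$n_features) {
    stop("feature-count mismatch: fit on ", params$n_features,
         " features, applied to ", ncol(matrix))
  }
  z <- sweep(matrix, 2L, params$mean, "-")
  sdv <- params$sd
  pos <- sdv > 0
  z[, pos] <- sweep(z[, pos, drop = FALSE], 2L, sdv[pos], "/")
  z[, !pos] <- 0
  out <- 0.5 * (tanh(params$c * z) + 1)
  dimnames(out) <- dimnames(matrix)
  out
}

#' Synergy class label from a Loewe score
#'
#' Scores below 0 are antagonistic, scores above 30 synergistic, and the
#' closed interval \[0, 30\] additive.
#'
#' @param loewe_score Numeric vector of finite Loewe additivity scores.
#' @return Factor with levels antagonistic, additive, synergistic.
#' @export
label_from_score <- function(loewe_score) {
  if (!is.numeric(loewe_score) || any(!is.finite(loewe_score))) {
    stop("loewe_score must be finite")
  }
  lab <- ifelse(loewe_score < 0, "antagonistic",
                ifelse(loewe_score > 30, "synergistic", "additive"))
  factor(lab, levels = SYNERGY_CLASSES)
}

# Canonical key of an unordered drug pair.
pair_key <- function(drug_a, drug_b) {
  paste(pmin(drug_a, drug_b), pmax(drug_a, drug_b), sep = "||")
}

# Evaluate `expr` under a private RNG stream, restoring the caller's state.
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Derive a child seed (< 2^31) from a master seed and stream indices.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) s <- (s * 69069 + as.double(k) * 104729 + 12345) %% 2147483647
  as.integer(s)
}

#' Drug-pair-disjoint fold assignment
#'
#' Unordered drug pairs are shuffled with the given seed and dealt round-robin
#' into `n_folds` folds, so every combination of a given pair (across all cell
#' lines) lands in exactly one fold.
#'
#' @param combinations A combination table (see [combination_table()]).
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed driving the shuffle.
#' @return An object of class `fold_assignment`: list with `n_folds` and
#'   `pair_to_fold` (named integer vector, folds in `0:(n_folds-1)`).
#' @export
make_pair_disjoint_folds <- function(combinations, n_folds = 5L, seed = 1L) {
  if (n_folds < 2L) stop("n_folds must be >= 2")
  keys <- sort(unique(pair_key(combinations$drug_a, combinations$drug_b)))
  if (length(keys) < n_folds) {
    stop("fewer distinct drug pairs (", length(keys), ") than folds (", n_folds, ")")
  }
  perm <- with_local_seed(seed, sample.int(length(keys)))
  shuffled <- keys[perm]
  folds <- (seq_along(shuffled) - 1L) %% n_folds
  structure(list(n_folds = as.integer(n_folds),
                 pair_to_fold = stats::setNames(as.integer(folds), shuffled)),
            class = "fold_assignment")
}

#' Fold index of each combination row
#'
#' @param assignment A `fold_assignment`.
#' @param combinations A combination table.
#' @return Integer vector of fold indices in `0:(n_folds-1)`.
#' @export
fold_of <- function(assignment, combinations) {
  stopifnot(inherits(assignment, "fold_assignment"))
  keys <- pair_key(combinations$drug_a, combinations$drug_b)
  f <- assignment$pair_to_fold[keys]
  if (anyNA(f)) stop("combination with a drug pair absent from the fold assignment")
  unname(f)
}

#' Export a fold assignment as a data.frame
#'
#' @param assignment A `fold_assignment`.
#' @return data.frame with columns `pair` and `fold`, suitable for CSV export.
#' @export
fold_assignment_table <- function(assignment) {
  stopifnot(inherits(assignment, "fold_assignment"))
  data.frame(pair = names(assignment$pair_to_fold),
             fold = unname(assignment$pair_to_fold),
             stringsAsFactors = FALSE)
}
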