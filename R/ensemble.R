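# Ensemble orchestration: the 4x4 view pairings, soft-voting averages, and
# drug-pair-disjoint five-fold cross-validation with per-fold refitting of
# all preprocessing (tanh normalization, VAE compressors).

#' Enumerate the drug-view x cell-view pairings
#'
#' Cartesian product in deterministic order: drug view major
#' (descriptor, graph, fingerprint, target), cell view minor (expression,
#' copy_number, mutation, proteomics); 16 pairings by default, fewer under
#' ablation subsets.
#'
#' @param drug_views Subset of drug view names.
#' @param cell_views Subset of cell view names.
#' @return data.frame with columns `drug_view`, `cell_view`.
#' @export
enumerate_view_pairs <- function(drug_views = DRUG_VIEW_NAMES,
                                 cell_views = CELL_VIEW_NAMES) {
  drug_views <- match.arg(drug_views, DRUG_VIEW_NAMES, several.ok = TRUE)
  cell_views <- match.arg(cell_views, CELL_VIEW_NAMES, several.ok = TRUE)
  out <- expand.grid(cell_view = cell_views, drug_view = drug_views,
                     stringsAsFactors = FALSE)[, c("drug_view", "cell_view")]
  rownames(out) <- NULL
  out
}

#' Average per-pairing predictions into the ensemble prediction
#'
#' Soft voting: the final score is the arithmetic mean of the member scores
#' and the final class probabilities the mean of the member probability
#' vectors (still on the simplex); the final label is the argmax of the
#' averaged probabilities.
#'
#' @param predictions Nonempty list of member predictions, each a list with
#'   `score` (length-n numeric) and `class_probs` (n x 3 matrix).
#' @return List of class `ensemble_prediction`: `member_scores` (n x m),
#'   `member_probs` (list of m matrices), `final_score`, `final_class_probs`,
#'   `final_label`.
#' @export
ensemble_average <- function(predictions) {
  if (!length(predictions)) stop("empty prediction list")
  scores <- vapply(predictions, function(p) as.numeric(p$score),
                   numeric(length(predictions[[1L]]$score)))
  if (!is.matrix(scores)) scores <- matrix(scores, nrow = 1L)
  probs <- lapply(predictions, `[[`, "class_probs")
  final_probs <- Reduce(`+`, probs) / length(probs)
  colnames(final_probs) <- SYNERGY_CLASSES
  structure(list(
    member_scores = scores,
    member_probs = probs,
    final_score = rowMeans(scores),
    final_class_probs = final_probs,
    final_label = factor(SYNERGY_CLASSES[max.col(final_probs, ties.method = "first")],
                         levels = SYNERGY_CLASSES)
  ), class = "ensemble_prediction")
}

#' Pipeline configuration
#'
#' Bundles the network configuration with the preprocessing and
#' cross-validation settings.  Defaults mirror the global reference setting;
#' fixture-scale runs override the sizes and epoch counts.
#'
#' @param model A [model_config()].
#' @param graph A [graph_view_config()].
#' @param n_folds Number of drug-pair-disjoint folds.
#' @param mode `"ensemble"` (16 multi-task models, default), `"concat"` (all
#'   views concatenated into one multi-task model) or `"single_task"` (two
#'   single-output models per pairing, then ensembled).
#' @param drug_views,cell_views View subsets (ablations).
#' @param vae_latent,vae_hidden,vae_beta,vae_epochs,vae_batch,vae_lr Per-view
#'   VAE compression settings.
#' @param tanh_c Tanh-norm scale constant.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(model = model_config(),
                            graph = graph_view_config(),
                            n_folds = 5L,
                            mode = c("ensemble", "concat", "single_task"),
                            drug_views = DRUG_VIEW_NAMES,
                            cell_views = CELL_VIEW_NAMES,
                            vae_latent = 256L, vae_hidden = c(1024L, 512L),
                            vae_beta = 1, vae_epochs = 200L,
                            vae_batch = 32L, vae_lr = 1e-3,
                            tanh_c = 0.01) {
  structure(list(model = model, graph = graph, n_folds = as.integer(n_folds),
                 mode = match.arg(mode),
                 drug_views = drug_views, cell_views = cell_views,
                 vae_latent = as.integer(vae_latent), vae_hidden = vae_hidden,
                 vae_beta = vae_beta, vae_epochs = as.integer(vae_epochs),
                 vae_batch = as.integer(vae_batch), vae_lr = vae_lr,
                 tanh_c = tanh_c),
            class = "pipeline_config")
}

# Fold-local drug views: refit tanh normalization of the continuous views on
# the training drugs only; binary views pass through.
fold_drug_views <- function(raw_views, train_drugs, tanh_c) {
  lapply(raw_views, function(v) {
    if (is.null(v$raw)) return(v)
    params <- tanh_norm_fit(v$raw[train_drugs, , drop = FALSE], c = tanh_c)
    drug_view_matrix(v$view_name, v$drug_ids, tanh_norm_apply(params, v$raw),
                     raw = v$raw, norm = params, vocabulary = v$vocabulary)
  })
}

subset_cells <- function(view, cells) {
  cell_view_matrix(view$view_name, cells,
                   view$matrix[cells, , drop = FALSE], view$feature_names)
}

concat_drug_views <- function(views, ids) {
  m <- do.call(cbind, lapply(views, function(v) {
    stopifnot(identical(v$drug_ids, ids))
    v$matrix
  }))
  drug_view_matrix(views[[1L]]$view_name, ids, m)
}

concat_cell_views <- function(views) {
  ids <- views[[1L]]$cell_ids
  m <- do.call(cbind, lapply(seq_along(views), function(i) {
    v <- views[[i]]
    stopifnot(identical(v$cell_ids, ids))
    mm <- v$matrix
    colnames(mm) <- paste0(v$view_name, "_", colnames(mm))
    mm
  }))
  cell_view_matrix(views[[1L]]$view_name, ids, m)
}

#' Drug-pair-disjoint cross-validation of the full ensemble
#'
#' For each fold: refits the continuous drug-view normalizations and the four
#' VAE compressors on training drugs/cells only, trains the per-pairing
#' models on the training folds, ensemble-predicts the test fold, and scores
#' it.  All seeds derive from `seed` via a fixed counter scheme, so identical
#' inputs give identical reports.
#'
#' @param drugs List of drug records.
#' @param omics Named list of the four raw `cell_view_matrix` objects
#'   (`expression`, `copy_number`, `mutation`, `proteomics`); the mutation
#'   view is binarized internally.
#' @param combos Combination table covering drugs/cells above.
#' @param config A [pipeline_config()].
#' @param seed Master integer seed.
#' @return List of class `cv_result`: `fold_reports`, `summary`
#'   (see [summarize_folds()]), `assignment`, and `predictions` (one row per
#'   combination with its fold, ensemble score, class probabilities and
#'   label).
#' @export
run_cross_validation <- function(drugs, omics, combos,
                                 config = pipeline_config(), seed = 1L) {
  stopifnot(inherits(config, "pipeline_config"))
  assignment <- make_pair_disjoint_folds(combos, config$n_folds,
                                         seed = derive_seed(seed, 0L))
  fold_idx <- fold_of(assignment, combos)
  if (length(unique(fold_idx)) < config$n_folds) {
    stop("a fold has no test combinations; use fewer folds or more pairs")
  }

  raw_drug_views <- with_local_seed(derive_seed(seed, 1L),
                                    compute_drug_views(drugs, config$graph,
                                                       c = config$tanh_c))
  raw_drug_views <- raw_drug_views[config$drug_views]
  omics <- omics[config$cell_views]
  omics <- lapply(omics, function(v) {
    if (identical(v$view_name, "mutation")) binarize_mutations(v) else v
  })

  pairs_tbl <- enumerate_view_pairs(config$drug_views, config$cell_views)
  reports <- vector("list", config$n_folds)
  pred_rows <- vector("list", config$n_folds)

  for (f in seq_len(config$n_folds) - 1L) {
    train <- combos[fold_idx != f, , drop = FALSE]
    test <- combos[fold_idx == f, , drop = FALSE]
    train_drugs <- unique(c(train$drug_a, train$drug_b))
    train_cells <- unique(train$cell_id)

    dviews <- fold_drug_views(raw_drug_views, train_drugs, config$tanh_c)
    cviews <- lapply(seq_along(omics), function(i) {
      v <- omics[[i]]
      comp <- fit_view_vae(subset_cells(v, train_cells),
                           latent_dim = config$vae_latent,
                           hidden = config$vae_hidden,
                           beta = config$vae_beta,
                           epochs = config$vae_epochs,
                           batch_size = config$vae_batch,
                           lr = config$vae_lr,
                           seed = derive_seed(seed, 2L, f, i),
                           tanh_c = config$tanh_c)
      compress_view(comp, v)
    })
    names(cviews) <- names(omics)

    if (config$mode == "concat") {
      dv <- concat_drug_views(dviews, drug_ids(drugs))
      cv <- concat_cell_views(cviews)
      mod <- train_view_pair_model(train, dv, cv, config$model,
                                   seed = derive_seed(seed, 3L, f, 0L))
      member_preds <- list(predict(mod, test, dv, cv))
    } else {
      member_preds <- lapply(seq_len(nrow(pairs_tbl)), function(p) {
        dv <- dviews[[pairs_tbl$drug_view[p]]]
        cv <- cviews[[pairs_tbl$cell_view[p]]]
        s <- derive_seed(seed, 3L, f, p)
        if (config$mode == "ensemble") {
          mod <- train_view_pair_model(train, dv, cv, config$model, seed = s)
          predict(mod, test, dv, cv)
        } else {  # single_task: one score model + one label model
          mr <- train_single_task_model(train, dv, cv, "regression",
                                        config$model, seed = s)
          mc <- train_single_task_model(train, dv, cv, "classification",
                                        config$model,
                                        seed = derive_seed(seed, 4L, f, p))
          c(predict(mr, test, dv, cv), predict(mc, test, dv, cv))
        }
      })
    }

    ens <- ensemble_average(member_preds)
    reports[[f + 1L]] <- fold_report(ens$final_score, ens$final_class_probs, test)
    pred_rows[[f + 1L]] <- data.frame(
      test[, c("drug_a", "drug_b", "cell_id", "loewe_score")],
      label = test$label, fold = f,
      pred_score = ens$final_score,
      p_antagonistic = ens$final_class_probs[, 1L],
      p_additive = ens$final_class_probs[, 2L],
      p_synergistic = ens$final_class_probs[, 3L],
      pred_label = ens$final_label,
      stringsAsFactors = FALSE
    )
  }

  structure(list(fold_reports = reports,
                 summary = summarize_folds(reports),
                 assignment = assignment,
                 predictions = do.call(rbind, pred_rows),
                 config = config, seed = seed),
            class = "cv_result")
}

#' Summary rows of a cross-validation result
#'
#' @param result A `cv_result`.
#' @return data.frame with one row per fold plus a mean and an sd row,
#'   shaped like a published results table.
#' @export
cv_summary_table <- function(result) {
  stopifnot(inherits(result, "cv_result"))
  metrics <- c("mse", "rmse", "pearson", "accuracy", "precision", "kappa",
               "roc_auc", "pr_auc")
  rows <- lapply(seq_along(result$fold_reports), function(i) {
    r <- result$fold_reports[[i]]
    data.frame(fold = i - 1L, t(vapply(metrics, function(m) as.numeric(r[[m]]),
                                       numeric(1))))
  })
  df <- do.call(rbind, rows)
  mean_row <- data.frame(fold = "mean", t(vapply(metrics, function(m)
    result$summary$mean[[m]], numeric(1))))
  sd_row <- data.frame(fold = "sd", t(vapply(metrics, function(m)
    result$summary$sd[[m]], numeric(1))))
  names(mean_row) <- names(df); names(sd_row) <- names(df)
  rbind(transform(df, fold = as.character(fold)), mean_row, sd_row)
}
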