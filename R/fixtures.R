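# Seeded synthetic fixtures: a pool of real small-molecule SMILES, rank-3
# latent-factor omics, and combinations whose Loewe score is a planted
# function of drug-target overlap, per-drug effects and the first cell
# latent factor, calibrated to roughly 20% antagonistic / 60% additive /
# 20% synergistic under the class thresholds.

# Pre-validated small-molecule SMILES (aspirin, caffeine, ibuprofen, common
# solvents and heterocycles); every entry parses in smiles_to_graph().
SMILES_POOL <- c(
  ethanol        = "CCO",
  benzene        = "c1ccccc1",
  aspirin        = "CC(=O)OC1=CC=CC=C1C(=O)O",
  caffeine       = "CN1C=NC2=C1C(=O)N(C(=O)N2C)C",
  ibuprofen      = "CC(C)CC1=CC=C(C=C1)C(C)C(=O)O",
  paracetamol    = "CC(=O)NC1=CC=C(C=C1)O",
  nicotine       = "CN1CCCC1C2=CC=CN=C2",
  toluene        = "Cc1ccccc1",
  phenol         = "Oc1ccccc1",
  aniline        = "Nc1ccccc1",
  pyridine       = "c1ccncc1",
  furan          = "c1ccoc1",
  thiophene      = "c1ccsc1",
  imidazole      = "c1c[nH]cn1",
  indole         = "c1ccc2[nH]ccc2c1",
  naphthalene    = "c1ccc2ccccc2c1",
  acetone        = "CC(=O)C",
  acetic_acid    = "CC(=O)O",
  glycine        = "NCC(=O)O",
  urea           = "NC(=O)N",
  cyclohexane    = "C1CCCCC1",
  ethyl_acetate  = "CCOC(=O)C",
  dmso           = "CS(=O)C",
  chloroform     = "ClC(Cl)Cl",
  isopropanol    = "CC(C)O",
  butanol        = "CCCCO",
  styrene        = "C=Cc1ccccc1",
  benzaldehyde   = "O=Cc1ccccc1",
  benzoic_acid   = "OC(=O)c1ccccc1",
  anisole        = "COc1ccccc1"
)

#' Fixture specification
#'
#' @param n_drugs Number of drugs (>= 4, at most the SMILES pool size).
#' @param n_cells Number of cell lines (>= 3).
#' @param genes Named integer vector: feature count per omics view.
#' @param noise_sd Noise level; scales both the omics measurement noise and
#'   (x 20, Loewe units) the score noise.  Zero gives scores that are a
#'   deterministic function of the planted features.
#' @param n_targets Size of the target vocabulary drugs draw from.
#' @param seed Master seed; the whole fixture regenerates bit-identically
#'   from (spec, seed).
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(n_drugs = 12L, n_cells = 8L,
                         genes = c(expression = 300L, copy_number = 240L,
                                   mutation = 180L, proteomics = 150L),
                         noise_sd = 0.1, n_targets = 20L, seed = 7L) {
  stopifnot(n_drugs >= 4L, n_cells >= 3L,
            setequal(names(genes), CELL_VIEW_NAMES))
  if (n_drugs > length(SMILES_POOL)) {
    stop("n_drugs exceeds the SMILES pool size (", length(SMILES_POOL), ")")
  }
  structure(list(n_drugs = as.integer(n_drugs), n_cells = as.integer(n_cells),
                 genes = genes, noise_sd = noise_sd,
                 n_targets = as.integer(n_targets), seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate fixture drugs
#'
#' Samples SMILES without replacement from the embedded pool and assigns each
#' drug 1-4 targets from a fixed vocabulary.
#'
#' @param spec A [fixture_spec()].
#' @return List of drug records.
#' @export
generate_drugs <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  vocab <- sprintf("T%02d", seq_len(spec$n_targets))
  with_local_seed(derive_seed(spec$seed, 11L), {
    smiles <- sample(unname(SMILES_POOL), spec$n_drugs)
    lapply(seq_len(spec$n_drugs), function(i) {
      k <- sample(1:4, 1L)
      drug_record(sprintf("D%02d", i), smiles[i], sample(vocab, k))
    })
  })
}

#' Generate fixture omics
#'
#' Expression, copy-number and proteomics views are Gaussian with a shared
#' rank-3 per-cell latent structure plus measurement noise of sd
#' `spec$noise_sd`; the mutation view is iid Bernoulli(0.1).  The latent
#' factor matrix is attached as the `"latent"` attribute (its first column
#' drives the planted synergy signal).
#'
#' @param spec A [fixture_spec()].
#' @return Named list of four raw `cell_view_matrix` objects.
#' @export
generate_omics <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  cells <- sprintf("CL%02d", seq_len(spec$n_cells))
  with_local_seed(derive_seed(spec$seed, 12L), {
    U <- matrix(stats::rnorm(spec$n_cells * 3L), spec$n_cells, 3L)
    views <- lapply(CELL_VIEW_NAMES, function(vn) {
      p <- spec$genes[[vn]]
      if (vn == "mutation") {
        m <- matrix(stats::rbinom(spec$n_cells * p, 1L, 0.1), spec$n_cells, p)
      } else {
        L <- matrix(stats::rnorm(3L * p), 3L, p)
        m <- U %*% L + spec$noise_sd * matrix(stats::rnorm(spec$n_cells * p),
                                              spec$n_cells, p)
      }
      colnames(m) <- sprintf("%s_g%04d", vn, seq_len(p))
      cell_view_matrix(vn, cells, m)
    })
    names(views) <- CELL_VIEW_NAMES
    attr(views, "latent") <- structure(U, dimnames = list(cells, NULL))
    views
  })
}

# Planted-signal coefficients (variance budget in the methods vignette):
# per-drug effects sd 10 (x2 drugs), cell-factor weight 9, target-overlap
# weight 6, overlap-by-cell interaction 5.  The raw planted score is then
# affinely standardized to mean 15 and sd 17.8, which puts the 0 / 30 class
# thresholds at -/+ 0.84 sd and so yields roughly 20% antagonistic / 60%
# additive / 20% synergistic regardless of the sampled drug/cell effects.
FIXTURE_SCORE_COEF <- list(drug_sd = 10, cell = 9, overlap = 6,
                           interaction = 5, noise_scale = 20,
                           target_mean = 15, target_sd = 17.8)

#' Generate fixture combinations
#'
#' Every unordered drug pair on every cell line.  The planted Loewe score is
#' `e_A + e_B + w_ov * ov + w_int * ov * u1 + w_cell * u1`, where `ov` is the
#' drugs' target-set overlap, `e_A`, `e_B` are per-drug effects and `u1` the
#' first cell latent factor; the scores are affinely standardized to mean 15
#' and sd 17.8 (calibrating the three-class split to roughly 20/60/20) and
#' Gaussian noise with sd `noise_scale * spec$noise_sd` is added.  Symmetric
#' in drug order by construction.
#'
#' @param drugs Drug records from [generate_drugs()].
#' @param cells Omics list from [generate_omics()] (supplies cell ids and
#'   latent factors).
#' @param spec A [fixture_spec()].
#' @return A combination table (see [combination_table()]).
#' @export
generate_combinations <- function(drugs, cells, spec) {
  stopifnot(inherits(spec, "fixture_spec"), length(drugs) >= 2L)
  U <- attr(cells, "latent")
  if (is.null(U)) stop("`cells` must be the generate_omics() result (latent attribute)")
  ids <- drug_ids(drugs)
  cf <- FIXTURE_SCORE_COEF
  with_local_seed(derive_seed(spec$seed, 13L), {
    eff <- stats::setNames(stats::rnorm(length(ids), sd = cf$drug_sd), ids)
    pairs <- utils::combn(ids, 2L)
    grid <- expand.grid(pair = seq_len(ncol(pairs)),
                        cell = rownames(U), stringsAsFactors = FALSE)
    a <- pairs[1L, grid$pair]; b <- pairs[2L, grid$pair]
    tg <- lapply(drugs, `[[`, "target_ids"); names(tg) <- ids
    ov <- mapply(function(x, y) length(intersect(tg[[x]], tg[[y]])), a, b)
    u1 <- U[grid$cell, 1L]
    raw <- eff[a] + eff[b] + cf$overlap * ov +
      cf$interaction * ov * u1 + cf$cell * u1
    score <- cf$target_mean + cf$target_sd * (raw - mean(raw)) / stats::sd(raw) +
      stats::rnorm(length(a), sd = cf$noise_scale * spec$noise_sd)
    combination_table(a, b, grid$cell, unname(score))
  })
}

#' Generate a complete fixture
#'
#' @param spec A [fixture_spec()].
#' @return List of class `mvs_fixture` with `drugs`, `omics`, `combos` and
#'   the spec.
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  drugs <- generate_drugs(spec)
  omics <- generate_omics(spec)
  combos <- generate_combinations(drugs, omics, spec)
  structure(list(drugs = drugs, omics = omics, combos = combos, spec = spec),
            class = "mvs_fixture")
}

#' Write a fixture to CSV files
#'
#' Writes `drugs.csv`, one `omics_<view>.csv` per view, and `combos.csv` in
#' the exact schemas the readers in this package consume.
#'
#' @param fixture An `mvs_fixture`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "mvs_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  drugs_df <- data.frame(
    drug_id = drug_ids(fixture$drugs),
    smiles = drug_smiles(fixture$drugs),
    targets = vapply(fixture$drugs, function(d)
      paste(d$target_ids, collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(drugs_df, file.path(dir, "drugs.csv"), row.names = FALSE,
                   quote = FALSE)
  for (vn in names(fixture$omics)) {
    v <- fixture$omics[[vn]]
    df <- data.frame(cell_id = v$cell_ids, v$matrix, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.csv(df, file.path(dir, paste0("omics_", vn, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(fixture$combos[, c("drug_a", "drug_b", "cell_id", "loewe_score")],
                   file.path(dir, "combos.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Fixture-scale pipeline configuration
#'
#' The reduced problem sizes used for fixture-scale runs (tests, examples,
#' the acceptance script): encoders and heads \[64, 32, 16\], 4 attention
#' heads over 16-wide tokens, AdamW at 3e-3 with batch 128 for 120 epochs,
#' and 16-dimensional VAE compression (hidden width 64, 60 epochs).  The
#' architecture is the reference one; only widths and schedules are scaled
#' down so a full five-fold, sixteen-model run fits in minutes on one CPU.
#'
#' @param epochs Multi-task training epochs per member model.
#' @param n_folds Number of drug-pair-disjoint folds.
#' @param ... Overrides passed on to [pipeline_config()].
#' @return A [pipeline_config()].
#' @export
fixture_pipeline_config <- function(epochs = 120L, n_folds = 5L, ...) {
  args <- list(
    model = model_config(encoder_hidden = c(64L, 32L, 16L),
                         head_hidden = c(64L, 32L, 16L),
                         attention_heads = 4L,
                         learning_rate = 3e-3,
                         batch_size = 128L,
                         epochs = as.integer(epochs)),
    n_folds = as.integer(n_folds),
    vae_latent = 16L, vae_hidden = c(64L), vae_epochs = 60L
  )
  args[names(list(...))] <- list(...)
  do.call(pipeline_config, args)
}
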