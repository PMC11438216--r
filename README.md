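# mvsynergy

Multi-view ensemble prediction of anticancer drug-combination synergy.

Screening every drug pair against every cell line is infeasible at lab
scale, so computational models that rank candidate combinations matter.
`mvsynergy` predicts, for a pair of drugs on a cancer cell line, both the
continuous **Loewe additivity synergy score** and a three-class **synergy
label** (antagonistic: score < 0; additive: score in [0, 30]; synergistic:
score > 30), for people building or benchmarking synergy predictors who
want a complete, self-contained, reproducible pipeline.

## The model

Four drug feature views are crossed with four cell-line omics views:

| drug views | cell-line views |
|---|---|
| 2D chemical descriptors (RDKit, filtered + tanh-normalized) | gene expression |
| multi-view molecular-graph embedding (walk/path statistics, hashed) | copy number |
| MACCS structural keys (166 bits) | mutation (binary) |
| drug–target binary vector | proteomics |

Each omics view is compressed by its own variational autoencoder
(diagonal-Gaussian latent, KL regularizer
`-0.5 Σ (1 + log σ² − μ² − σ²)`, deterministic mean at compression time).
Each of the 16 (drug view, cell view) pairings feeds one **multi-task
attention network**: three per-entity encoders produce tokens for drug A,
drug B and the cell line; two learned task queries attend over the tokens
with 4-head scaled dot-product attention; attended vectors are residually
concatenated, mixed across tasks by a learnable 2×2 **cross-stitch** unit
(init [[0.9, 0.1], [0.1, 0.9]]), concatenated again, and fed to two PReLU
heads emitting the score (linear unit) and the label (3-way softmax).  The
joint loss is `MSE + cross-entropy` with L1 = L2 = 0.001 on dense weights
and hidden activities, optimized by AdamW.  The sixteen member predictions
are soft-voting averaged: mean score, mean probability vector, argmax label.

Evaluation uses drug-pair-disjoint five-fold cross-validation (every
unordered drug pair lives in exactly one fold), reporting MSE, RMSE,
Pearson correlation with a Student-t 95% CI for the MSE, plus accuracy,
synergistic-class precision, Cohen's kappa, ROC-AUC and PR-AUC.

A seeded synthetic-fixture generator (drugs from an embedded SMILES pool,
rank-3 latent-factor omics, planted synergy signal calibrated to a
~20/60/20 class split) makes the whole pipeline runnable with no external
data.  See `vignettes/methods.Rmd` for the full model description and
design rationale.

## Worked example

A reduced run — 2 drug views × 2 cell views, 60 training epochs — on the
noise-free synthetic fixture (12 drugs × 8 cell lines, 528 combinations):

```r
library(mvsynergy)

fx  <- generate_fixture(fixture_spec(noise_sd = 0))
cfg <- fixture_pipeline_config(epochs = 60L,
                               drug_views = c("fingerprint", "target"),
                               cell_views = c("expression", "proteomics"))
res <- run_cross_validation(fx$drugs, fx$omics, fx$combos, cfg, seed = 1)
print(cv_summary_table(res), digits = 3)
```

```
  fold   mse   rmse pearson accuracy precision  kappa roc_auc pr_auc
1    0 197.0 14.036  0.5553   0.5982        NA 0.1417  0.7560  0.465
2    1 189.2 13.754  0.7117   0.5865    0.6875 0.1644  0.8004  0.706
3    2 148.9 12.204  0.7371   0.6346    0.7500 0.2377  0.8137  0.472
4    3 203.0 14.247  0.5618   0.6058        NA 0.1540  0.8517  0.516
5    4 155.6 12.476  0.6167   0.6538        NA 0.0000  0.8569  0.646
6 mean 178.7 13.343  0.6365   0.6158    0.7188 0.1395  0.8158  0.561
7   sd  24.8  0.937  0.0842   0.0277    0.0442 0.0865  0.0412  0.109
```

One row per test fold, then the fold mean and sd.  `mse`/`rmse`/`pearson`
score the predicted synergy values against the planted ones; `precision`,
`roc_auc` and `pr_auc` judge the synergistic class (precision is `NA` in
folds where no sample was predicted synergistic).  The fold-level MSE CI:

```r
ci <- res$summary$mse_ci
sprintf("MSE %.2f +/- %.2f, 95%% CI [%.2f, %.2f]", ci$mean, ci$sd, ci$lo, ci$hi)
#> "MSE 178.75 +/- 24.75, 95% CI [148.01, 209.48]"
```

The full configuration — all 16 pairings, 120 epochs,
`run_cross_validation(fx$drugs, fx$omics, fx$combos,
fixture_pipeline_config(), seed = 1)` — takes about 13 minutes on one CPU
and reached fold-mean Pearson 0.94, ROC-AUC 0.94 and MSE 130 on the same
fixture: the ensemble recovers the planted signal on held-out drug pairs.

A thin CLI wrapper with `fixtures` and `cv` subcommands ships in
`inst/cli/mvsynergy`.

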