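test_that("drug table reading parses rows, splits targets, rejects duplicates", {
  df <- data.frame(drug_id = c("d1", "d2"),
                   smiles = c("CCO", "CCC"),
                   targets = c("T1;T3", ""))
  path <- write_temp_csv(df, name = "drugs_ok.csv")
  drugs <- read_drug_table(path)
  expect_length(drugs, 2L)
  expect_equal(drugs[[1]]$drug_id, "d1")
  expect_setequal(drugs[[1]]$target_ids, c("T1", "T3"))
  expect_identical(drugs[[2]]$target_ids, character(0))

  dup <- df; dup$drug_id <- c("d1", "d1")
  expect_error(read_drug_table(write_temp_csv(dup, name = "drugs_dup.csv")),
               "duplicate drug_id")
  bad <- df; bad$smiles[2] <- "not_a_molecule(("
  expect_error(read_drug_table(write_temp_csv(bad, name = "drugs_bad.csv")),
               "row 2")
  expect_error(read_drug_table(write_temp_csv(df[, 1:2], name = "drugs_miss.csv")),
               "missing column")
})

test_that("omics matrix reading keeps order and rejects malformed files", {
  df <- data.frame(cell_id = c("c1", "c2", "c3"),
                   g1 = c(1, 2, 3), g2 = c(0, 1, 0),
                   g3 = c(5.5, 1.25, -2), g4 = c(0, 0, 1))
  v <- read_omics_matrix(write_temp_csv(df, name = "om_ok.csv"), "expression")
  expect_identical(v$cell_ids, c("c1", "c2", "c3"))
  expect_identical(v$feature_names, c("g1", "g2", "g3", "g4"))
  expect_equal(dim(v$matrix), c(3L, 4L))
  expect_equal(v$matrix["c2", "g3"], 1.25)

  nn <- df; nn$g1 <- c("1", "x", "3")
  expect_error(read_omics_matrix(write_temp_csv(nn, name = "om_chr.csv"), "expression"),
               "non-numeric")
  dup <- df; dup$cell_id <- c("c1", "c1", "c3")
  expect_error(read_omics_matrix(write_temp_csv(dup, name = "om_dup.csv"), "expression"),
               "duplicate cell id")
  ragged <- file.path(tempdir(), "om_ragged.csv")
  writeLines(c("cell_id,g1,g2", "c1,1,2", "c2,3"), ragged)
  expect_error(read_omics_matrix(ragged, "expression"))
})

test_that("written tables round-trip losslessly through the readers", {
  fx <- tiny_fixture()
  dir <- file.path(tempdir(), "roundtrip")
  write_fixture(fx, dir)
  drugs2 <- read_drug_table(file.path(dir, "drugs.csv"))
  expect_identical(vapply(drugs2, `[[`, "", "smiles"),
                   vapply(fx$drugs, `[[`, "", "smiles"))
  expect_identical(lapply(drugs2, function(d) sort(d$target_ids)),
                   lapply(fx$drugs, function(d) sort(d$target_ids)))
  om2 <- read_omics_matrix(file.path(dir, "omics_expression.csv"), "expression")
  expect_identical(om2$cell_ids, fx$omics$expression$cell_ids)
  expect_equal(om2$matrix, fx$omics$expression$matrix, tolerance = 1e-12)
  cb2 <- read_combination_table(file.path(dir, "combos.csv"))
  expect_equal(cb2$loewe_score, fx$combos$loewe_score, tolerance = 1e-12)
  expect_identical(as.character(cb2$label), as.character(fx$combos$label))
})

test_that("tanh normalization maps centers to 0.5, constants to 0.5, and into (0,1)", {
  set.seed(1)
  X <- cbind(rnorm(20, 5, 2), rnorm(20, -3, 0.5), rep(7, 20))
  p <- tanh_norm_fit(X)
  # the fitted means map exactly to the midpoint
  at_mean <- tanh_norm_apply(p, matrix(colMeans(X), 1))
  expect_equal(as.numeric(at_mean), c(0.5, 0.5, 0.5))
  # constant column maps to 0.5 everywhere
  out <- tanh_norm_apply(p, X)
  expect_true(all(out[, 3] == 0.5))
  expect_true(all(out > 0 & out < 1))
  # closed form: mean 0, sd 1, c = 0.01, x = 100 -> 0.5 * (tanh(1) + 1)
  p1 <- tanh_norm_fit(matrix(c(-1, 1) / sqrt(2), ncol = 1))  # mean 0, sd 1
  expect_equal(as.numeric(tanh_norm_apply(p1, matrix(100, 1))),
               0.5 * (tanh(1) + 1), tolerance = 1e-12)
  expect_equal(0.5 * (tanh(1) + 1), 0.8808, tolerance = 1e-4)

  expect_error(tanh_norm_apply(p, X[, 1:2]), "mismatch")
  expect_error(tanh_norm_apply(list(), X), "fit")
})

test_that("synergy labeling partitions the line with closed [0,30] additive", {
  expect_identical(as.character(label_from_score(c(-5, 0, 15, 30, 45))),
                   c("antagonistic", "additive", "additive", "additive",
                     "synergistic"))
  expect_error(label_from_score(NaN), "finite")
  expect_error(label_from_score(Inf), "finite")
  # exactly one label per score, over a dense grid
  grid <- seq(-50, 80, by = 0.25)
  labs <- label_from_score(grid)
  expect_false(anyNA(labs))
  expect_identical(labs[grid < 0], factor(rep("antagonistic", sum(grid < 0)),
                                          levels = levels(labs)))
  expect_true(all(labs[grid >= 0 & grid <= 30] == "additive"))
  expect_true(all(labs[grid > 30] == "synergistic"))
})

test_that("pair-disjoint folds are disjoint, symmetric in drug order, seeded", {
  fx <- tiny_fixture()
  fa <- make_pair_disjoint_folds(fx$combos, n_folds = 5L, seed = 3L)
  folds <- fold_of(fa, fx$combos)
  expect_true(all(folds %in% 0:4))
  # disjointness: each unordered pair in exactly one fold
  tab <- fold_assignment_table(fa)
  expect_false(anyDuplicated(tab$pair) > 0)
  by_fold <- split(tab$pair, tab$fold)
  for (i in seq_along(by_fold)) for (j in seq_along(by_fold)) {
    if (i < j) expect_length(intersect(by_fold[[i]], by_fold[[j]]), 0L)
  }
  # (A,B) and (B,A) land in the same fold
  swapped <- fx$combos
  tmp <- swapped$drug_a; swapped$drug_a <- swapped$drug_b; swapped$drug_b <- tmp
  expect_identical(fold_of(fa, swapped), folds)
  # same seed, same assignment; different seed reshuffles
  fa2 <- make_pair_disjoint_folds(fx$combos, n_folds = 5L, seed = 3L)
  expect_identical(fa, fa2)
  # round-robin balance: fold sizes differ by at most one pair
  sizes <- table(tab$fold)
  expect_lte(max(sizes) - min(sizes), 1L)
  expect_error(make_pair_disjoint_folds(fx$combos[1, , drop = FALSE], 5L, 1L),
               "fewer distinct drug pairs")
})

test_that("combination tables reject self-pairs and derive labels", {
  expect_error(combination_table("a", "a", "c", 1), "drug_a == drug_b")
  tb <- combination_table(c("a", "b"), c("b", "c"), c("c1", "c2"), c(-1, 31))
  expect_identical(as.character(tb$label), c("antagonistic", "synergistic"))
})
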