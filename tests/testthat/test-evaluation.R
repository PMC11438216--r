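test_that("regression metrics match hand arithmetic", {
  truth <- c(1, 2, 3)
  perfect <- regression_metrics(truth, truth)
  expect_equal(perfect$mse, 0); expect_equal(perfect$rmse, 0)
  expect_equal(perfect$pearson, 1)
  shifted <- regression_metrics(truth + 2, truth)
  expect_equal(shifted$mse, 4); expect_equal(shifted$rmse, 2)
  expect_equal(shifted$pearson, 1)
  doubled <- regression_metrics(2 * truth, truth)
  expect_equal(doubled$mse, 14 / 3)
  expect_equal(doubled$pearson, 1)
  expect_error(regression_metrics(c(1, 2), c(5, 5)), "constant truth")
})

test_that("the fold-MSE confidence interval is the Student-t interval", {
  # five folds with mean 206.57 and sd 43.92 give [152.04, 261.10]
  target_mean <- 206.57; target_sd <- 43.92
  x <- c(-sqrt(2), -sqrt(0.5), 0, sqrt(0.5), sqrt(2))  # mean 0, sd 1
  mses <- target_mean + target_sd * x / stats::sd(x)
  ci <- mse_confidence_interval(mses)
  expect_equal(ci$mean, 206.57, tolerance = 1e-9)
  expect_equal(ci$sd, 43.92, tolerance = 1e-9)
  expect_equal(round(ci$lo, 2), 152.04)
  expect_equal(round(ci$hi, 2), 261.10)
  # symmetric around the mean, monotone in sd
  expect_equal(ci$hi - ci$mean, ci$mean - ci$lo, tolerance = 1e-9)
  wider <- mse_confidence_interval(target_mean + 2 * target_sd * x / stats::sd(x))
  expect_gt(wider$hi - wider$lo, ci$hi - ci$lo)
  # identical folds collapse to a point
  flat <- mse_confidence_interval(rep(10, 4))
  expect_equal(flat$lo, 10); expect_equal(flat$hi, 10)
  expect_error(mse_confidence_interval(5), "at least two")
})

test_that("classification metrics are exact on the hand-built contingency case", {
  # synergistic-vs-rest: TP = 3, FP = 1, FN = 1, TN = 5
  labels <- c(rep("synergistic", 4), rep("additive", 6))
  probs <- matrix(0, 10, 3)
  pred_pos <- c(1, 2, 3, 5)  # three true positives, one false positive
  for (i in 1:10) {
    probs[i, ] <- if (i %in% pred_pos) c(0.05, 0.15, 0.8) else c(0.15, 0.85, 0.0)
  }
  m <- classification_metrics(probs, labels)
  expect_equal(m$precision, 0.75)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$kappa, (0.8 - 0.52) / (1 - 0.52), tolerance = 1e-12)
  expect_equal(m$kappa, 0.5833, tolerance = 1e-4)
  # perfect predictions saturate every metric
  perfect <- matrix(0, 10, 3)
  lab3 <- factor(c(rep("antagonistic", 3), rep("additive", 4),
                   rep("synergistic", 3)),
                 levels = c("antagonistic", "additive", "synergistic"))
  perfect[cbind(1:10, as.integer(lab3))] <- 1
  mp <- classification_metrics(perfect, lab3)
  expect_equal(unlist(mp), c(accuracy = 1, precision = 1, kappa = 1,
                             roc_auc = 1, pr_auc = 1))
  expect_error(classification_metrics(perfect, rep("additive", 10)),
               "single-class")
})

test_that("ROC-AUC agrees with the pairwise-comparison oracle and pROC", {
  skip_if_not_installed("pROC")
  set.seed(11)
  for (i in 1:100) {
    n <- sample(10:40, 1)
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(pos) || all(pos)) next
    scores <- round(rnorm(n), 1)  # coarse rounding forces ties
    a <- roc_auc(scores, pos)
    # oracle 1: mean over all positive-negative pairs with half-credit ties
    sp <- scores[pos]; sn <- scores[!pos]
    cmp <- outer(sp, sn, function(x, y) (x > y) + 0.5 * (x == y))
    expect_equal(a, mean(cmp), tolerance = 1e-12)
    # oracle 2: the reference implementation
    ref <- suppressMessages(pROC::auc(pROC::roc(response = pos,
                                                predictor = scores,
                                                direction = "<", quiet = TRUE)))
    expect_equal(a, as.numeric(ref), tolerance = 1e-9)
  }
})

test_that("accuracy and kappa agree with the e1071 reference on random tables", {
  skip_if_not_installed("e1071")
  set.seed(12)
  classes <- c("antagonistic", "additive", "synergistic")
  for (i in 1:100) {
    n <- sample(12:50, 1)
    truth <- factor(sample(classes, n, replace = TRUE), levels = classes)
    if (length(unique(truth)) < 2) next
    probs <- matrix(rexp(3 * n), n)
    probs <- probs / rowSums(probs)
    if (!any(truth == "synergistic") || all(truth == "synergistic")) next
    m <- classification_metrics(probs, truth)
    pred <- factor(classes[max.col(probs, ties.method = "first")],
                   levels = classes)
    ca <- e1071::classAgreement(table(pred, truth))
    expect_equal(m$accuracy, ca$diag, tolerance = 1e-9)
    expect_equal(m$kappa, ca$kappa, tolerance = 1e-9)
  }
})

test_that("PR-AUC matches hand-traced curves", {
  # scores 0.9, 0.8, 0.7, 0.6 with positives at ranks 1 and 3
  a <- pr_auc(c(0.9, 0.8, 0.7, 0.6), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(a, 0.5 + (0.5 + 2 / 3) / 2 * 0.5, tolerance = 1e-12)
  # perfect ranking gives area 1
  expect_equal(pr_auc(c(3, 2, 1), c(TRUE, TRUE, FALSE)), 1)
  # uniform scores: a single point at (recall 1, precision = prevalence)
  expect_equal(pr_auc(rep(1, 10), c(rep(TRUE, 3), rep(FALSE, 7))), 0.3)
})

test_that("kappa is centred at zero for frequency-matched random predictions", {
  set.seed(13)
  classes <- c("antagonistic", "additive", "synergistic")
  truth <- factor(sample(classes, 300, replace = TRUE, prob = c(0.2, 0.6, 0.2)),
                  levels = classes)
  ks <- replicate(300, cohen_kappa(sample(truth), truth))
  expect_lt(abs(mean(ks)), 0.02)
})

test_that("per-group metrics decompose the global ones", {
  set.seed(14)
  fx <- tiny_fixture()
  combos <- fx$combos[1:40, ]
  pred <- combos$loewe_score + rnorm(40, sd = 4)
  probs <- matrix(rexp(120), 40); probs <- probs / rowSums(probs)
  pg <- per_group_metrics(pred, probs, combos, combos$cell_id)
  # single group equals the global metrics
  one <- per_group_metrics(pred, probs, combos, rep("all", 40))
  expect_equal(one$all$mse, mean((pred - combos$loewe_score)^2))
  # global MSE is the sample-count-weighted mean of group MSEs
  w <- vapply(pg, `[[`, 1, "n"); m <- vapply(pg, `[[`, 1, "mse")
  expect_equal(sum(w * m) / sum(w), mean((pred - combos$loewe_score)^2),
               tolerance = 1e-12)
  # a single-class group is reported with NA AUC and a reason, but keeps MSE
  combos2 <- combos; combos2$label <- factor("additive",
                                             levels = levels(combos$label))
  pg2 <- per_group_metrics(pred, probs, combos2, combos2$cell_id)
  expect_true(all(vapply(pg2, function(r) is.na(r$roc_auc), logical(1))))
  expect_true(all(vapply(pg2, function(r) is.finite(r$mse), logical(1))))
  expect_true(all(vapply(pg2, function(r) !is.null(r$reason), logical(1))))
})
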