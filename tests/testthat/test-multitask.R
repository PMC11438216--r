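test_that("cross-stitch reduces to identity, averaging, and the hand 2x2 case", {
  h1 <- c(1, 0); h2 <- c(0, 1)
  id <- cross_stitch(h1, h2, diag(2))
  expect_equal(id$h_reg, h1); expect_equal(id$h_cls, h2)
  half <- cross_stitch(h1, h2, matrix(0.5, 2, 2))
  expect_equal(half$h_reg, (h1 + h2) / 2)
  expect_equal(half$h_cls, (h1 + h2) / 2)
  def <- cross_stitch(h1, h2)
  expect_equal(def$h_reg, c(0.9, 0.1))
  expect_equal(def$h_cls, c(0.1, 0.9))
  expect_error(cross_stitch(1:3, 1:2), "equal length")
})

test_that("residual concatenation preserves order and length", {
  expect_equal(residual_concat(c(1, 2), 3), c(1, 2, 3))
  set.seed(2)
  for (i in 1:5) {
    x <- rnorm(sample(1:10, 1)); y <- rnorm(sample(1:10, 1))
    expect_length(residual_concat(x, y), length(x) + length(y))
    expect_equal(residual_concat(x, y)[seq_along(x)], x)
  }
})

test_that("task attention weights normalize and degenerate cases collapse", {
  set.seed(3)
  d <- 8L
  tokens <- matrix(rnorm(3 * d), 3, d)
  q <- matrix(rnorm(2 * d), 2, d)
  Wk <- matrix(rnorm(d * d, sd = 0.3), d, d)
  Wv <- matrix(rnorm(d * d, sd = 0.3), d, d)
  att <- task_attention(tokens, q, Wk, Wv, diag(d), n_heads = 4L)
  for (tk in 1:2) for (h in 1:4) {
    expect_equal(sum(att$weights[[tk]][[h]]), 1)
    expect_true(all(att$weights[[tk]][[h]] > 0))
  }
  # identical tokens: the attended vector equals the common value projection
  same <- matrix(rep(tokens[1, ], 3), 3, byrow = TRUE)
  att_same <- task_attention(same, q, Wk, Wv, diag(d), n_heads = 4L)
  expect_equal(as.numeric(att_same$vectors[1, ]),
               as.numeric(tokens[1, , drop = FALSE] %*% Wv), tolerance = 1e-12)
  expect_error(task_attention(tokens, q, Wk, Wv, diag(d), n_heads = 3L),
               "divide")
})

test_that("one-head identity-projection attention equals the softmax oracle", {
  set.seed(4)
  d <- 6L
  tokens <- matrix(rnorm(3 * d), 3, d)
  q <- rnorm(d)
  att <- task_attention(tokens, q, diag(d), diag(d), diag(d), n_heads = 1L)
  s <- as.numeric(tokens %*% q) / sqrt(d)
  w <- exp(s - max(s)); w <- w / sum(w)
  oracle <- colSums(w * tokens)
  expect_equal(as.numeric(att$vectors[1, ]), oracle, tolerance = 1e-12)
  expect_equal(att$weights[[1]][[1]], w, tolerance = 1e-12)
})

test_that("entity encoders produce tokens of the configured width", {
  set.seed(5)
  cfg <- tiny_model_config()
  params <- mvsynergy:::mt_init_params(10L, 10L, 7L, cfg)
  x <- rnorm(10)
  tok <- encode_entity(x, params$encA)
  expect_length(tok, 8L)  # last encoder width
  # zero weights map anything to zero (linear final layer)
  zero_enc <- lapply(params$encA, function(l) list(W = l$W * 0, b = l$b * 0))
  expect_equal(encode_entity(x, zero_enc), rep(0, 8L))
  # the three encoders are distinct: perturbing one changes only its token
  tokA <- encode_entity(x, params$encA)
  tokB <- encode_entity(x, params$encB)
  expect_false(isTRUE(all.equal(tokA, tokB)))
})

test_that("prediction heads emit simplex probabilities and configured widths", {
  set.seed(6)
  cfg <- tiny_model_config()
  params <- mvsynergy:::mt_init_params(10L, 10L, 7L, cfg)
  width <- 2L * 4L * 8L
  out <- predict_heads(rnorm(width), rnorm(width),
                       params$head_reg, params$head_cls)
  expect_length(out$score_pred, 1L)
  expect_length(out$class_probs, 3L)
  expect_equal(sum(out$class_probs), 1)
  expect_true(all(out$class_probs > 0))
  # head layer widths follow the config
  expect_equal(vapply(params$head_reg$layers, function(l) ncol(l$W), 1L),
               c(12L, 8L))
})

test_that("joint loss reduces to its closed forms", {
  out <- list(score_pred = 5, class_probs = c(0, 0, 1))
  expect_equal(joint_loss(out, 5, "synergistic"), 0, tolerance = 1e-9)
  # uniform probabilities: cross-entropy is log(3)
  unif <- list(score_pred = 5, class_probs = rep(1 / 3, 3))
  expect_equal(joint_loss(unif, 5, "additive"), log(3), tolerance = 1e-12)
  # lambda_cls = 0 reduces to the squared error
  expect_equal(joint_loss(unif, 7, "additive", lambda_cls = 0), 4)
})

test_that("training is deterministic per seed and fits a small fixture", {
  fx <- tiny_fixture()
  dv <- compute_target_view(fx$drugs)
  comp <- fit_view_vae(fx$omics$expression, latent_dim = 6L, hidden = c(24L),
                       epochs = 30L, seed = 5L)
  cv <- compress_view(comp, fx$omics$expression)
  cfg <- tiny_model_config(epochs = 120L)
  sub <- fx$combos[seq_len(60L), ]
  m1 <- train_view_pair_model(sub, dv, cv, cfg, seed = 21L)
  m2 <- train_view_pair_model(sub, dv, cv, cfg, seed = 21L)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(m1$params, m2$params)
  # the model fits signal: training MSE below the target variance
  pr <- predict(m1, sub, dv, cv)
  expect_lt(mean((pr$score - sub$loewe_score)^2), stats::var(sub$loewe_score))
  # with full-batch training, permuting the input rows leaves the fit
  # unchanged up to floating-point summation order
  cfg_fb <- tiny_model_config(epochs = 5L, batch_size = 128L)
  m3a <- train_view_pair_model(sub, dv, cv, cfg_fb, seed = 21L)
  m3b <- train_view_pair_model(sub[rev(seq_len(nrow(sub))), ], dv, cv,
                               cfg_fb, seed = 21L)
  expect_equal(predict(m3b, sub, dv, cv)$score,
               predict(m3a, sub, dv, cv)$score, tolerance = 1e-6)
  expect_error(train_view_pair_model(sub[0, ], dv, cv, cfg), "empty training set")
})

test_that("exported predictions are invariant to drug order", {
  fx <- tiny_fixture()
  dv <- compute_fingerprint_view(fx$drugs)
  comp <- fit_view_vae(fx$omics$proteomics, latent_dim = 4L, hidden = c(16L),
                       epochs = 10L, seed = 2L)
  cv <- compress_view(comp, fx$omics$proteomics)
  m <- train_view_pair_model(fx$combos[1:40, ], dv, cv,
                             tiny_model_config(epochs = 10L), seed = 1L)
  pr <- predict(m, fx$combos[1:40, ], dv, cv)
  swapped <- fx$combos[1:40, ]
  tmp <- swapped$drug_a; swapped$drug_a <- swapped$drug_b; swapped$drug_b <- tmp
  pr2 <- predict(m, swapped, dv, cv)
  expect_identical(pr$score, pr2$score)
  expect_identical(pr$class_probs, pr2$class_probs)
  # probabilities are on the simplex, scores finite
  expect_equal(unname(rowSums(pr$class_probs)), rep(1, 40), tolerance = 1e-12)
  expect_true(all(is.finite(pr$score)))
})

test_that("the exclude-additive flag drops the middle class from training", {
  fx <- tiny_fixture()
  dv <- compute_target_view(fx$drugs)
  comp <- fit_view_vae(fx$omics$expression, latent_dim = 4L, hidden = c(16L),
                       epochs = 5L, seed = 2L)
  cv <- compress_view(comp, fx$omics$expression)
  only_add <- fx$combos[fx$combos$label == "additive", ]
  expect_error(train_view_pair_model(only_add, dv, cv,
                                     tiny_model_config(epochs = 2L,
                                                       exclude_additive = TRUE),
                                     seed = 1L),
               "empty training set")
})
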