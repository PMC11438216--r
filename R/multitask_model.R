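# The multi-task attention network bound to one (drug view, cell view)
# pairing: three per-entity encoders -> task-specific multi-head attention
# over the three tokens -> residual concatenation -> cross-stitch unit ->
# residual concatenation -> two PReLU prediction heads emitting the synergy
# score and the three-class logits.  Forward and backward passes are written
# out by hand on top of the nn_* primitives; gradients are pinned by
# finite-difference tests.

#' Model configuration
#'
#' Defaults follow the reference setting: encoder stack \[1024, 512, 256\]
#' (the last entry is the attention token width), prediction heads
#' \[1024, 128, 64\], 4 attention heads, AdamW with learning rate 1e-4,
#' batch size 512, 500 epochs, and L1 = L2 = 0.001 applied to the weights
#' and hidden outputs of every fully connected layer.  Tests and fixtures
#' override these with much smaller values.
#'
#' @param encoder_hidden Encoder layer sizes; the last entry is the token
#'   width and must be divisible by `attention_heads`.
#' @param head_hidden Prediction-head layer sizes.
#' @param attention_heads Number of attention heads.
#' @param learning_rate,batch_size,epochs AdamW training schedule.
#' @param l1,l2 Weight-regularization coefficients for dense layers.
#' @param activity_l1,activity_l2 Activity-regularization coefficients on
#'   hidden dense outputs (default: same as `l1`, `l2`).
#' @param lambda_reg,lambda_cls Loss weights of the regression (squared
#'   error) and classification (cross-entropy) tasks.
#' @param cross_stitch_init Initial 2x2 cross-stitch matrix.
#' @param per_dim_cross_stitch If `TRUE`, a separate 2x2 mixing matrix is
#'   learned per feature dimension instead of one shared matrix.
#' @param prelu_init Initial PReLU slope.
#' @param weight_decay Decoupled AdamW weight decay (default 0; the explicit
#'   L1/L2 terms carry the penalty).
#' @param exclude_additive If `TRUE`, additive-class samples are dropped from
#'   training entirely (both losses).
#' @return A list of class `model_config`.
#' @export
model_config <- function(encoder_hidden = c(1024L, 512L, 256L),
                         head_hidden = c(1024L, 128L, 64L),
                         attention_heads = 4L,
                         learning_rate = 1e-4,
                         batch_size = 512L,
                         epochs = 500L,
                         l1 = 0.001, l2 = 0.001,
                         activity_l1 = l1, activity_l2 = l2,
                         lambda_reg = 1, lambda_cls = 1,
                         cross_stitch_init = matrix(c(0.9, 0.1, 0.1, 0.9), 2L, 2L,
                                                    byrow = TRUE),
                         per_dim_cross_stitch = FALSE,
                         prelu_init = 0.25,
                         weight_decay = 0,
                         exclude_additive = FALSE) {
  d <- encoder_hidden[length(encoder_hidden)]
  if (d %% attention_heads != 0) {
    stop("attention_heads (", attention_heads, ") must divide the token width (",
         d, ")")
  }
  structure(list(encoder_hidden = as.integer(encoder_hidden),
                 head_hidden = as.integer(head_hidden),
                 attention_heads = as.integer(attention_heads),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 l1 = l1, l2 = l2,
                 activity_l1 = activity_l1, activity_l2 = activity_l2,
                 lambda_reg = lambda_reg, lambda_cls = lambda_cls,
                 cross_stitch_init = cross_stitch_init,
                 per_dim_cross_stitch = isTRUE(per_dim_cross_stitch),
                 prelu_init = prelu_init,
                 weight_decay = weight_decay,
                 exclude_additive = isTRUE(exclude_additive)),
            class = "model_config")
}

# ---- parameter initialization ---------------------------------------------

mt_init_encoder <- function(nin, hidden) {
  layers <- list()
  for (h in hidden) { layers[[length(layers) + 1L]] <- nn_dense_init(nin, h); nin <- h }
  layers
}

mt_init_head <- function(nin, hidden, nout, prelu_init) {
  layers <- list()
  for (h in hidden) { layers[[length(layers) + 1L]] <- nn_dense_init(nin, h); nin <- h }
  list(layers = layers, a = rep(prelu_init, length(hidden)),
       out = nn_dense_init(nin, nout, scale = sqrt(1 / nin)))
}

mt_init_params <- function(pA, pB, pC, config) {
  d <- config$encoder_hidden[length(config$encoder_hidden)]
  width <- 4L * d  # tokens (3d) + attended vector (d)
  cs <- config$cross_stitch_init
  rep_a <- function(x) if (config$per_dim_cross_stitch) rep(x, width) else x
  list(
    encA = mt_init_encoder(pA, config$encoder_hidden),
    encB = mt_init_encoder(pB, config$encoder_hidden),
    encC = mt_init_encoder(pC, config$encoder_hidden),
    att = list(Q = matrix(stats::rnorm(2L * d, sd = 1 / sqrt(d)), 2L, d),
               Wk = matrix(stats::rnorm(d * d, sd = 1 / sqrt(d)), d, d),
               Wv = matrix(stats::rnorm(d * d, sd = 1 / sqrt(d)), d, d),
               Wo = matrix(stats::rnorm(d * d, sd = 1 / sqrt(d)), d, d)),
    alpha = list(a11 = rep_a(cs[1, 1]), a12 = rep_a(cs[1, 2]),
                 a21 = rep_a(cs[2, 1]), a22 = rep_a(cs[2, 2])),
    head_reg = mt_init_head(2L * width, config$head_hidden, 1L, config$prelu_init),
    head_cls = mt_init_head(2L * width, config$head_hidden, 3L, config$prelu_init)
  )
}

# Multiply by a cross-stitch coefficient (scalar, or per-dimension vector).
cs_mul <- function(a, U) {
  if (length(a) == 1L) a * U else sweep(U, 2L, a[seq_len(ncol(U))], "*")
}
cs_grad <- function(dUp, U, per_dim) {
  if (per_dim) colSums(dUp * U) else sum(dUp * U)
}

# ---- forward ---------------------------------------------------------------

mt_encoder_forward <- function(layers, X) {
  nl <- length(layers)
  Zs <- vector("list", nl); As <- vector("list", nl)
  A <- X
  for (i in seq_len(nl)) {
    Z <- nn_dense_forward(layers[[i]], A)
    Zs[[i]] <- Z
    A <- if (i < nl) nn_relu(Z) else Z  # linear final layer: the token
    As[[i]] <- A
  }
  list(X = X, Zs = Zs, As = As, token = A)
}

# Multi-head scaled dot-product attention of `m` task queries over the
# 3-token sequence.  Ts: list of (n x d) token matrices.
mt_attention_forward <- function(att, Ts, n_heads) {
  d <- ncol(att$Wk); n <- nrow(Ts[[1L]])
  dh <- d %/% n_heads
  m <- nrow(att$Q)
  Ks <- lapply(Ts, function(T) T %*% att$Wk)
  Vs <- lapply(Ts, function(T) T %*% att$Wv)
  A_att <- vector("list", m)   # concat-head attended vectors, pre-Wo
  W_soft <- vector("list", m)  # per task: list over heads of (n x 3) weights
  for (tk in seq_len(m)) {
    A <- matrix(0, n, d)
    Wh <- vector("list", n_heads)
    for (h in seq_len(n_heads)) {
      ih <- ((h - 1L) * dh + 1L):(h * dh)
      q <- att$Q[tk, ih]
      S <- vapply(Ks, function(K) as.numeric(K[, ih, drop = FALSE] %*% q),
                  numeric(n)) / sqrt(dh)
      if (n == 1L) S <- matrix(S, 1L)
      W <- nn_softmax_rows(S)
      Wh[[h]] <- W
      for (i in seq_along(Ts)) {
        A[, ih] <- A[, ih] + W[, i] * Vs[[i]][, ih, drop = FALSE]
      }
    }
    A_att[[tk]] <- A
    W_soft[[tk]] <- Wh
  }
  O <- lapply(A_att, function(A) A %*% att$Wo)
  list(Ks = Ks, Vs = Vs, A_att = A_att, W_soft = W_soft, O = O,
       dh = dh, n_heads = n_heads)
}

mt_head_forward <- function(head, V) {
  nl <- length(head$layers)
  Zs <- vector("list", nl); Hs <- vector("list", nl)
  H <- V
  for (i in seq_len(nl)) {
    Z <- nn_dense_forward(head$layers[[i]], H)
    Zs[[i]] <- Z
    H <- nn_prelu(Z, head$a[i])
    Hs[[i]] <- H
  }
  list(V = V, Zs = Zs, Hs = Hs, out = nn_dense_forward(head$out, H))
}

mt_forward <- function(params, config, XA, XB, XC) {
  encA <- mt_encoder_forward(params$encA, XA)
  encB <- mt_encoder_forward(params$encB, XB)
  encC <- mt_encoder_forward(params$encC, XC)
  Ts <- list(encA$token, encB$token, encC$token)
  att <- mt_attention_forward(params$att, Ts, config$attention_heads)
  Xcat <- cbind(Ts[[1L]], Ts[[2L]], Ts[[3L]])
  U1 <- cbind(Xcat, att$O[[1L]])
  U2 <- cbind(Xcat, att$O[[2L]])
  al <- params$alpha
  U1p <- cs_mul(al$a11, U1) + cs_mul(al$a12, U2)
  U2p <- cs_mul(al$a21, U1) + cs_mul(al$a22, U2)
  V1 <- cbind(U1, U1p)
  V2 <- cbind(U2, U2p)
  hr <- mt_head_forward(params$head_reg, V1)
  hc <- mt_head_forward(params$head_cls, V2)
  probs <- nn_softmax_rows(hc$out)
  list(encA = encA, encB = encB, encC = encC, Ts = Ts, att = att,
       Xcat = Xcat, U1 = U1, U2 = U2, U1p = U1p, U2p = U2p,
       V1 = V1, V2 = V2, hr = hr, hc = hc,
       score = as.numeric(hr$out), probs = probs)
}

# Activity-regularization loss over hidden outputs (mean over batch).
mt_activity_loss <- function(cache, config) {
  outs <- c(cache$encA$As, cache$encB$As, cache$encC$As,
            cache$hr$Hs, cache$hc$Hs)
  n <- nrow(cache$U1)
  s <- 0
  for (A in outs) s <- s + config$activity_l1 * sum(abs(A)) +
    config$activity_l2 * sum(A^2)
  s / n
}

mt_weight_list <- function(params) {
  c(lapply(params$encA, `[[`, "W"), lapply(params$encB, `[[`, "W"),
    lapply(params$encC, `[[`, "W"),
    lapply(params$head_reg$layers, `[[`, "W"), list(params$head_reg$out$W),
    lapply(params$head_cls$layers, `[[`, "W"), list(params$head_cls$out$W))
}

mt_loss <- function(params, config, cache, y, Y1hot) {
  n <- length(y)
  mse_term <- config$lambda_reg * sum((cache$score - y)^2) / n
  ce_term <- config$lambda_cls *
    sum(-log(pmax(cache$probs, 1e-12)) * Y1hot) / n
  reg <- nn_reg_loss(mt_weight_list(params), config$l1, config$l2)
  act <- mt_activity_loss(cache, config)
  list(loss = mse_term + ce_term + reg + act,
       mse = sum((cache$score - y)^2) / n, ce = ce_term)
}

# ---- backward --------------------------------------------------------------

mt_encoder_backward <- function(layers, cache, dT, config, grads_enc) {
  nl <- length(layers)
  n <- nrow(dT)
  dA <- dT
  for (i in rev(seq_len(nl))) {
    # activity regularization on this layer's output
    Ai <- cache$As[[i]]
    dA <- dA + (config$activity_l1 * sign(Ai) + 2 * config$activity_l2 * Ai) / n
    dZ <- if (i < nl) nn_relu_backward(cache$Zs[[i]], dA) else dA
    below <- if (i > 1L) cache$As[[i - 1L]] else cache$X
    bd <- nn_dense_backward(layers[[i]], below, dZ)
    grads_enc[[i]]$W <- grads_enc[[i]]$W + bd$dW
    grads_enc[[i]]$b <- grads_enc[[i]]$b + bd$db
    dA <- bd$dX
  }
  grads_enc
}

mt_head_backward <- function(head, cache, dOut, config, grads_head) {
  n <- nrow(dOut)
  nl <- length(head$layers)
  bo <- nn_dense_backward(head$out, cache$Hs[[nl]], dOut)
  grads_head$out$W <- grads_head$out$W + bo$dW
  grads_head$out$b <- grads_head$out$b + bo$db
  dH <- bo$dX
  for (i in rev(seq_len(nl))) {
    Hi <- cache$Hs[[i]]
    dH <- dH + (config$activity_l1 * sign(Hi) + 2 * config$activity_l2 * Hi) / n
    pb <- nn_prelu_backward(cache$Zs[[i]], head$a[i], dH)
    grads_head$a[i] <- grads_head$a[i] + pb$da
    below <- if (i > 1L) cache$Hs[[i - 1L]] else cache$V
    bd <- nn_dense_backward(head$layers[[i]], below, pb$dZ)
    grads_head$layers[[i]]$W <- grads_head$layers[[i]]$W + bd$dW
    grads_head$layers[[i]]$b <- grads_head$layers[[i]]$b + bd$db
    dH <- bd$dX
  }
  list(grads = grads_head, dV = dH)
}

mt_attention_backward <- function(att, cache_att, Ts, dOs, grads_att) {
  d <- ncol(att$Wk)
  n <- nrow(Ts[[1L]])
  n_heads <- cache_att$n_heads; dh <- cache_att$dh
  dTs <- lapply(Ts, function(T) matrix(0, n, d))
  dKs <- lapply(Ts, function(T) matrix(0, n, d))
  dVs <- lapply(Ts, function(T) matrix(0, n, d))
  for (tk in seq_along(dOs)) {
    dO <- dOs[[tk]]
    grads_att$Wo <- grads_att$Wo + t(cache_att$A_att[[tk]]) %*% dO
    dA <- dO %*% t(att$Wo)
    for (h in seq_len(n_heads)) {
      ih <- ((h - 1L) * dh + 1L):(h * dh)
      dA_h <- dA[, ih, drop = FALSE]
      W <- cache_att$W_soft[[tk]][[h]]
      dWt <- matrix(0, n, length(Ts))
      for (i in seq_along(Ts)) {
        V_ih <- cache_att$Vs[[i]][, ih, drop = FALSE]
        dWt[, i] <- rowSums(dA_h * V_ih)
        dVs[[i]][, ih] <- dVs[[i]][, ih] + W[, i] * dA_h
      }
      rs <- rowSums(W * dWt)
      dS <- W * (dWt - rs)  # softmax backward, rows
      q <- att$Q[tk, ih]
      sc <- 1 / sqrt(dh)
      for (i in seq_along(Ts)) {
        K_ih <- cache_att$Ks[[i]][, ih, drop = FALSE]
        grads_att$Q[tk, ih] <- grads_att$Q[tk, ih] +
          sc * as.numeric(t(K_ih) %*% dS[, i])
        dKs[[i]][, ih] <- dKs[[i]][, ih] + sc * outer(dS[, i], q)
      }
    }
  }
  for (i in seq_along(Ts)) {
    grads_att$Wk <- grads_att$Wk + t(Ts[[i]]) %*% dKs[[i]]
    grads_att$Wv <- grads_att$Wv + t(Ts[[i]]) %*% dVs[[i]]
    dTs[[i]] <- dTs[[i]] + dKs[[i]] %*% t(att$Wk) + dVs[[i]] %*% t(att$Wv)
  }
  list(grads = grads_att, dTs = dTs)
}

mt_backward <- function(params, config, cache, y, Y1hot) {
  n <- length(y)
  d <- ncol(cache$Ts[[1L]])
  width <- 4L * d
  grads <- nn_zeros_like(params)

  dscore <- config$lambda_reg * 2 * (cache$score - y) / n
  dyhat <- matrix(dscore, n, 1L)
  dlogits <- config$lambda_cls * (cache$probs - Y1hot) / n

  hb_r <- mt_head_backward(params$head_reg, cache$hr, dyhat, config, grads$head_reg)
  grads$head_reg <- hb_r$grads
  hb_c <- mt_head_backward(params$head_cls, cache$hc, dlogits, config, grads$head_cls)
  grads$head_cls <- hb_c$grads

  dU1 <- hb_r$dV[, seq_len(width), drop = FALSE]
  dU1p <- hb_r$dV[, width + seq_len(width), drop = FALSE]
  dU2 <- hb_c$dV[, seq_len(width), drop = FALSE]
  dU2p <- hb_c$dV[, width + seq_len(width), drop = FALSE]

  al <- params$alpha
  per_dim <- config$per_dim_cross_stitch
  grads$alpha$a11 <- cs_grad(dU1p, cache$U1, per_dim)
  grads$alpha$a12 <- cs_grad(dU1p, cache$U2, per_dim)
  grads$alpha$a21 <- cs_grad(dU2p, cache$U1, per_dim)
  grads$alpha$a22 <- cs_grad(dU2p, cache$U2, per_dim)
  dU1 <- dU1 + cs_mul(al$a11, dU1p) + cs_mul(al$a21, dU2p)
  dU2 <- dU2 + cs_mul(al$a12, dU1p) + cs_mul(al$a22, dU2p)

  dXcat <- dU1[, seq_len(3L * d), drop = FALSE] + dU2[, seq_len(3L * d), drop = FALSE]
  dOs <- list(dU1[, 3L * d + seq_len(d), drop = FALSE],
              dU2[, 3L * d + seq_len(d), drop = FALSE])

  ab <- mt_attention_backward(params$att, cache$att, cache$Ts, dOs, grads$att)
  grads$att <- ab$grads
  dTs <- ab$dTs
  for (i in 1:3) {
    dTs[[i]] <- dTs[[i]] + dXcat[, (i - 1L) * d + seq_len(d), drop = FALSE]
  }

  grads$encA <- mt_encoder_backward(params$encA, cache$encA, dTs[[1L]], config, grads$encA)
  grads$encB <- mt_encoder_backward(params$encB, cache$encB, dTs[[2L]], config, grads$encB)
  grads$encC <- mt_encoder_backward(params$encC, cache$encC, dTs[[3L]], config, grads$encC)

  # weight (L1+L2) regularization on dense layers
  add_reg <- function(g, p) { g$W <- g$W + nn_reg_grad(p$W, config$l1, config$l2); g }
  for (nm in c("encA", "encB", "encC")) {
    for (i in seq_along(params[[nm]])) {
      grads[[nm]][[i]] <- add_reg(grads[[nm]][[i]], params[[nm]][[i]])
    }
  }
  for (nm in c("head_reg", "head_cls")) {
    for (i in seq_along(params[[nm]]$layers)) {
      grads[[nm]]$layers[[i]] <- add_reg(grads[[nm]]$layers[[i]], params[[nm]]$layers[[i]])
    }
    grads[[nm]]$out <- add_reg(grads[[nm]]$out, params[[nm]]$out)
  }
  grads
}

# ---- spec-surface wrappers -------------------------------------------------

#' Encode an entity's features into an attention token
#'
#' Applies a fully connected encoder stack (ReLU between layers, linear final
#' layer) to a feature vector or matrix.
#'
#' @param features Numeric vector (one entity) or matrix (rows = entities).
#' @param encoder Encoder parameters: list of layers, each `list(W, b)` (as
#'   found in `model$params$encA` of a trained model).
#' @return Token vector (or matrix) of width `ncol` of the last layer.
#' @export
encode_entity <- function(features, encoder) {
  X <- if (is.matrix(features)) features else matrix(features, 1L)
  tok <- mt_encoder_forward(encoder, X)$token
  if (is.matrix(features)) tok else as.numeric(tok)
}

#' Task-specific multi-head attention over entity tokens
#'
#' Each task query attends (scaled dot-product, `n_heads` heads) over the
#' token sequence; per task and head the attention weights are a softmax
#' distribution over the tokens.
#'
#' @param tokens Matrix with one token per row (typically 3 x d:
#'   drug A, drug B, cell line).
#' @param query Task query matrix (tasks x d) or a single query vector.
#' @param Wk,Wv,Wo Key/value/output projection matrices (d x d).
#' @param n_heads Number of heads (must divide d).
#' @return List with `vectors` (tasks x d attended task vectors) and
#'   `weights` (per task, per head, the softmax weights over tokens).
#' @export
task_attention <- function(tokens, query, Wk, Wv, Wo, n_heads = 4L) {
  stopifnot(is.matrix(tokens))
  d <- ncol(tokens)
  if (d %% n_heads != 0) stop("n_heads must divide the token width")
  Q <- if (is.matrix(query)) query else matrix(query, 1L)
  att <- list(Q = Q, Wk = Wk, Wv = Wv, Wo = Wo)
  Ts <- lapply(seq_len(nrow(tokens)), function(i) tokens[i, , drop = FALSE])
  fw <- mt_attention_forward(att, Ts, n_heads)
  vectors <- do.call(rbind, lapply(fw$O, as.numeric))
  weights <- lapply(fw$W_soft, function(Wh) lapply(Wh, as.numeric))
  list(vectors = vectors, weights = weights)
}

#' Residual concatenation
#'
#' Pure concatenation in the order (input, output), used after both the
#' attention stage and the cross-stitch stage.
#'
#' @param x,y Numeric vectors.
#' @return `c(x, y)`.
#' @export
residual_concat <- function(x, y) c(x, y)

#' Cross-stitch mixing of the two task streams
#'
#' Elementwise `[h_reg'; h_cls'] = alpha %*% [h_reg; h_cls]` with a shared
#' 2x2 mixing matrix.
#'
#' @param h_reg,h_cls Equal-length numeric vectors (task streams).
#' @param alpha 2x2 mixing matrix (default the \[\[0.9, 0.1\], \[0.1, 0.9\]\]
#'   initialization).
#' @return List with elements `h_reg` and `h_cls`.
#' @export
cross_stitch <- function(h_reg, h_cls,
                         alpha = matrix(c(0.9, 0.1, 0.1, 0.9), 2L, 2L, byrow = TRUE)) {
  if (length(h_reg) != length(h_cls)) stop("h_reg and h_cls must have equal length")
  list(h_reg = alpha[1, 1] * h_reg + alpha[1, 2] * h_cls,
       h_cls = alpha[2, 1] * h_reg + alpha[2, 2] * h_cls)
}

#' Prediction heads
#'
#' Applies the two PReLU head stacks to the post-cross-stitch task vectors;
#' the regression head ends in one linear unit, the classification head in a
#' three-way softmax.
#'
#' @param task_vec_reg,task_vec_cls Numeric task vectors (or matrices).
#' @param head_reg,head_cls Head parameters (as in `model$params$head_reg`).
#' @return List with `score_pred` (numeric) and `class_probs` (simplex
#'   vector, or matrix with rows on the simplex).
#' @export
predict_heads <- function(task_vec_reg, task_vec_cls, head_reg, head_cls) {
  Vr <- if (is.matrix(task_vec_reg)) task_vec_reg else matrix(task_vec_reg, 1L)
  Vc <- if (is.matrix(task_vec_cls)) task_vec_cls else matrix(task_vec_cls, 1L)
  score <- as.numeric(mt_head_forward(head_reg, Vr)$out)
  probs <- nn_softmax_rows(mt_head_forward(head_cls, Vc)$out)
  if (!is.matrix(task_vec_cls)) probs <- as.numeric(probs)
  list(score_pred = score, class_probs = probs)
}

#' Joint multi-task loss
#'
#' Per-sample loss `lambda_reg * (score_pred - target_score)^2 +
#' lambda_cls * cross_entropy(class_probs, target_label)`; the training loop
#' adds the weight/activity regularization terms on top.
#'
#' @param outputs List with `score_pred` and `class_probs` (vector of 3, or
#'   n x 3 matrix).
#' @param target_score Numeric target synergy score(s).
#' @param target_label Target label(s): factor or character in
#'   antagonistic/additive/synergistic.
#' @param lambda_reg,lambda_cls Task weights.
#' @return Mean per-sample joint loss.
#' @export
joint_loss <- function(outputs, target_score, target_label,
                       lambda_reg = 1, lambda_cls = 1) {
  P <- outputs$class_probs
  if (!is.matrix(P)) P <- matrix(P, 1L)
  lab <- factor(as.character(target_label), levels = SYNERGY_CLASSES)
  idx <- cbind(seq_along(target_score), as.integer(lab))
  ce <- -log(pmax(P[idx], 1e-12))
  mean(lambda_reg * (outputs$score_pred - target_score)^2 + lambda_cls * ce)
}

# ---- training and prediction ----------------------------------------------

mt_design <- function(combos, drug_view, cell_view, flip = FALSE) {
  a <- if (flip) combos$drug_b else combos$drug_a
  b <- if (flip) combos$drug_a else combos$drug_b
  missing_d <- setdiff(unique(c(a, b)), drug_view$drug_ids)
  if (length(missing_d)) stop("drugs not featurized: ", paste(missing_d, collapse = ", "))
  missing_c <- setdiff(unique(combos$cell_id), cell_view$cell_ids)
  if (length(missing_c)) stop("cells not featurized: ", paste(missing_c, collapse = ", "))
  list(XA = drug_view$matrix[a, , drop = FALSE],
       XB = drug_view$matrix[b, , drop = FALSE],
       XC = cell_view$matrix[combos$cell_id, , drop = FALSE])
}

#' Train one view-pair model
#'
#' Trains the multi-task attention network on one (drug view, cell view)
#' pairing with AdamW.  Deterministic given `seed` (weight initialization and
#' batch shuffling both derive from it).
#'
#' @param combos Training combination table (see [combination_table()]).
#' @param drug_view A `drug_view_matrix` covering all drugs in `combos`.
#' @param cell_view A `cell_view_matrix` covering all cells in `combos`.
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @return Object of class `view_pair_model` with the trained parameters,
#'   the pairing, and the per-epoch loss trace.
#' @export
train_view_pair_model <- function(combos, drug_view, cell_view,
                                  config = model_config(), seed = 1L) {
  if (config$exclude_additive) combos <- combos[combos$label != "additive", , drop = FALSE]
  if (!nrow(combos)) stop("empty training set")
  des <- mt_design(combos, drug_view, cell_view)
  y <- combos$loewe_score
  n <- nrow(combos)
  lab <- factor(as.character(combos$label), levels = SYNERGY_CLASSES)
  Y1hot <- matrix(0, n, 3L)
  Y1hot[cbind(seq_len(n), as.integer(lab))] <- 1
  with_local_seed(seed, {
    params <- mt_init_params(ncol(des$XA), ncol(des$XB), ncol(des$XC), config)
    state <- adamw_init(params)
    bs <- min(config$batch_size, n)
    trace <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      idx <- sample.int(n)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, n, by = bs)) {
        rows <- idx[start:min(start + bs - 1L, n)]
        cache <- mt_forward(params, config,
                            des$XA[rows, , drop = FALSE],
                            des$XB[rows, , drop = FALSE],
                            des$XC[rows, , drop = FALSE])
        l <- mt_loss(params, config, cache, y[rows],
                     Y1hot[rows, , drop = FALSE])
        grads <- mt_backward(params, config, cache, y[rows],
                             Y1hot[rows, , drop = FALSE])
        upd <- adamw_step(params, grads, state, lr = config$learning_rate,
                          weight_decay = config$weight_decay)
        params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + l$loss; nb <- nb + 1L
      }
      trace[ep] <- ep_loss / nb
    }
    structure(list(params = params, config = config,
                   drug_view = drug_view$view_name,
                   cell_view = cell_view$view_name,
                   loss_trace = trace, seed = seed),
              class = "view_pair_model")
  })
}

#' Predict synergy for combinations with one view-pair model
#'
#' The two drug encoders are distinct, so the raw network is not symmetric in
#' drug order; by default the two orientations (A,B) and (B,A) are averaged,
#' making the exported prediction order-invariant.
#'
#' @param object A `view_pair_model`.
#' @param combos Combination table (scores/labels ignored if present).
#' @param drug_view,cell_view Featurized views (same view names as training).
#' @param average_orientations Average predictions over both drug orders
#'   (default `TRUE`).
#' @param ... Unused.
#' @return List with `score` (numeric vector) and `class_probs` (n x 3 matrix
#'   with columns antagonistic/additive/synergistic).
#' @export
predict.view_pair_model <- function(object, combos, drug_view, cell_view,
                                    average_orientations = TRUE, ...) {
  config <- object$config
  des <- mt_design(combos, drug_view, cell_view)
  fw <- mt_forward(object$params, config, des$XA, des$XB, des$XC)
  score <- fw$score; probs <- fw$probs
  if (average_orientations) {
    des2 <- mt_design(combos, drug_view, cell_view, flip = TRUE)
    fw2 <- mt_forward(object$params, config, des2$XA, des2$XB, des2$XC)
    score <- (score + fw2$score) / 2
    probs <- (probs + fw2$probs) / 2
  }
  dimnames(probs) <- list(NULL, SYNERGY_CLASSES)
  list(score = score, class_probs = probs)
}
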