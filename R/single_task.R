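# Single-task ablation network: per-entity encoders, concatenation, one
# PReLU prediction head, one output (score, or 3-class softmax).  Two such
# models per view pairing replace the multi-task network in the
# "single_task" pipeline mode.

st_init_params <- function(pA, pB, pC, config, nout) {
  d <- config$encoder_hidden[length(config$encoder_hidden)]
  list(encA = mt_init_encoder(pA, config$encoder_hidden),
       encB = mt_init_encoder(pB, config$encoder_hidden),
       encC = mt_init_encoder(pC, config$encoder_hidden),
       head = mt_init_head(3L * d, config$head_hidden, nout, config$prelu_init))
}

st_forward <- function(params, XA, XB, XC) {
  encA <- mt_encoder_forward(params$encA, XA)
  encB <- mt_encoder_forward(params$encB, XB)
  encC <- mt_encoder_forward(params$encC, XC)
  V <- cbind(encA$token, encB$token, encC$token)
  hd <- mt_head_forward(params$head, V)
  list(encA = encA, encB = encB, encC = encC, V = V, hd = hd, out = hd$out)
}

st_backward <- function(params, config, cache, dOut) {
  d <- ncol(cache$encA$token)
  grads <- nn_zeros_like(params)
  hb <- mt_head_backward(params$head, cache$hd, dOut, config, grads$head)
  grads$head <- hb$grads
  dV <- hb$dV
  grads$encA <- mt_encoder_backward(params$encA, cache$encA,
                                    dV[, seq_len(d), drop = FALSE], config, grads$encA)
  grads$encB <- mt_encoder_backward(params$encB, cache$encB,
                                    dV[, d + seq_len(d), drop = FALSE], config, grads$encB)
  grads$encC <- mt_encoder_backward(params$encC, cache$encC,
                                    dV[, 2L * d + seq_len(d), drop = FALSE], config, grads$encC)
  add_reg <- function(g, p) { g$W <- g$W + nn_reg_grad(p$W, config$l1, config$l2); g }
  for (nm in c("encA", "encB", "encC")) {
    for (i in seq_along(params[[nm]])) {
      grads[[nm]][[i]] <- add_reg(grads[[nm]][[i]], params[[nm]][[i]])
    }
  }
  for (i in seq_along(params$head$layers)) {
    grads$head$layers[[i]] <- add_reg(grads$head$layers[[i]], params$head$layers[[i]])
  }
  grads$head$out <- add_reg(grads$head$out, params$head$out)
  grads
}

#' Train one single-task model
#'
#' Same encoders and head widths as the multi-task network but no attention
#' or cross-stitch, and a single output: the synergy score (`task =
#' "regression"`) or the three-class label (`task = "classification"`).
#'
#' @param combos Training combination table.
#' @param drug_view,cell_view Featurized views.
#' @param task `"regression"` or `"classification"`.
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @return Object of class `single_task_model`.
#' @export
train_single_task_model <- function(combos, drug_view, cell_view,
                                    task = c("regression", "classification"),
                                    config = model_config(), seed = 1L) {
  task <- match.arg(task)
  if (config$exclude_additive) combos <- combos[combos$label != "additive", , drop = FALSE]
  if (!nrow(combos)) stop("empty training set")
  des <- mt_design(combos, drug_view, cell_view)
  y <- combos$loewe_score
  n <- nrow(combos)
  lab <- factor(as.character(combos$label), levels = SYNERGY_CLASSES)
  Y1hot <- matrix(0, n, 3L)
  Y1hot[cbind(seq_len(n), as.integer(lab))] <- 1
  nout <- if (task == "regression") 1L else 3L
  with_local_seed(seed, {
    params <- st_init_params(ncol(des$XA), ncol(des$XB), ncol(des$XC), config, nout)
    state <- adamw_init(params)
    bs <- min(config$batch_size, n)
    trace <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      idx <- sample.int(n)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, n, by = bs)) {
        rows <- idx[start:min(start + bs - 1L, n)]
        nb_rows <- length(rows)
        cache <- st_forward(params,
                            des$XA[rows, , drop = FALSE],
                            des$XB[rows, , drop = FALSE],
                            des$XC[rows, , drop = FALSE])
        if (task == "regression") {
          resid <- as.numeric(cache$out) - y[rows]
          loss <- sum(resid^2) / nb_rows
          dOut <- matrix(2 * resid / nb_rows, nb_rows, 1L)
        } else {
          P <- nn_softmax_rows(cache$out)
          Yb <- Y1hot[rows, , drop = FALSE]
          loss <- sum(-log(pmax(P, 1e-12)) * Yb) / nb_rows
          dOut <- (P - Yb) / nb_rows
        }
        grads <- st_backward(params, config, cache, dOut)
        upd <- adamw_step(params, grads, state, lr = config$learning_rate,
                          weight_decay = config$weight_decay)
        params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + loss; nb <- nb + 1L
      }
      trace[ep] <- ep_loss / nb
    }
    structure(list(params = params, config = config, task = task,
                   drug_view = drug_view$view_name,
                   cell_view = cell_view$view_name,
                   loss_trace = trace, seed = seed),
              class = "single_task_model")
  })
}

#' Predict with a single-task model
#'
#' @param object A `single_task_model`.
#' @param combos Combination table.
#' @param drug_view,cell_view Featurized views.
#' @param average_orientations Average over both drug orders (default `TRUE`).
#' @param ... Unused.
#' @return For regression: list with `score`; for classification: list with
#'   `class_probs`.
#' @export
predict.single_task_model <- function(object, combos, drug_view, cell_view,
                                      average_orientations = TRUE, ...) {
  des <- mt_design(combos, drug_view, cell_view)
  out <- st_forward(object$params, des$XA, des$XB, des$XC)$out
  if (object$task == "regression") {
    score <- as.numeric(out)
    if (average_orientations) {
      des2 <- mt_design(combos, drug_view, cell_view, flip = TRUE)
      score <- (score + as.numeric(st_forward(object$params, des2$XA, des2$XB,
                                              des2$XC)$out)) / 2
    }
    list(score = score)
  } else {
    P <- nn_softmax_rows(out)
    if (average_orientations) {
      des2 <- mt_design(combos, drug_view, cell_view, flip = TRUE)
      P <- (P + nn_softmax_rows(st_forward(object$params, des2$XA, des2$XB,
                                           des2$XC)$out)) / 2
    }
    dimnames(P) <- list(NULL, SYNERGY_CLASSES)
    list(class_probs = P)
  }
}
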