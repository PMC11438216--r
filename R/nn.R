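# Minimal internal neural-network toolkit: dense layers, activations and the
# AdamW optimizer, with hand-derived backward passes.  The multitask network
# and the VAE compose these pieces; correctness is pinned by
# finite-difference gradient tests in the test suite.

nn_dense_init <- function(nin, nout, scale = sqrt(2 / nin)) {
  list(W = matrix(stats::rnorm(nin * nout, sd = scale), nin, nout),
       b = numeric(nout))
}

nn_dense_forward <- function(layer, X) {
  sweep(X %*% layer$W, 2L, layer$b, "+")
}

# Backward through Z = X W + b: returns dX and accumulates dW, db.
nn_dense_backward <- function(layer, X, dZ) {
  list(dX = dZ %*% t(layer$W),
       dW = t(X) %*% dZ,
       db = colSums(dZ))
}

nn_relu <- function(Z) Z * (Z > 0)
nn_relu_backward <- function(Z, dA) dA * (Z > 0)

# PReLU with one learnable slope per layer (initialized 0.25 by callers).
nn_prelu <- function(Z, a) ifelse(Z > 0, Z, a * Z)
nn_prelu_backward <- function(Z, a, dA) {
  neg <- Z <= 0
  list(dZ = dA * ifelse(neg, a, 1),
       da = sum(dA * Z * neg))
}

nn_softmax_rows <- function(Z) {
  m <- apply(Z, 1L, max)
  E <- exp(Z - m)
  E / rowSums(E)
}

# L1+L2 penalty over a flat list of weight matrices (biases excluded by the
# callers, which pass only W entries).
nn_reg_loss <- function(weights, l1, l2) {
  s <- 0
  for (W in weights) s <- s + l1 * sum(abs(W)) + l2 * sum(W^2)
  s
}

nn_reg_grad <- function(W, l1, l2) l1 * sign(W) + 2 * l2 * W

# ---- AdamW over an arbitrary nested list of numeric arrays ----------------

adamw_init <- function(params) {
  zeros <- function(p) {
    if (is.list(p)) lapply(p, zeros)
    else if (is.null(dim(p))) numeric(length(p))
    else array(0, dim = dim(p))
  }
  list(m = zeros(params), v = zeros(params), t = 0L)
}

adamw_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (k in seq_along(p)) {
        r <- walk(p[[k]], g[[k]], m[[k]], v[[k]])
        out_p[[k]] <- r$p; out_m[[k]] <- r$m; out_v[[k]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * ((m / bc1) / (sqrt(v / bc2) + eps) + weight_decay * p)
    list(p = p, m = m, v = v)
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

# Map a function over two parallel nested lists of arrays (used to add
# gradient contributions).
nn_zip <- function(a, b, f) {
  if (is.list(a)) {
    for (k in seq_along(a)) a[[k]] <- nn_zip(a[[k]], b[[k]], f)
    a
  } else {
    f(a, b)
  }
}

nn_zeros_like <- function(params) {
  if (is.list(params)) lapply(params, nn_zeros_like)
  else if (is.matrix(params)) matrix(0, nrow(params), ncol(params))
  else numeric(length(params))
}
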