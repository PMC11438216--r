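# Cell-line views: multi-source merging by feature intersection, mutation
# binarization, and per-view variational-autoencoder compression to a fixed
# latent width followed by tanh normalization.

#' Merge omics matrices from multiple sources by feature intersection
#'
#' Different providers cover different cell lines; their matrices are merged
#' by keeping the intersection of feature names (in sorted order) and
#' stacking the rows.
#'
#' @param matrices List of `cell_view_matrix` objects with pairwise-disjoint
#'   cell-id sets.
#' @param view_name View label of the result (default: the first source's).
#' @return A single `cell_view_matrix`.
#' @export
merge_by_intersection <- function(matrices, view_name = matrices[[1L]]$view_name) {
  stopifnot(length(matrices) >= 1L)
  feats <- Reduce(intersect, lapply(matrices, `[[`, "feature_names"))
  if (!length(feats)) stop("empty feature intersection across sources")
  feats <- sort(feats)
  all_cells <- unlist(lapply(matrices, `[[`, "cell_ids"))
  if (anyDuplicated(all_cells)) {
    stop("overlapping cell ids across sources: ",
         paste(unique(all_cells[duplicated(all_cells)]), collapse = ", "))
  }
  m <- do.call(rbind, lapply(matrices, function(v) v$matrix[, feats, drop = FALSE]))
  cell_view_matrix(view_name, all_cells, m, feats)
}

#' Binarize a mutation matrix
#'
#' Any nonzero entry becomes 1, zero stays 0.  Idempotent on already-binary
#' matrices.
#'
#' @param x A numeric matrix or a `cell_view_matrix`.
#' @return Object of the same type with entries in \{0, 1\}.
#' @export
binarize_mutations <- function(x) {
  if (inherits(x, "cell_view_matrix")) {
    x$matrix <- binarize_mutations(x$matrix)
    return(x)
  }
  if (anyNA(x)) stop("NaN/NA entries in mutation matrix")
  m <- (x != 0) * 1
  dimnames(m) <- dimnames(x)
  m
}

#' KL divergence of a diagonal Gaussian to the unit Gaussian
#'
#' `-0.5 * sum(1 + log(sigma^2) - mu^2 - sigma^2)`, the standard nonnegative
#' Kullback-Leibler divergence KL(N(mu, sigma^2) || N(0, 1)) used as the
#' latent regularizer of the VAE.  It is zero exactly when `mu = 0` and
#' `sigma = 1`.
#'
#' @param mu Numeric vector of latent means.
#' @param sigma Numeric vector of latent standard deviations (positive).
#' @return Nonnegative scalar.
#' @export
kl_loss <- function(mu, sigma) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  stopifnot(length(mu) == length(sigma))
  -0.5 * sum(1 + log(sigma^2) - mu^2 - sigma^2)
}

vae_init_params <- function(input_dim, hidden, latent_dim) {
  enc <- list()
  nin <- input_dim
  for (h in hidden) { enc[[length(enc) + 1L]] <- nn_dense_init(nin, h); nin <- h }
  dec <- list()
  din <- latent_dim
  for (h in rev(hidden)) { dec[[length(dec) + 1L]] <- nn_dense_init(din, h); din <- h }
  list(enc = enc,
       mu = nn_dense_init(nin, latent_dim, scale = sqrt(1 / nin)),
       lv = nn_dense_init(nin, latent_dim, scale = sqrt(1 / nin)),
       dec = dec,
       out = nn_dense_init(din, input_dim, scale = sqrt(1 / din)))
}

# Forward pass; eps = NULL gives the deterministic mean path (z = mu).
vae_forward <- function(params, X, eps = NULL, lv_clamp = 8) {
  cache <- list(X = X, Zs = list(), As = list())
  A <- X
  for (i in seq_along(params$enc)) {
    Z <- nn_dense_forward(params$enc[[i]], A)
    cache$Zs[[i]] <- Z
    A <- nn_relu(Z)
    cache$As[[i]] <- A
  }
  mu <- nn_dense_forward(params$mu, A)
  lv_raw <- nn_dense_forward(params$lv, A)
  lv <- pmin(pmax(lv_raw, -lv_clamp), lv_clamp)
  z <- if (is.null(eps)) mu else mu + exp(0.5 * lv) * eps
  cache$enc_top <- A; cache$mu <- mu; cache$lv <- lv; cache$lv_raw <- lv_raw
  cache$z <- z; cache$eps <- eps
  cache$dZs <- list(); cache$dAs <- list()
  Ad <- z
  for (i in seq_along(params$dec)) {
    Zd <- nn_dense_forward(params$dec[[i]], Ad)
    cache$dZs[[i]] <- Zd
    Ad <- nn_relu(Zd)
    cache$dAs[[i]] <- Ad
  }
  cache$xhat <- nn_dense_forward(params$out, Ad)
  cache
}

vae_loss <- function(cache, X, beta) {
  n <- nrow(X)
  recon <- sum((cache$xhat - X)^2) / n
  klrow <- -0.5 * rowSums(1 + cache$lv - cache$mu^2 - exp(cache$lv))
  kl <- sum(klrow) / n
  list(loss = recon + beta * kl, recon = recon, kl = kl)
}

vae_backward <- function(params, cache, X, beta) {
  n <- nrow(X)
  grads <- nn_zeros_like(params)
  dxhat <- 2 * (cache$xhat - X) / n
  top_in <- if (length(params$dec)) cache$dAs[[length(params$dec)]] else cache$z
  bo <- nn_dense_backward(params$out, top_in, dxhat)
  grads$out$W <- bo$dW; grads$out$b <- bo$db
  dA <- bo$dX
  for (i in rev(seq_along(params$dec))) {
    dZ <- nn_relu_backward(cache$dZs[[i]], dA)
    below <- if (i > 1L) cache$dAs[[i - 1L]] else cache$z
    bd <- nn_dense_backward(params$dec[[i]], below, dZ)
    grads$dec[[i]]$W <- bd$dW; grads$dec[[i]]$b <- bd$db
    dA <- bd$dX
  }
  dz <- dA
  dmu <- dz + beta * cache$mu / n
  dlv <- -0.5 * beta * (1 - exp(cache$lv)) / n
  if (!is.null(cache$eps)) dlv <- dlv + dz * cache$eps * 0.5 * exp(0.5 * cache$lv)
  dlv <- dlv * (abs(cache$lv_raw) < 8)  # clamp region has zero slope outside
  bmu <- nn_dense_backward(params$mu, cache$enc_top, dmu)
  blv <- nn_dense_backward(params$lv, cache$enc_top, dlv)
  grads$mu$W <- bmu$dW; grads$mu$b <- bmu$db
  grads$lv$W <- blv$dW; grads$lv$b <- blv$db
  dA <- bmu$dX + blv$dX
  for (i in rev(seq_along(params$enc))) {
    dZ <- nn_relu_backward(cache$Zs[[i]], dA)
    below <- if (i > 1L) cache$As[[i - 1L]] else cache$X
    be <- nn_dense_backward(params$enc[[i]], below, dZ)
    grads$enc[[i]]$W <- be$dW; grads$enc[[i]]$b <- be$db
    dA <- be$dX
  }
  grads
}

#' Fit a variational autoencoder to one cell view
#'
#' Encoder (ReLU hidden stack) to a diagonal-Gaussian latent of width
#' `latent_dim`, mirror decoder, loss = per-sample reconstruction MSE (summed
#' over features) + `beta` x KL to the unit Gaussian, optimized with AdamW.
#' Training samples the latent via the reparameterization trick; compression
#' later uses the deterministic latent mean.
#'
#' @param view A `cell_view_matrix` of training cells.
#' @param latent_dim Compressed width (default 256; must be < feature count).
#' @param hidden Encoder hidden sizes (decoder mirrors them).
#' @param beta KL weight.
#' @param epochs,batch_size,lr AdamW training schedule.
#' @param seed Integer seed (weights, shuffling, reparameterization noise).
#' @param tanh_c Scale constant of the tanh normalization fitted on the
#'   training cells' latent means.
#' @return An object of class `view_compressor` (parameters, config, fitted
#'   latent tanh-norm, per-epoch loss trace).
#' @export
fit_view_vae <- function(view, latent_dim = 256L, hidden = c(1024L, 512L),
                         beta = 1, epochs = 200L, batch_size = 32L,
                         lr = 1e-3, seed = 1L, tanh_c = 0.01) {
  stopifnot(inherits(view, "cell_view_matrix"))
  X <- view$matrix
  if (latent_dim >= ncol(X)) {
    stop("latent_dim (", latent_dim, ") must be smaller than the input ",
         "dimension (", ncol(X), ")")
  }
  n <- nrow(X)
  with_local_seed(seed, {
    params <- vae_init_params(ncol(X), hidden, latent_dim)
    state <- adamw_init(params)
    trace <- numeric(epochs)
    bs <- min(batch_size, n)
    for (ep in seq_len(epochs)) {
      idx <- sample.int(n)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, n, by = bs)) {
        rows <- idx[start:min(start + bs - 1L, n)]
        Xb <- X[rows, , drop = FALSE]
        eps <- matrix(stats::rnorm(length(rows) * latent_dim),
                      length(rows), latent_dim)
        cache <- vae_forward(params, Xb, eps)
        l <- vae_loss(cache, Xb, beta)
        grads <- vae_backward(params, cache, Xb, beta)
        upd <- adamw_step(params, grads, state, lr = lr)
        params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + l$loss; nb <- nb + 1L
      }
      trace[ep] <- ep_loss / nb
    }
    mu_train <- vae_forward(params, X)$mu
    structure(list(params = params, latent_dim = as.integer(latent_dim),
                   hidden = hidden, beta = beta, view_name = view$view_name,
                   feature_names = view$feature_names,
                   norm = tanh_norm_fit(mu_train, c = tanh_c),
                   loss_trace = trace, seed = seed),
              class = "view_compressor")
  })
}

#' Compress a cell view with a fitted VAE
#'
#' Encodes each cell to its deterministic latent mean and applies the
#' tanh normalization fitted on the training cells, giving `latent_dim`
#' columns in (0,1).  Deterministic given the fitted compressor.
#'
#' @param compressor A `view_compressor` from [fit_view_vae()].
#' @param view A `cell_view_matrix` with the same features as the fit.
#' @return A `cell_view_matrix` with `latent_dim` columns.
#' @export
compress_view <- function(compressor, view) {
  stopifnot(inherits(compressor, "view_compressor"),
            inherits(view, "cell_view_matrix"))
  if (!identical(view$feature_names, compressor$feature_names)) {
    if (!setequal(view$feature_names, compressor$feature_names)) {
      stop("view features do not match the compressor's training features")
    }
    view$matrix <- view$matrix[, compressor$feature_names, drop = FALSE]
  }
  mu <- vae_forward(compressor$params, view$matrix)$mu
  z <- tanh_norm_apply(compressor$norm, mu)
  colnames(z) <- sprintf("latent%03d", seq_len(compressor$latent_dim))
  cell_view_matrix(view$view_name, view$cell_ids, z, colnames(z))
}
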