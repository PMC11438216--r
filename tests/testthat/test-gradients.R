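# Finite-difference verification of the hand-derived backward passes.

flatten_params <- function(x, prefix = "") {
  if (is.list(x)) {
    nm <- names(x)
    unlist(lapply(seq_along(x), function(i) {
      tag <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else as.character(i)
      flatten_params(x[[i]], paste0(prefix, "/", tag))
    }), recursive = FALSE)
  } else {
    stats::setNames(list(x), prefix)
  }
}

perturb_param <- function(params, path_str, ix, delta) {
  path <- strsplit(sub("^/", "", path_str), "/")[[1]]
  expr <- "params"
  for (k in path) {
    expr <- paste0(expr, "[[", if (grepl("^[0-9]+$", k)) k
                   else paste0("\"", k, "\""), "]]")
  }
  val <- eval(parse(text = expr))
  val[ix] <- val[ix] + delta
  eval(parse(text = paste0(expr, " <- val")))
  params
}

check_grads <- function(params, grads, lossfun, n_per_param = 3L, tol = 1e-4) {
  pf <- flatten_params(params)
  gf <- flatten_params(grads)
  for (nm in names(pf)) {
    v <- pf[[nm]]
    for (ix in sample(length(v), min(n_per_param, length(v)))) {
      h <- 1e-6
      num <- (lossfun(perturb_param(params, nm, ix, h)) -
                lossfun(perturb_param(params, nm, ix, -h))) / (2 * h)
      ana <- gf[[nm]][ix]
      rel <- abs(num - ana) / max(1e-6, abs(num) + abs(ana))
      expect_lt(rel, tol, label = paste0("gradient at ", nm, "[", ix, "]"))
    }
  }
}

test_that("multitask network gradients match finite differences", {
  set.seed(42)
  cfg <- model_config(encoder_hidden = c(6L, 4L), head_hidden = c(5L, 4L),
                      attention_heads = 2L)
  n <- 5; pA <- 7; pC <- 6
  XA <- matrix(rnorm(n * pA), n); XB <- matrix(rnorm(n * pA), n)
  XC <- matrix(rnorm(n * pC), n)
  y <- rnorm(n, 10, 5)
  lab <- sample(c("antagonistic", "additive", "synergistic"), n, replace = TRUE)
  Y <- matrix(0, n, 3)
  Y[cbind(1:n, as.integer(factor(lab, levels = c("antagonistic", "additive",
                                                 "synergistic"))))] <- 1
  params <- mvsynergy:::mt_init_params(pA, pA, pC, cfg)
  lossfun <- function(p) {
    cache <- mvsynergy:::mt_forward(p, cfg, XA, XB, XC)
    mvsynergy:::mt_loss(p, cfg, cache, y, Y)$loss
  }
  cache <- mvsynergy:::mt_forward(params, cfg, XA, XB, XC)
  grads <- mvsynergy:::mt_backward(params, cfg, cache, y, Y)
  check_grads(params, grads, lossfun)
})

test_that("per-dimension cross-stitch gradients match finite differences", {
  set.seed(43)
  cfg <- model_config(encoder_hidden = c(5L, 4L), head_hidden = c(4L),
                      attention_heads = 2L, per_dim_cross_stitch = TRUE)
  n <- 4; p <- 5
  XA <- matrix(rnorm(n * p), n); XB <- matrix(rnorm(n * p), n)
  XC <- matrix(rnorm(n * p), n)
  y <- rnorm(n); lab <- rep(c("additive", "synergistic"), 2)
  Y <- matrix(0, n, 3)
  Y[cbind(1:n, as.integer(factor(lab, levels = c("antagonistic", "additive",
                                                 "synergistic"))))] <- 1
  params <- mvsynergy:::mt_init_params(p, p, p, cfg)
  expect_length(params$alpha$a11, 4L * 4L)  # one coefficient per stream dimension
  lossfun <- function(pp) {
    cache <- mvsynergy:::mt_forward(pp, cfg, XA, XB, XC)
    mvsynergy:::mt_loss(pp, cfg, cache, y, Y)$loss
  }
  cache <- mvsynergy:::mt_forward(params, cfg, XA, XB, XC)
  grads <- mvsynergy:::mt_backward(params, cfg, cache, y, Y)
  check_grads(params, grads, lossfun)
})

test_that("VAE gradients match finite differences", {
  set.seed(7)
  p <- 9; n <- 4; lat <- 3
  params <- mvsynergy:::vae_init_params(p, c(6L), lat)
  X <- matrix(rnorm(n * p), n)
  eps <- matrix(rnorm(n * lat), n)
  beta <- 0.7
  lossfun <- function(pp) {
    cache <- mvsynergy:::vae_forward(pp, X, eps)
    mvsynergy:::vae_loss(cache, X, beta)$loss
  }
  cache <- mvsynergy:::vae_forward(params, X, eps)
  grads <- mvsynergy:::vae_backward(params, cache, X, beta)
  check_grads(params, grads, lossfun)
})

test_that("single-task network gradients match finite differences", {
  set.seed(9)
  cfg <- model_config(encoder_hidden = c(5L, 4L), head_hidden = c(4L),
                      attention_heads = 2L)
  n <- 4; p <- 5
  XA <- matrix(rnorm(n * p), n); XB <- matrix(rnorm(n * p), n)
  XC <- matrix(rnorm(n * p), n)
  y <- rnorm(n)
  params <- mvsynergy:::st_init_params(p, p, p, cfg, 1L)
  lossfun <- function(pp) {
    cache <- mvsynergy:::st_forward(pp, XA, XB, XC)
    resid <- as.numeric(cache$out) - y
    sum(resid^2) / n +
      mvsynergy:::nn_reg_loss(c(lapply(pp$encA, `[[`, "W"),
                                lapply(pp$encB, `[[`, "W"),
                                lapply(pp$encC, `[[`, "W"),
                                lapply(pp$head$layers, `[[`, "W"),
                                list(pp$head$out$W)), cfg$l1, cfg$l2) +
      local({
        outs <- c(cache$encA$As, cache$encB$As, cache$encC$As, cache$hd$Hs)
        s <- 0
        for (A in outs) s <- s + cfg$activity_l1 * sum(abs(A)) +
          cfg$activity_l2 * sum(A^2)
        s / n
      })
  }
  cache <- mvsynergy:::st_forward(params, XA, XB, XC)
  resid <- as.numeric(cache$out) - y
  grads <- mvsynergy:::st_backward(params, cfg, cache,
                                   matrix(2 * resid / n, n, 1L))
  check_grads(params, grads, lossfun)
})

test_that("task losses stay isolated except through shared attention and cross-stitch", {
  set.seed(10)
  cfg <- model_config(encoder_hidden = c(5L, 4L), head_hidden = c(4L),
                      attention_heads = 2L, l1 = 0, l2 = 0,
                      activity_l1 = 0, activity_l2 = 0,
                      lambda_reg = 1, lambda_cls = 0)
  n <- 4; p <- 5
  XA <- matrix(rnorm(n * p), n); XB <- matrix(rnorm(n * p), n)
  XC <- matrix(rnorm(n * p), n)
  y <- rnorm(n)
  Y <- matrix(1 / 3, n, 3)
  params <- mvsynergy:::mt_init_params(p, p, p, cfg)
  cache <- mvsynergy:::mt_forward(params, cfg, XA, XB, XC)
  grads <- mvsynergy:::mt_backward(params, cfg, cache, y, Y)
  # with zero classification weight, the classification head receives no
  # gradient at all...
  zero <- function(g) all(vapply(flatten_params(g), function(v)
    all(abs(v) < 1e-14), logical(1)))
  expect_true(zero(grads$head_cls))
  # ...but the regression loss still reaches the shared attention parameters
  # (both task streams mix in the cross-stitch before the regression head)
  expect_false(zero(grads$att))
  expect_false(zero(grads$encA))
  # and symmetrically for the regression head under lambda_reg = 0
  cfg2 <- cfg; cfg2$lambda_reg <- 0; cfg2$lambda_cls <- 1
  lab <- factor(rep(c("additive", "synergistic"), 2),
                levels = c("antagonistic", "additive", "synergistic"))
  Y2 <- matrix(0, n, 3); Y2[cbind(1:n, as.integer(lab))] <- 1
  grads2 <- mvsynergy:::mt_backward(params, cfg2, cache, y, Y2)
  expect_true(zero(grads2$head_reg))
  expect_false(zero(grads2$head_cls))
})
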