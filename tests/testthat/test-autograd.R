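# The autodiff tape is the substrate of the window classifier; every op's
# hand-derived gradient is checked against central finite differences.

sv <- asNamespace("svscout")

num_grad <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

# Runs op_fun on leaf nodes built from inputs, backprops a fixed random
# cotangent and compares each input's gradient with finite differences.
check_op <- function(op_fun, inputs, tol = 1e-5) {
  set.seed(400)
  out0 <- local({
    leaves <- lapply(inputs, sv$ag_leaf)
    do.call(op_fun, leaves)$val
  })
  ct <- matrix(stats::rnorm(length(out0)), nrow(out0), ncol(out0))
  scalar <- function(xs) {
    leaves <- lapply(xs, sv$ag_leaf)
    sum(do.call(op_fun, leaves)$val * ct)
  }
  sv$ag_tape_start()
  leaves <- lapply(inputs, sv$ag_leaf)
  out <- do.call(op_fun, leaves)
  # seed the cotangent by building sum(out * ct) with primitive ops
  loss <- sv$ag_node(matrix(sum(out$val * ct), 1, 1),
                     backward = local({
                       o <- out
                       function(g) sv$ag_accum(o, as.numeric(g) * ct)
                     }))
  sv$ag_backward(loss)
  for (k in seq_along(inputs)) {
    ana <- leaves[[k]]$grad
    if (is.null(ana)) ana <- inputs[[k]] * 0
    num <- num_grad(function(x) {
      xs <- inputs; xs[[k]] <- x
      scalar(xs)
    }, inputs[[k]])
    expect_lt(max(abs(ana - num)) / max(1, max(abs(num))), tol)
  }
  sv$ag_tape_stop()
}

test_that("matmul, add, mul and pointwise op gradients match finite differences", {
  set.seed(11)
  A <- matrix(rnorm(12), 3, 4); B <- matrix(rnorm(8), 4, 2)
  check_op(function(a, b) sv$ag_matmul(a, b), list(A, B))
  check_op(function(a, b) sv$ag_add(a, b), list(A, A + 1))
  check_op(function(a, b) sv$ag_add(a, b), list(A, matrix(rnorm(4), 1, 4)))
  check_op(function(a, b) sv$ag_mul(a, b), list(A, A * 2))
  check_op(function(a, b) sv$ag_mul(a, b), list(A, matrix(rnorm(3), 3, 1)))
  check_op(function(a) sv$ag_relu(a), list(A))
  check_op(function(a) sv$ag_sigmoid(a), list(A))
  check_op(function(a) sv$ag_softmax_rows(a), list(A))
})

test_that("structural op gradients (gather, pooling, im2col, cbind, norms) are exact", {
  set.seed(12)
  X <- matrix(rnorm(48), 12, 4)
  check_op(function(a) sv$ag_gather(a, c(1L, 1L, 3L, 5L, 12L)), list(X))
  check_op(function(a) sv$ag_block_mean(a, 3L), list(X))
  check_op(function(a) sv$ag_block_max(a, 3L), list(X))
  check_op(function(a) sv$ag_rowmean(a), list(X))
  check_op(function(a) sv$ag_rowmax(a), list(X))
  check_op(function(a) sv$ag_im2col(a, 6L, 3L), list(X))
  check_op(function(a, b) sv$ag_cbind(list(a, b)), list(X, X * 2))
  check_op(function(a) sv$ag_cols(a, c(2L, 4L)), list(X))
  g <- matrix(rnorm(4), 1, 4); b <- matrix(rnorm(4), 1, 4)
  check_op(function(a, gg, bb) sv$ag_layernorm(a, gg, bb), list(X, g, b),
           tol = 1e-4)
})

test_that("fused attention gradients match finite differences, with masking", {
  set.seed(13)
  T <- 4L; B <- 3L; dh <- 5L
  Q <- matrix(rnorm(T * B * dh), T * B, dh)
  K <- matrix(rnorm(T * B * dh), T * B, dh)
  V <- matrix(rnorm(T * B * dh), T * B, dh)
  valid <- rep(TRUE, T * B); valid[c(4L, 8L)] <- FALSE
  check_op(function(q, k, v) sv$ag_attention(q, k, v, T, valid), list(Q, K, V),
           tol = 1e-4)
})

test_that("weighted logistic loss gradient and whole-model backprop are correct", {
  set.seed(14)
  z <- matrix(rnorm(8), 8, 1)
  y <- rep(c(0, 1), 4); w <- c(1, 2, 1, 0, 1, 2, 1, 1)
  check_op(function(a) sv$ag_bce_logits(a, y, w), list(z))

  cfg <- sv$sv_model_config(conv_channels = c(4L, 6L), kernel = 3L,
                            input_pool = 2L, pool = 4L,
                            attention_reduction = 2L, spatial_kernel = 3L,
                            embed_dim = 8L, n_heads = 2L, n_layers = 1L,
                            ff_dim = 12L, dropout = 0, seed = 3L)
  set.seed(3)
  params <- sv$init_params(cfg)
  x <- matrix(rexp(2000 * 20, 2), 2000L, 20L)
  valid <- rep(TRUE, 10L)
  y <- rep(c(0, 1), 5L)
  w <- ifelse(y == 1, 3, 1)
  lossfun <- function(p) {
    fw <- sv$model_forward(p, cfg, x, valid, training = FALSE)
    zz <- as.vector(fw$logits$val)
    sum(w * (pmax(zz, 0) - y * zz + log1p(exp(-abs(zz))))) / sum(w)
  }
  sv$ag_tape_start()
  fw <- sv$model_forward(params, cfg, x, valid, training = FALSE)
  loss <- sv$ag_bce_logits(fw$logits, y, w)
  sv$ag_backward(loss)
  grads <- lapply(fw$leaves, function(nd) nd$grad)
  sv$ag_tape_stop()
  set.seed(5)
  for (nm in c("cw1", "cw2", "ca_w1", "sp_w", "pw", "l1_wq", "l1_ff1",
               "l1_ln1_g", "lnf_g", "hw")) {
    g <- grads[[nm]]
    expect_false(is.null(g), info = nm)
    for (i in sample(length(params[[nm]]), 2L)) {
      eps <- 1e-5
      p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
      num <- (lossfun(p1) - lossfun(p2)) / (2 * eps)
      expect_lt(abs(num - g[i]) / max(1e-6, abs(num) + abs(g[i])), 1e-4,
                label = sprintf("param %s[%d] relative gradient error", nm, i))
    }
  }
})
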