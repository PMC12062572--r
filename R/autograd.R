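# Reverse-mode automatic differentiation over base-R matrices.
#
# A global tape records nodes in forward order; ag_backward() walks it in
# reverse, each node distributing its upstream gradient to its inputs via a
# closure. Every op gradient is exercised against central finite differences
# in the test suite. The engine only supports what the window classifier
# needs: dense matmul, broadcast add/mul, pointwise nonlinearities, row
# softmax / layer norm, block pooling, im2col for 1-D convolution, a fused
# scaled-dot-product attention, dropout and a weighted logistic loss.

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL
.ag$n <- 0L

#' @noRd
ag_tape_start <- function() {
  .ag$tape <- vector("list", 256L)
  .ag$n <- 0L
  invisible(NULL)
}

#' @noRd
ag_tape_stop <- function() {
  .ag$tape <- NULL
  .ag$n <- 0L
  invisible(NULL)
}

ag_push <- function(node) {
  if (!is.null(.ag$tape)) {
    n <- .ag$n + 1L
    if (n > length(.ag$tape)) .ag$tape <- c(.ag$tape, vector("list", length(.ag$tape)))
    .ag$tape[[n]] <- node
    .ag$n <- n
  }
  node
}

ag_node <- function(val, backward = NULL) {
  node <- new.env(parent = emptyenv())
  node$val <- val
  node$grad <- NULL
  node$backward <- backward
  class(node) <- "ag_node"
  ag_push(node)
}

#' @noRd
ag_leaf <- function(val) {
  if (!is.matrix(val)) val <- as.matrix(val)
  ag_node(val)
}

ag_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

#' Run backpropagation from a scalar loss node through the active tape.
#' @noRd
ag_backward <- function(loss) {
  if (is.null(.ag$tape)) stop("no active autodiff tape; call ag_tape_start() first")
  loss$grad <- matrix(1, 1L, 1L)
  for (i in seq(.ag$n, 1L)) {
    nd <- .ag$tape[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

# ---- primitive ops ---------------------------------------------------------

ag_matmul <- function(a, b) {
  av <- a$val; bv <- b$val
  ag_node(av %*% bv, function(g) {
    ag_accum(a, g %*% t(bv))
    ag_accum(b, t(av) %*% g)
  })
}

# b may be a 1 x C bias row, broadcast over the rows of a.
ag_add <- function(a, b) {
  av <- a$val; bv <- b$val
  if (nrow(bv) == 1L && nrow(av) > 1L) {
    out <- av + rep(as.vector(bv), each = nrow(av))
    ag_node(out, function(g) {
      ag_accum(a, g)
      ag_accum(b, matrix(colSums(g), 1L))
    })
  } else {
    ag_node(av + bv, function(g) {
      ag_accum(a, g)
      ag_accum(b, g)
    })
  }
}

# Elementwise product; b may be an N x 1 column, broadcast over columns of a.
ag_mul <- function(a, b) {
  av <- a$val; bv <- b$val
  if (ncol(bv) == 1L && ncol(av) > 1L) {
    bb <- as.vector(bv)
    ag_node(av * bb, function(g) {
      ag_accum(a, g * bb)
      ag_accum(b, matrix(rowSums(g * av), ncol = 1L))
    })
  } else {
    ag_node(av * bv, function(g) {
      ag_accum(a, g * bv)
      ag_accum(b, g * av)
    })
  }
}

ag_relu <- function(a) {
  av <- a$val
  pos <- av > 0
  ag_node(av * pos, function(g) ag_accum(a, g * pos))
}

ag_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$val))
  ag_node(s, function(g) ag_accum(a, g * s * (1 - s)))
}

ag_softmax_rows <- function(a) {
  av <- a$val
  m <- av - apply(av, 1L, max)
  e <- exp(m)
  p <- e / rowSums(e)
  ag_node(p, function(g) ag_accum(a, p * (g - rowSums(g * p))))
}

# Per-row layer normalisation with learned gain/offset (1 x C each).
ag_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  av <- a$val
  C <- ncol(av)
  mu <- rowMeans(av)
  xc <- av - mu
  sd <- sqrt(rowSums(xc * xc) / C + eps)
  xhat <- xc / sd
  gv <- as.vector(gamma$val)
  out <- xhat * rep(gv, each = nrow(av)) + rep(as.vector(beta$val), each = nrow(av))
  ag_node(out, function(g) {
    ag_accum(gamma, matrix(colSums(g * xhat), 1L))
    ag_accum(beta, matrix(colSums(g), 1L))
    dxhat <- g * rep(gv, each = nrow(g))
    dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / sd
    ag_accum(a, dx)
  })
}

# Column selection (used to split attention heads).
ag_cols <- function(a, idx) {
  av <- a$val
  ag_node(av[, idx, drop = FALSE], function(g) {
    da <- matrix(0, nrow(av), ncol(av))
    da[, idx] <- g
    ag_accum(a, da)
  })
}

ag_cbind <- function(nodes) {
  vals <- lapply(nodes, function(n) n$val)
  widths <- vapply(vals, ncol, 0L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ag_node(do.call(cbind, vals), function(g) {
    for (i in seq_along(nodes)) {
      ag_accum(nodes[[i]], g[, starts[i]:ends[i], drop = FALSE])
    }
  })
}

# Mean over consecutive row blocks of length L: (G*L) x C -> G x C.
ag_block_mean <- function(a, L) {
  av <- a$val
  G <- nrow(av) %/% L
  grp <- rep(seq_len(G), each = L)
  out <- rowsum(av, grp, reorder = FALSE) / L
  ag_node(out, function(g) {
    ag_accum(a, g[grp, , drop = FALSE] / L)
  })
}

# Max over consecutive row blocks of length L: (G*L) x C -> G x C.
ag_block_max <- function(a, L) {
  av <- a$val
  N <- nrow(av); C <- ncol(av)
  G <- N %/% L
  M <- matrix(as.vector(av), L, G * C)   # column j <-> (g, c), g fastest
  amax <- max.col(t(M), ties.method = "first")
  j <- seq_len(G * C)
  gi <- ((j - 1L) %% G) + 1L
  ci <- ((j - 1L) %/% G) + 1L
  lin <- (ci - 1L) * N + (gi - 1L) * L + amax
  out <- matrix(M[cbind(amax, j)], G, C)
  ag_node(out, function(g) {
    da <- numeric(N * C)
    da[lin] <- da[lin] + as.vector(g)
    ag_accum(a, matrix(da, N, C))
  })
}

# Row-wise mean / max over columns -> N x 1 (spatial attention inputs).
ag_rowmean <- function(a) {
  av <- a$val
  C <- ncol(av)
  ag_node(matrix(rowMeans(av), ncol = 1L), function(g) {
    ag_accum(a, matrix(as.vector(g) / C, nrow(av), C))
  })
}

ag_rowmax <- function(a) {
  av <- a$val
  amax <- max.col(av, ties.method = "first")
  N <- nrow(av)
  lin <- (amax - 1L) * N + seq_len(N)
  ag_node(matrix(av[cbind(seq_len(N), amax)], ncol = 1L), function(g) {
    da <- numeric(N * ncol(av))
    da[lin] <- as.vector(g)
    ag_accum(a, matrix(da, N, ncol(av)))
  })
}

# im2col over the position axis of consecutive blocks of L rows, kernel k
# (odd), zero padding. (G*L) x C -> (G*L) x (k*C); tap t occupies columns
# ((t-1)*C+1):(t*C).
ag_im2col_idx <- function(N, L, k) {
  G <- N %/% L
  pad <- (k - 1L) %/% 2L
  pos <- rep(seq_len(L), G)
  base <- rep((seq_len(G) - 1L) * L, each = L)
  idx <- matrix(0L, N, k)
  for (t in seq_len(k)) {
    src <- pos + (t - 1L) - pad
    ok <- src >= 1L & src <= L
    idx[, t] <- ifelse(ok, base + src, 0L)
  }
  idx
}

ag_im2col <- function(a, L, k) {
  av <- a$val
  N <- nrow(av); C <- ncol(av)
  idx <- ag_im2col_idx(N, L, k)
  xp <- rbind(matrix(0, 1L, C), av)
  out <- matrix(0, N, k * C)
  for (t in seq_len(k)) {
    out[, ((t - 1L) * C + 1L):(t * C)] <- xp[idx[, t] + 1L, , drop = FALSE]
  }
  ag_node(out, function(g) {
    da <- matrix(0, N, C)
    for (t in seq_len(k)) {
      gt <- g[, ((t - 1L) * C + 1L):(t * C), drop = FALSE]
      keep <- idx[, t] > 0L
      if (any(keep)) {
        rs <- rowsum(gt[keep, , drop = FALSE], idx[keep, t], reorder = FALSE)
        rows <- as.integer(rownames(rs))
        da[rows, ] <- da[rows, ] + rs
      }
    }
    ag_accum(a, da)
  })
}

# Row gather (duplication allowed): out[i, ] = a[idx[i], ].
ag_gather <- function(a, idx) {
  av <- a$val
  ag_node(av[idx, , drop = FALSE], function(g) {
    rs <- rowsum(g, idx, reorder = FALSE)
    da <- matrix(0, nrow(av), ncol(av))
    rows <- as.integer(rownames(rs))
    da[rows, ] <- rs
    ag_accum(a, da)
  })
}

ag_dropout <- function(a, p) {
  if (p <= 0) return(a)
  av <- a$val
  mask <- matrix((stats::runif(length(av)) >= p) / (1 - p), nrow(av), ncol(av))
  ag_node(av * mask, function(g) ag_accum(a, g * mask))
}

# Fused scaled-dot-product attention over T tokens per window. q, k, v are
# (B*T) x dh with window-major rows (window b occupies rows (b-1)*T+1 .. b*T).
# `valid` is a logical vector of length B*T; invalid tokens are excluded as
# keys (their output rows are handled downstream by the probability mask).
ag_attention <- function(q, k, v, T, valid = NULL) {
  qv <- q$val; kv <- k$val; vv <- v$val
  dh <- ncol(qv)
  B <- nrow(qv) %/% T
  scale <- 1 / sqrt(dh)
  Qa <- array(qv, c(T, B, dh))
  Ka <- array(kv, c(T, B, dh))
  Va <- array(vv, c(T, B, dh))
  vmask <- if (is.null(valid)) matrix(TRUE, T, B) else matrix(valid, T, B)
  # scores and row-softmax over keys j, per (window, query i)
  P <- array(0, c(B, T, T))
  for (i in seq_len(T)) {
    S <- matrix(-Inf, B, T)
    Qi <- matrix(Qa[i, , ], B, dh)
    for (j in seq_len(T)) {
      sj <- rowSums(Qi * matrix(Ka[j, , ], B, dh)) * scale
      sj[!vmask[j, ]] <- -Inf
      S[, j] <- sj
    }
    mx <- apply(S, 1L, max)
    E <- exp(S - mx)
    P[, i, ] <- E / rowSums(E)
  }
  Oa <- array(0, c(T, B, dh))
  for (i in seq_len(T)) {
    Oi <- matrix(0, B, dh)
    for (j in seq_len(T)) {
      Oi <- Oi + P[, i, j] * matrix(Va[j, , ], B, dh)
    }
    Oa[i, , ] <- Oi
  }
  out <- matrix(as.vector(Oa), B * T, dh)
  ag_node(out, function(g) {
    Ga <- array(g, c(T, B, dh))
    dQ <- array(0, c(T, B, dh))
    dK <- array(0, c(T, B, dh))
    dV <- array(0, c(T, B, dh))
    for (i in seq_len(T)) {
      Gi <- matrix(Ga[i, , ], B, dh)
      dP <- matrix(0, B, T)
      for (j in seq_len(T)) {
        dV[j, , ] <- matrix(dV[j, , ], B, dh) + P[, i, j] * Gi
        dP[, j] <- rowSums(Gi * matrix(Va[j, , ], B, dh))
      }
      Pi <- matrix(P[, i, ], B, T)
      dS <- Pi * (dP - rowSums(dP * Pi))
      Qi <- matrix(Qa[i, , ], B, dh)
      for (j in seq_len(T)) {
        dQ[i, , ] <- matrix(dQ[i, , ], B, dh) + dS[, j] * matrix(Ka[j, , ], B, dh) * scale
        dK[j, , ] <- matrix(dK[j, , ], B, dh) + dS[, j] * Qi * scale
      }
    }
    ag_accum(q, matrix(as.vector(dQ), B * T, dh))
    ag_accum(k, matrix(as.vector(dK), B * T, dh))
    ag_accum(v, matrix(as.vector(dV), B * T, dh))
  })
}

# Numerically stable weighted binary cross-entropy on logits. z: N x 1 node;
# y, w: plain numeric vectors (w = 0 drops a token, e.g. padding).
ag_bce_logits <- function(z, y, w) {
  zv <- as.vector(z$val)
  wsum <- sum(w)
  l <- pmax(zv, 0) - y * zv + log1p(exp(-abs(zv)))
  out <- matrix(sum(w * l) / wsum, 1L, 1L)
  ag_node(out, function(g) {
    s <- 1 / (1 + exp(-zv))
    ag_accum(z, matrix(as.numeric(g) * w * (s - y) / wsum, ncol = 1L))
  })
}

# ---- Adam optimiser --------------------------------------------------------

#' @noRd
adam_state <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

#' @noRd
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
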