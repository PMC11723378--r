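# Minimal reverse-mode automatic differentiation on matrices.
#
# The recurrent (LSTM) and attention (transformer) classifiers are trained
# through this tape rather than the compiled convolutional engine: they are
# used at small scale, where clarity and gradient correctness matter more
# than throughput. Each op records its parents and a backward closure; the
# tape is replayed in reverse to accumulate gradients. Gradient correctness
# is pinned against finite differences in the test suite.

ad_tape <- function() {
  new.env(parent = emptyenv())
}

ad_node <- function(tape, value, parents = list(), backward = NULL,
                    param = FALSE) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$backward <- backward
  node$param <- param
  if (is.null(tape$nodes)) tape$nodes <- list()
  tape$nodes[[length(tape$nodes) + 1L]] <- node
  node
}

ad_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
}

ad_const <- function(tape, value) ad_node(tape, value)
ad_param <- function(tape, value) ad_node(tape, value, param = TRUE)

ad_mm <- function(tape, a, b) {
  ad_node(tape, a$value %*% b$value, list(a, b), function(node) {
    ad_accum(a, node$grad %*% t(b$value))
    ad_accum(b, t(a$value) %*% node$grad)
  })
}

# a + b; b may be a 1-row matrix broadcast over rows of a
ad_add <- function(tape, a, b) {
  bv <- b$value
  broadcast <- nrow(bv) == 1L && nrow(a$value) > 1L
  val <- if (broadcast) sweep(a$value, 2, bv[1, ], "+") else a$value + bv
  ad_node(tape, val, list(a, b), function(node) {
    ad_accum(a, node$grad)
    ad_accum(b, if (broadcast) matrix(colSums(node$grad), 1) else node$grad)
  })
}

ad_mul <- function(tape, a, b) {
  ad_node(tape, a$value * b$value, list(a, b), function(node) {
    ad_accum(a, node$grad * b$value)
    ad_accum(b, node$grad * a$value)
  })
}

ad_scale <- function(tape, a, s) {
  ad_node(tape, a$value * s, list(a), function(node) {
    ad_accum(a, node$grad * s)
  })
}

ad_tanh <- function(tape, a) {
  v <- tanh(a$value)
  ad_node(tape, v, list(a), function(node) {
    ad_accum(a, node$grad * (1 - v^2))
  })
}

ad_sigmoid <- function(tape, a) {
  v <- 1 / (1 + exp(-a$value))
  ad_node(tape, v, list(a), function(node) {
    ad_accum(a, node$grad * v * (1 - v))
  })
}

ad_relu <- function(tape, a) {
  mask <- a$value > 0
  ad_node(tape, a$value * mask, list(a), function(node) {
    ad_accum(a, node$grad * mask)
  })
}

ad_cols <- function(tape, a, idx) {
  ad_node(tape, a$value[, idx, drop = FALSE], list(a), function(node) {
    g <- matrix(0, nrow(a$value), ncol(a$value))
    g[, idx] <- node$grad
    ad_accum(a, g)
  })
}

ad_cbind <- function(tape, a, b) {
  na <- ncol(a$value)
  ad_node(tape, cbind(a$value, b$value), list(a, b), function(node) {
    ad_accum(a, node$grad[, seq_len(na), drop = FALSE])
    ad_accum(b, node$grad[, -seq_len(na), drop = FALSE])
  })
}

# fixed multiplicative mask (inverted dropout; mask supplied by the caller)
ad_dropmask <- function(tape, a, mask) {
  ad_node(tape, a$value * mask, list(a), function(node) {
    ad_accum(a, node$grad * mask)
  })
}

# mean over each sample's `t_len` consecutive rows: (n*t_len x d) -> (n x d)
ad_pool_mean <- function(tape, a, n, t_len) {
  grp <- rep(seq_len(n), each = t_len)
  val <- rowsum(a$value, grp) / t_len
  ad_node(tape, val, list(a), function(node) {
    ad_accum(a, node$grad[grp, , drop = FALSE] / t_len)
  })
}

# per-row layer normalization with learned gain/bias (1 x d parameters)
ad_layernorm <- function(tape, a, gamma, beta, eps = 1e-5) {
  x <- a$value
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  val <- sweep(xhat, 2, gamma$value[1, ], "*")
  val <- sweep(val, 2, beta$value[1, ], "+")
  ad_node(tape, val, list(a, gamma, beta), function(node) {
    g <- node$grad
    ad_accum(gamma, matrix(colSums(g * xhat), 1))
    ad_accum(beta, matrix(colSums(g), 1))
    dxhat <- sweep(g, 2, gamma$value[1, ], "*")
    d <- ncol(x)
    dx <- inv * (dxhat - rowMeans(dxhat) -
                   xhat * rowMeans(dxhat * xhat))
    ad_accum(a, dx)
  })
}

# scaled dot-product attention within each sample's block of `t_len` rows
ad_attention <- function(tape, q, k, v, n, t_len) {
  dk <- ncol(q$value)
  probs <- vector("list", n)
  out <- matrix(0, n * t_len, dk)
  for (i in seq_len(n)) {
    rows <- (i - 1) * t_len + seq_len(t_len)
    s <- q$value[rows, , drop = FALSE] %*%
      t(k$value[rows, , drop = FALSE]) / sqrt(dk)
    s <- s - apply(s, 1, max)
    p <- exp(s)
    p <- p / rowSums(p)
    probs[[i]] <- p
    out[rows, ] <- p %*% v$value[rows, , drop = FALSE]
  }
  ad_node(tape, out, list(q, k, v), function(node) {
    gq <- matrix(0, n * t_len, dk)
    gk <- gq
    gv <- gq
    for (i in seq_len(n)) {
      rows <- (i - 1) * t_len + seq_len(t_len)
      p <- probs[[i]]
      go <- node$grad[rows, , drop = FALSE]
      gv[rows, ] <- t(p) %*% go
      gp <- go %*% t(v$value[rows, , drop = FALSE])
      gs <- p * (gp - rowSums(gp * p))
      gq[rows, ] <- gs %*% k$value[rows, , drop = FALSE] / sqrt(dk)
      gk[rows, ] <- t(gs) %*% q$value[rows, , drop = FALSE] / sqrt(dk)
    }
    ad_accum(q, gq)
    ad_accum(k, gk)
    ad_accum(v, gv)
  })
}

# mean softmax cross-entropy against integer labels in {0, 1, ...}
ad_softmax_ce <- function(tape, logits, y) {
  z <- logits$value
  z <- z - apply(z, 1, max)
  e <- exp(z)
  p <- e / rowSums(e)
  n <- nrow(z)
  pick <- cbind(seq_len(n), y + 1L)
  loss <- -mean(log(pmax(p[pick], 1e-12)))
  ad_node(tape, matrix(loss), list(logits), function(node) {
    g <- p
    g[pick] <- g[pick] - 1
    ad_accum(logits, g / n * node$grad[1, 1])
  })
}

# reverse sweep from `loss` (a 1x1 node); fills $grad of all reachable nodes
ad_backward <- function(tape, loss) {
  for (node in tape$nodes) node$grad <- NULL
  loss$grad <- matrix(1)
  for (node in rev(tape$nodes)) {
    if (!is.null(node$grad) && !is.null(node$backward)) node$backward(node)
  }
  invisible(NULL)
}

# one Adam update over a flat list of parameter matrices held in `state`
ad_adam_step <- function(state, params, lr = 1e-3, b1 = 0.9, b2 = 0.999,
                         eps = 1e-8) {
  state$t <- (state$t %||% 0) + 1
  if (is.null(state$m)) {
    state$m <- lapply(params, function(p) p$value * 0)
    state$v <- lapply(params, function(p) p$value * 0)
  }
  for (j in seq_along(params)) {
    g <- params[[j]]$grad
    if (is.null(g)) next
    state$m[[j]] <- b1 * state$m[[j]] + (1 - b1) * g
    state$v[[j]] <- b2 * state$v[[j]] + (1 - b2) * g^2
    mh <- state$m[[j]] / (1 - b1^state$t)
    vh <- state$v[[j]] / (1 - b2^state$t)
    params[[j]]$value <- params[[j]]$value - lr * mh / (sqrt(vh) + eps)
  }
  invisible(NULL)
}
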