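# LSTM and transformer lab-of-origin classifiers, trained on the autodiff
# tape in ad.R. These mirror the architectures used as robustness checks
# alongside the main convolutional models: a 2-layer LSTM with inter-layer
# dropout, and a small patch-embedding transformer encoder. Both are O(R
# interpreter) slow and meant for modest problem sizes; the workhorse
# models (ResNet/CNN/MLP) run in the compiled engine.

new_weights <- function(shapes, gen_sd) {
  lapply(shapes, function(s) {
    matrix(stats::rnorm(s[1] * s[2], 0, gen_sd(s)), s[1], s[2])
  })
}

# ---- LSTM -----------------------------------------------------------------

lstm_init <- function(units, n_layers) {
  w <- list()
  for (l in seq_len(n_layers)) {
    d_in <- if (l == 1) 1L else units
    sd_w <- 1 / sqrt(d_in + units)
    w[[paste0("W", l)]] <- matrix(stats::rnorm((d_in + units) * 4 * units,
                                               0, sd_w),
                                  d_in + units, 4 * units)
    b <- matrix(0, 1, 4 * units)
    b[1, units + seq_len(units)] <- 1  # forget-gate bias
    w[[paste0("b", l)]] <- b
  }
  w$W_out <- matrix(stats::rnorm(units * 2, 0, 1 / sqrt(units)), units, 2)
  w$b_out <- matrix(0, 1, 2)
  w
}

lstm_forward <- function(tape, params, X, units, n_layers, dropout,
                        train) {
  n <- nrow(X)
  len <- ncol(X)
  h <- lapply(seq_len(n_layers), function(l)
    ad_const(tape, matrix(0, n, units)))
  cc <- lapply(seq_len(n_layers), function(l)
    ad_const(tape, matrix(0, n, units)))
  masks <- NULL
  if (train && dropout > 0 && n_layers > 1) {
    masks <- lapply(seq_len(n_layers - 1), function(l)
      matrix(stats::rbinom(n * units, 1, 1 - dropout) / (1 - dropout),
             n, units))
  }
  iu <- seq_len(units)
  for (t_i in seq_len(len)) {
    below <- ad_const(tape, matrix(X[, t_i], n, 1))
    for (l in seq_len(n_layers)) {
      z <- ad_add(tape,
                  ad_mm(tape, ad_cbind(tape, below, h[[l]]),
                        params[[paste0("W", l)]]),
                  params[[paste0("b", l)]])
      gi <- ad_sigmoid(tape, ad_cols(tape, z, iu))
      gf <- ad_sigmoid(tape, ad_cols(tape, z, units + iu))
      gg <- ad_tanh(tape, ad_cols(tape, z, 2 * units + iu))
      go <- ad_sigmoid(tape, ad_cols(tape, z, 3 * units + iu))
      cc[[l]] <- ad_add(tape, ad_mul(tape, gf, cc[[l]]),
                        ad_mul(tape, gi, gg))
      h[[l]] <- ad_mul(tape, go, ad_tanh(tape, cc[[l]]))
      below <- h[[l]]
      if (!is.null(masks) && l < n_layers) {
        below <- ad_dropmask(tape, below, masks[[l]])
      }
    }
  }
  ad_add(tape, ad_mm(tape, h[[n_layers]], params$W_out), params$b_out)
}

# ---- transformer ----------------------------------------------------------

transformer_init <- function(embed, heads, blocks, patch, t_len) {
  w <- list(
    W_emb = matrix(stats::rnorm(patch * embed, 0, 1 / sqrt(patch)),
                   patch, embed),
    b_emb = matrix(0, 1, embed),
    pos = matrix(stats::rnorm(t_len * embed, 0, 0.02), t_len, embed)
  )
  dh <- embed / heads
  for (b in seq_len(blocks)) {
    for (h in seq_len(heads)) {
      for (nm in c("q", "k", "v")) {
        w[[sprintf("W%s_%d_%d", nm, b, h)]] <-
          matrix(stats::rnorm(embed * dh, 0, 1 / sqrt(embed)), embed, dh)
      }
    }
    w[[paste0("Wo_", b)]] <- matrix(stats::rnorm(embed * embed, 0,
                                                 1 / sqrt(embed)),
                                    embed, embed)
    w[[paste0("g1_", b)]] <- matrix(1, 1, embed)
    w[[paste0("be1_", b)]] <- matrix(0, 1, embed)
    w[[paste0("Wf1_", b)]] <- matrix(stats::rnorm(embed * 4 * embed, 0,
                                                  1 / sqrt(embed)),
                                     embed, 4 * embed)
    w[[paste0("bf1_", b)]] <- matrix(0, 1, 4 * embed)
    w[[paste0("Wf2_", b)]] <- matrix(stats::rnorm(4 * embed * embed, 0,
                                                  1 / sqrt(4 * embed)),
                                     4 * embed, embed)
    w[[paste0("bf2_", b)]] <- matrix(0, 1, embed)
    w[[paste0("g2_", b)]] <- matrix(1, 1, embed)
    w[[paste0("be2_", b)]] <- matrix(0, 1, embed)
  }
  w$W_out <- matrix(stats::rnorm(embed * 2, 0, 1 / sqrt(embed)), embed, 2)
  w$b_out <- matrix(0, 1, 2)
  w
}

transformer_forward <- function(tape, params, X, embed, heads, blocks,
                                patch) {
  n <- nrow(X)
  t_len <- ncol(X) %/% patch
  # patch matrix: (n * t_len) x patch, consecutive non-overlapping windows
  P <- matrix(0, n * t_len, patch)
  for (j in seq_len(t_len)) {
    P[(seq_len(n) - 1) * t_len + j, ] <-
      X[, (j - 1) * patch + seq_len(patch), drop = FALSE]
  }
  emb <- ad_add(tape, ad_mm(tape, ad_const(tape, P), params$W_emb),
                params$b_emb)
  pos <- params$pos
  x <- ad_node(tape, emb$value + pos$value[rep(seq_len(t_len), n), ],
               list(emb, pos), function(node) {
                 ad_accum(emb, node$grad)
                 ad_accum(pos, rowsum(node$grad,
                                      rep(seq_len(t_len), n)))
               })
  for (b in seq_len(blocks)) {
    head_out <- NULL
    for (h in seq_len(heads)) {
      q <- ad_mm(tape, x, params[[sprintf("Wq_%d_%d", b, h)]])
      k <- ad_mm(tape, x, params[[sprintf("Wk_%d_%d", b, h)]])
      v <- ad_mm(tape, x, params[[sprintf("Wv_%d_%d", b, h)]])
      o <- ad_attention(tape, q, k, v, n, t_len)
      head_out <- if (is.null(head_out)) o else ad_cbind(tape, head_out, o)
    }
    att <- ad_mm(tape, head_out, params[[paste0("Wo_", b)]])
    x <- ad_layernorm(tape, ad_add(tape, x, att),
                      params[[paste0("g1_", b)]],
                      params[[paste0("be1_", b)]])
    ff <- ad_mm(tape,
                ad_relu(tape, ad_add(tape,
                                     ad_mm(tape, x,
                                           params[[paste0("Wf1_", b)]]),
                                     params[[paste0("bf1_", b)]])),
                params[[paste0("Wf2_", b)]])
    ff <- ad_add(tape, ff, params[[paste0("bf2_", b)]])
    x <- ad_layernorm(tape, ad_add(tape, x, ff),
                      params[[paste0("g2_", b)]],
                      params[[paste0("be2_", b)]])
  }
  pooled <- ad_pool_mean(tape, x, n, t_len)
  ad_add(tape, ad_mm(tape, pooled, params$W_out), params$b_out)
}

# ---- shared training loop -------------------------------------------------

# forward_fn(tape, params, Xbatch, train) -> logits node
train_tape_model <- function(weights, forward_fn, Xtr, ytr, Xte, yte,
                             epochs, batch, lr, seed) {
  with_seed(seed, {
    n <- nrow(Xtr)
    state <- new.env(parent = emptyenv())
    for (e in seq_len(epochs)) {
      ord <- sample.int(n)
      for (s in seq(1, n, by = batch)) {
        take <- ord[s:min(n, s + batch - 1)]
        if (length(take) < 2) next
        tape <- ad_tape()
        params <- lapply(weights, function(w) ad_param(tape, w))
        logits <- forward_fn(tape, params, Xtr[take, , drop = FALSE],
                             train = TRUE)
        loss <- ad_softmax_ce(tape, logits, ytr[take])
        ad_backward(tape, loss)
        ad_adam_step(state, params, lr = lr)
        weights <- lapply(params, function(p) p$value)
      }
    }
    # evaluation in chunks (no dropout)
    pred <- integer(nrow(Xte))
    for (s in seq(1, nrow(Xte), by = 256)) {
      take <- s:min(nrow(Xte), s + 255)
      tape <- ad_tape()
      params <- lapply(weights, function(w) ad_param(tape, w))
      logits <- forward_fn(tape, params, Xte[take, , drop = FALSE],
                           train = FALSE)
      pred[take] <- max.col(logits$value) - 1L
    }
    mean(pred == yte)
  })
}

train_lstm <- function(Xtr, ytr, Xte, yte, units = 128, n_layers = 2,
                       dropout = 0.5, epochs = 50, batch = 32, lr = 1e-3,
                       seed = 1) {
  weights <- with_seed(seed, lstm_init(units, n_layers))
  fwd <- function(tape, params, X, train) {
    lstm_forward(tape, params, X, units, n_layers, dropout, train)
  }
  train_tape_model(weights, fwd, Xtr, ytr, Xte, yte, epochs, batch, lr,
                   fold_seed(seed, 1))
}

train_transformer <- function(Xtr, ytr, Xte, yte, blocks = 4, heads = 4,
                              embed = 4, patch = 5, epochs = 50,
                              batch = 32, lr = 1e-3, seed = 1) {
  t_len <- ncol(Xtr) %/% patch
  if (t_len < 2) stop_gs("series too short for patch size ", patch)
  weights <- with_seed(seed, transformer_init(embed, heads, blocks, patch,
                                              t_len))
  fwd <- function(tape, params, X, train) {
    transformer_forward(tape, params, X, embed, heads, blocks, patch)
  }
  train_tape_model(weights, fwd, Xtr, ytr, Xte, yte, epochs, batch, lr,
                   fold_seed(seed, 1))
}
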