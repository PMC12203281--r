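# Internal neural-network machinery for the sequence-labeling stack.
#
# Everything operates on one sequence at a time as (T x D) matrices, which at
# desk scale keeps all heavy operations inside BLAS. Each block exposes a
# forward function returning (out, cache) and a backward function returning
# the input gradient plus parameter gradients; gradients are hand-derived and
# verified against finite differences in the test suite.

init_mat <- function(nr, nc, scale = NULL) {
  scale <- scale %||% sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -scale, scale), nr, nc)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(t = 0,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(params, grads, state, lr = 0.02, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

accumulate_grads <- function(total, g) {
  if (is.null(total)) return(g)
  for (nm in names(g)) {
    total[[nm]] <- if (is.null(total[[nm]])) g[[nm]] else total[[nm]] + g[[nm]]
  }
  total
}

# ---- embedding -------------------------------------------------------------

embedding_forward <- function(E, ids) {
  list(out = E[ids, , drop = FALSE], cache = list(ids = ids, V = nrow(E)))
}

embedding_backward <- function(cache, dout) {
  dE <- matrix(0, cache$V, ncol(dout))
  # accumulate duplicate ids
  agg <- rowsum(dout, group = cache$ids)
  dE[as.integer(rownames(agg)), ] <- agg
  dE
}

# ---- dilated convolution stack (kernel 3) ----------------------------------

shift_rows <- function(X, s) {
  # shifted[t, ] = X[t + s, ], zero outside
  T_ <- nrow(X)
  out <- matrix(0, T_, ncol(X))
  if (s == 0) return(X)
  src <- seq_len(T_) + s
  ok <- src >= 1 & src <= T_
  out[ok, ] <- X[src[ok], , drop = FALSE]
  out
}

idcnn_init <- function(depth_dilations, dim, prefix = "conv") {
  params <- list()
  for (l in seq_along(depth_dilations)) {
    for (k in 1:3) {
      params[[sprintf("%s%d_W%d", prefix, l, k)]] <- init_mat(dim, dim)
    }
    params[[sprintf("%s%d_b", prefix, l)]] <- numeric(dim)
  }
  params
}

idcnn_forward <- function(params, X, dilations, prefix = "conv") {
  caches <- vector("list", length(dilations))
  for (l in seq_along(dilations)) {
    d <- dilations[l]
    Xm <- shift_rows(X, -d)   # x_{t-d}
    Xp <- shift_rows(X, d)    # x_{t+d}
    Z <- Xm %*% params[[sprintf("%s%d_W1", prefix, l)]] +
      X %*% params[[sprintf("%s%d_W2", prefix, l)]] +
      Xp %*% params[[sprintf("%s%d_W3", prefix, l)]]
    Z <- sweep(Z, 2, params[[sprintf("%s%d_b", prefix, l)]], `+`)
    Y <- pmax(Z, 0)
    caches[[l]] <- list(X = X, Xm = Xm, Xp = Xp, Z = Z, d = d)
    X <- Y
  }
  # unit-scale output so a recurrent stack on top starts in its useful range
  ln <- layernorm_forward(X)
  list(out = ln$out, cache = list(layers = caches, ln = ln$cache))
}

idcnn_backward <- function(params, caches, dout, prefix = "conv") {
  grads <- list()
  dout <- layernorm_backward(caches$ln, dout)
  caches <- caches$layers
  for (l in rev(seq_along(caches))) {
    cc <- caches[[l]]
    dZ <- dout * (cc$Z > 0)
    grads[[sprintf("%s%d_W1", prefix, l)]] <- crossprod(cc$Xm, dZ)
    grads[[sprintf("%s%d_W2", prefix, l)]] <- crossprod(cc$X, dZ)
    grads[[sprintf("%s%d_W3", prefix, l)]] <- crossprod(cc$Xp, dZ)
    grads[[sprintf("%s%d_b", prefix, l)]] <- colSums(dZ)
    # z_t depends on x_{t-d} (W1), x_t (W2), x_{t+d} (W3)
    dout <- shift_rows(dZ, cc$d) %*% t(params[[sprintf("%s%d_W1", prefix, l)]]) +
      dZ %*% t(params[[sprintf("%s%d_W2", prefix, l)]]) +
      shift_rows(dZ, -cc$d) %*% t(params[[sprintf("%s%d_W3", prefix, l)]])
  }
  list(dX = dout, grads = grads)
}

# ---- LSTM (fused gates, order i|f|o|g) -------------------------------------

lstm_init <- function(input_dim, hidden, prefix) {
  p <- list()
  p[[paste0(prefix, "_Wx")]] <- init_mat(input_dim, 4 * hidden)
  p[[paste0(prefix, "_Wh")]] <- init_mat(hidden, 4 * hidden)
  b <- numeric(4 * hidden)
  b[(hidden + 1):(2 * hidden)] <- 1  # forget-gate bias
  p[[paste0(prefix, "_b")]] <- b
  p
}

lstm_seq_forward <- function(params, X, hidden, prefix) {
  T_ <- nrow(X)
  Wx <- params[[paste0(prefix, "_Wx")]]
  Wh <- params[[paste0(prefix, "_Wh")]]
  b <- params[[paste0(prefix, "_b")]]
  XW <- sweep(X %*% Wx, 2, b, `+`)       # (T x 4H), input part precomputed
  H <- matrix(0, T_, hidden)
  Cc <- matrix(0, T_, hidden)
  gates <- matrix(0, T_, 4 * hidden)
  h <- numeric(hidden); cstate <- numeric(hidden)
  i1 <- 1:hidden; i2 <- hidden + i1; i3 <- 2 * hidden + i1; i4 <- 3 * hidden + i1
  for (t in seq_len(T_)) {
    a <- XW[t, ] + drop(h %*% Wh)
    i_g <- 1 / (1 + exp(-a[i1]))
    f_g <- 1 / (1 + exp(-a[i2]))
    o_g <- 1 / (1 + exp(-a[i3]))
    g_g <- tanh(a[i4])
    cstate <- f_g * cstate + i_g * g_g
    h <- o_g * tanh(cstate)
    gates[t, ] <- c(i_g, f_g, o_g, g_g)
    H[t, ] <- h
    Cc[t, ] <- cstate
  }
  list(out = H, cache = list(X = X, H = H, C = Cc, gates = gates, hidden = hidden,
                             prefix = prefix))
}

lstm_seq_backward <- function(params, cache, dout) {
  X <- cache$X; H <- cache$H; Cc <- cache$C; gates <- cache$gates
  hidden <- cache$hidden; prefix <- cache$prefix
  Wx <- params[[paste0(prefix, "_Wx")]]
  Wh <- params[[paste0(prefix, "_Wh")]]
  T_ <- nrow(X)
  i1 <- 1:hidden; i2 <- hidden + i1; i3 <- 2 * hidden + i1; i4 <- 3 * hidden + i1
  dA <- matrix(0, T_, 4 * hidden)
  dh_next <- numeric(hidden); dc_next <- numeric(hidden)
  for (t in rev(seq_len(T_))) {
    dh <- dout[t, ] + dh_next
    i_g <- gates[t, i1]; f_g <- gates[t, i2]; o_g <- gates[t, i3]; g_g <- gates[t, i4]
    tc <- tanh(Cc[t, ])
    dc <- dc_next + dh * o_g * (1 - tc^2)
    c_prev <- if (t > 1) Cc[t - 1, ] else numeric(hidden)
    da <- c(dc * g_g * i_g * (1 - i_g),
            dc * c_prev * f_g * (1 - f_g),
            dh * tc * o_g * (1 - o_g),
            dc * i_g * (1 - g_g^2))
    dA[t, ] <- da
    dh_next <- drop(Wh %*% da)
    dc_next <- dc * f_g
  }
  Hprev <- rbind(numeric(hidden), H[-T_, , drop = FALSE])
  grads <- list()
  grads[[paste0(prefix, "_Wx")]] <- crossprod(X, dA)
  grads[[paste0(prefix, "_Wh")]] <- crossprod(Hprev, dA)
  grads[[paste0(prefix, "_b")]] <- colSums(dA)
  list(dX = dA %*% t(Wx), grads = grads)
}

bilstm_init <- function(input_dim, hidden, prefix = "lstm") {
  c(lstm_init(input_dim, hidden, paste0(prefix, "_fw")),
    lstm_init(input_dim, hidden, paste0(prefix, "_bw")))
}

bilstm_forward <- function(params, X, hidden, prefix = "lstm") {
  fw <- lstm_seq_forward(params, X, hidden, paste0(prefix, "_fw"))
  rev_idx <- rev(seq_len(nrow(X)))
  bw <- lstm_seq_forward(params, X[rev_idx, , drop = FALSE], hidden, paste0(prefix, "_bw"))
  out <- cbind(fw$out, bw$out[rev_idx, , drop = FALSE])
  list(out = out, cache = list(fw = fw$cache, bw = bw$cache, hidden = hidden,
                               rev_idx = rev_idx))
}

bilstm_backward <- function(params, cache, dout) {
  hidden <- cache$hidden
  rev_idx <- cache$rev_idx
  d_fw <- dout[, 1:hidden, drop = FALSE]
  d_bw <- dout[, hidden + 1:hidden, drop = FALSE][rev_idx, , drop = FALSE]
  g_fw <- lstm_seq_backward(params, cache$fw, d_fw)
  g_bw <- lstm_seq_backward(params, cache$bw, d_bw)
  dX <- g_fw$dX + g_bw$dX[rev_idx, , drop = FALSE]
  list(dX = dX, grads = c(g_fw$grads, g_bw$grads))
}

# ---- transformer encoder block (pre-residual, no layer norm) ---------------

transformer_layer_init <- function(dim, heads, ff_mult = 2, prefix) {
  p <- list()
  sc <- 0.08
  for (nm in c("Wq", "Wk", "Wv", "Wo")) {
    p[[paste0(prefix, "_", nm)]] <- init_mat(dim, dim, sc)
  }
  p[[paste0(prefix, "_W1")]] <- init_mat(dim, ff_mult * dim, sc)
  p[[paste0(prefix, "_b1")]] <- numeric(ff_mult * dim)
  p[[paste0(prefix, "_W2")]] <- init_mat(ff_mult * dim, dim, sc)
  p[[paste0(prefix, "_b2")]] <- numeric(dim)
  p
}

transformer_layer_forward <- function(params, X, heads, prefix) {
  g <- function(nm) params[[paste0(prefix, "_", nm)]]
  D <- ncol(X); dh <- D / heads
  Q <- X %*% g("Wq"); K <- X %*% g("Wk"); V <- X %*% g("Wv")
  Cmat <- matrix(0, nrow(X), D)
  Ah <- vector("list", heads)
  for (h in seq_len(heads)) {
    sl <- ((h - 1) * dh + 1):(h * dh)
    S <- Q[, sl, drop = FALSE] %*% t(K[, sl, drop = FALSE]) / sqrt(dh)
    A <- exp(S - apply(S, 1, max)); A <- A / rowSums(A)
    Cmat[, sl] <- A %*% V[, sl, drop = FALSE]
    Ah[[h]] <- A
  }
  attn_out <- Cmat %*% g("Wo")
  X2 <- X + attn_out
  Z <- sweep(X2 %*% g("W1"), 2, g("b1"), `+`)
  H1 <- pmax(Z, 0)
  Y <- X2 + sweep(H1 %*% g("W2"), 2, g("b2"), `+`)
  list(out = Y, cache = list(X = X, Q = Q, K = K, V = V, Cmat = Cmat, Ah = Ah,
                             X2 = X2, Z = Z, H1 = H1, dh = dh, heads = heads))
}

transformer_layer_backward <- function(params, cache, dout, prefix) {
  g <- function(nm) params[[paste0(prefix, "_", nm)]]
  grads <- list()
  # FFN
  dX2 <- dout
  dH1 <- dout %*% t(g("W2"))
  grads[[paste0(prefix, "_W2")]] <- crossprod(cache$H1, dout)
  grads[[paste0(prefix, "_b2")]] <- colSums(dout)
  dZ <- dH1 * (cache$Z > 0)
  grads[[paste0(prefix, "_W1")]] <- crossprod(cache$X2, dZ)
  grads[[paste0(prefix, "_b1")]] <- colSums(dZ)
  dX2 <- dX2 + dZ %*% t(g("W1"))
  # attention
  dattn <- dX2
  dX <- dX2                                   # residual
  dC <- dattn %*% t(g("Wo"))
  grads[[paste0(prefix, "_Wo")]] <- crossprod(cache$Cmat, dattn)
  dQ <- matrix(0, nrow(dout), ncol(dout))
  dK <- dQ; dV <- dQ
  for (h in seq_len(cache$heads)) {
    dh <- cache$dh
    sl <- ((h - 1) * dh + 1):(h * dh)
    A <- cache$Ah[[h]]
    dO <- dC[, sl, drop = FALSE]
    Vh <- cache$V[, sl, drop = FALSE]
    dA <- dO %*% t(Vh)
    dV[, sl] <- crossprod(A, dO)
    dS <- A * (dA - rowSums(A * dA))
    dQ[, sl] <- dS %*% cache$K[, sl, drop = FALSE] / sqrt(dh)
    dK[, sl] <- crossprod(dS, cache$Q[, sl, drop = FALSE]) / sqrt(dh)
  }
  grads[[paste0(prefix, "_Wq")]] <- crossprod(cache$X, dQ)
  grads[[paste0(prefix, "_Wk")]] <- crossprod(cache$X, dK)
  grads[[paste0(prefix, "_Wv")]] <- crossprod(cache$X, dV)
  dX <- dX + dQ %*% t(g("Wq")) + dK %*% t(g("Wk")) + dV %*% t(g("Wv"))
  list(dX = dX, grads = grads)
}

# sinusoidal position encoding, fixed (not learned)
position_encoding <- function(T_, D) {
  pos <- seq_len(T_) - 1
  out <- matrix(0, T_, D)
  for (j in seq_len(D)) {
    k <- floor((j - 1) / 2)
    w <- 1 / 10000^(2 * k / D)
    out[, j] <- if (j %% 2 == 1) sin(pos * w) else cos(pos * w)
  }
  out
}

# ---- softmax cross-entropy over a vocabulary (masked LM head) --------------

softmax_xent_forward <- function(logits, targets, positions) {
  # loss averaged over `positions`; targets are ids at those positions
  L <- logits[positions, , drop = FALSE]
  M <- L - apply(L, 1, max)
  P <- exp(M) / rowSums(exp(M))
  n <- length(positions)
  loss <- -mean(log(P[cbind(seq_len(n), targets)] + 1e-300))
  dL <- P
  dL[cbind(seq_len(n), targets)] <- dL[cbind(seq_len(n), targets)] - 1
  dlogits <- matrix(0, nrow(logits), ncol(logits))
  dlogits[positions, ] <- dL / n
  list(loss = loss, dlogits = dlogits, probs = P)
}

# ---- fast CRF forward-backward for training --------------------------------
# Column-wise log-sum-exp uses a single global shift; path scores stay small
# during training so this is numerically safe and much faster than per-column
# shifting.

lse_cols <- function(M) {
  m <- max(M)
  log(colSums(exp(M - m))) + m
}

lse_rows <- function(M) {
  m <- max(M)
  log(rowSums(exp(M - m))) + m
}

crf_nll_grads <- function(emissions, params, tags_idx) {
  n <- nrow(emissions); L <- ncol(emissions)
  A <- params$transitions
  alpha <- matrix(0, n, L)
  alpha[1, ] <- params$start + emissions[1, ]
  if (n > 1) for (t in 2:n) {
    alpha[t, ] <- lse_cols(alpha[t - 1, ] + A) + emissions[t, ]
  }
  beta <- matrix(0, n, L)
  beta[n, ] <- params$stop
  if (n > 1) for (t in (n - 1):1) {
    beta[t, ] <- lse_rows(sweep(A, 2, emissions[t + 1, ] + beta[t + 1, ], `+`))
  }
  logZ <- logsumexp(alpha[n, ] + params$stop)
  marg <- exp(alpha + beta - logZ)
  dE <- marg
  dE[cbind(seq_len(n), tags_idx)] <- dE[cbind(seq_len(n), tags_idx)] - 1
  dA <- matrix(0, L, L)
  if (n > 1) for (t in 1:(n - 1)) {
    lp <- outer(alpha[t, ], emissions[t + 1, ] + beta[t + 1, ], `+`) + A - logZ
    dA <- dA + exp(lp)
    dA[tags_idx[t], tags_idx[t + 1]] <- dA[tags_idx[t], tags_idx[t + 1]] - 1
  }
  dstart <- marg[1, ]; dstart[tags_idx[1]] <- dstart[tags_idx[1]] - 1
  dstop <- marg[n, ]; dstop[tags_idx[n]] <- dstop[tags_idx[n]] - 1
  score <- crf_path_score(emissions, params, tags_idx)
  list(nll = logZ - score, d_emissions = dE, d_transitions = dA,
       d_start = dstart, d_stop = dstop)
}

# ---- row-wise layer normalization (no learnable gain/bias) -----------------

layernorm_forward <- function(X, eps = 1e-5) {
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc^2)
  inv_sd <- 1 / sqrt(v + eps)
  Y <- Xc * inv_sd
  list(out = Y, cache = list(Y = Y, inv_sd = inv_sd))
}

layernorm_backward <- function(cache, dout) {
  Y <- cache$Y
  (dout - rowMeans(dout) - Y * rowMeans(dout * Y)) * cache$inv_sd
}
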