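test_that("attention reduces to identity and uniform-mean special cases", {
  expect_equal(attention(matrix(1), matrix(1), matrix(1)), matrix(1))
  # identical keys -> uniform weights -> unweighted mean of V rows
  K <- matrix(1, 3, 2)
  V <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2)
  out <- attention(matrix(c(0.3, -1), 1, 2), K, V)
  expect_equal(out, matrix(colMeans(V), 1))
  expect_error(attention(matrix(1, 1, 2), matrix(1, 2, 3), matrix(1, 2, 1)),
               class = "hichds_shape_error")
  expect_error(attention(matrix(1), matrix(1), matrix(1, 2, 1)),
               class = "hichds_shape_error")
})

test_that("attention matches direct evaluation and rows normalize", {
  Q <- matrix(c(1, 0, 2, 1), 2, 2)
  K <- matrix(c(1, 1, 0, 2), 2, 2)
  V <- matrix(c(1, 2, 3, 4), 2, 2)
  S <- Q %*% t(K) / sqrt(2)
  W <- t(apply(S, 1, function(r) exp(r) / sum(exp(r))))
  expect_equal(attention(Q, K, V), W %*% V, tolerance = 1e-12)
  set.seed(3)
  for (i in 1:10) {
    n <- sample(2:6, 1); d <- sample(1:4, 1)
    res <- attention(matrix(rnorm(n * d), n, d), matrix(rnorm(n * d), n, d),
                     matrix(rnorm(n * 2), n, 2), weights = TRUE)
    expect_equal(rowSums(res$weights), rep(1, n), tolerance = 1e-10)
    # outputs are convex combinations of V rows: inside the per-column range
    V2 <- matrix(rnorm(n * 2), n, 2)
    out2 <- attention(matrix(rnorm(n * d), n, d), matrix(rnorm(n * d), n, d), V2)
    for (j in 1:2) {
      expect_true(all(out2[, j] >= min(V2[, j]) - 1e-12 &
                        out2[, j] <= max(V2[, j]) + 1e-12))
    }
  }
})

test_that("receptive fields match support enumeration (kernel 3, doubling dilations)", {
  sched <- dilation_schedule(3, c(1, 2, 4))
  expect_equal(receptive_field(sched, 1), 3)
  expect_equal(receptive_field(sched, 2), 7)
  expect_equal(receptive_field(sched, 3), 15)
  # the doubling schedule realizes 2^(l+1) - 1 at layer l (3, 7, 15, ...)
  for (l in 1:3) expect_equal(receptive_field(sched, l), 2^(l + 1) - 1)
  set.seed(5)
  for (rep_i in 1:10) {
    k <- sample(c(3, 5), 1)
    dil <- sample(1:4, sample(1:3, 1), replace = TRUE)
    sc <- dilation_schedule(k, dil)
    for (l in seq_along(dil)) {
      expect_equal(receptive_field(sc, l), enumerate_receptive_field(k, dil, l))
    }
  }
  expect_error(receptive_field(sched, 4), class = "hichds_range_error")
  expect_error(dilation_schedule(4, 1), class = "hichds_contract_error")
})

test_that("lstm_step follows the gate equations exactly", {
  H <- 3; E <- 2
  zero <- lstm_cell(matrix(0, H, H + E), matrix(0, H, H + E),
                    matrix(0, H, H + E), matrix(0, H, H + E))
  st <- lstm_step(zero, rep(1, E), rep(0, H), rep(0, H))
  expect_equal(st$gates$f, rep(0.5, H))
  expect_equal(st$gates$i, rep(0.5, H))
  expect_equal(st$gates$o, rep(0.5, H))
  expect_equal(st$C, rep(0, H))
  expect_equal(st$h, rep(0, H))
  # saturated gates: C_t -> C_prev + 1, h_t -> tanh(C_t)
  sat <- lstm_cell(matrix(0, 1, 2), matrix(0, 1, 2), matrix(0, 1, 2),
                   matrix(0, 1, 2), b_f = 50, b_i = 50, b_o = 50, b_c = 50)
  st <- lstm_step(sat, 0, 0, 0.7)
  expect_equal(st$C, 0.7 + 1, tolerance = 1e-8)
  expect_equal(st$h, tanh(1.7), tolerance = 1e-8)
  # 1-dimensional pencil-and-paper case
  cell <- lstm_cell(matrix(c(0.5, 1), 1, 2), matrix(c(-1, 0.5), 1, 2),
                    matrix(c(0.2, 0.3), 1, 2), matrix(c(1, -0.5), 1, 2),
                    b_f = 0.1, b_i = -0.1, b_o = 0.2, b_c = 0)
  h_prev <- 0.4; c_prev <- -0.2; u <- 0.6
  sig <- function(z) 1 / (1 + exp(-z))
  f <- sig(0.5 * h_prev + 1 * u + 0.1)
  i <- sig(-1 * h_prev + 0.5 * u - 0.1)
  o <- sig(0.2 * h_prev + 0.3 * u + 0.2)
  g <- tanh(1 * h_prev - 0.5 * u)
  Cexp <- f * c_prev + i * g
  st <- lstm_step(cell, u, h_prev, c_prev)
  expect_equal(st$C, Cexp, tolerance = 1e-12)
  expect_equal(st$h, o * tanh(Cexp), tolerance = 1e-12)
  expect_error(lstm_step(cell, c(1, 2), 0, 0), class = "hichds_shape_error")
})

test_that("lstm gates stay strictly inside (0,1) over random inputs", {
  set.seed(8)
  for (i in 1:15) {
    H <- sample(1:4, 1); E <- sample(1:3, 1)
    cell <- lstm_cell(matrix(rnorm(H * (H + E)), H), matrix(rnorm(H * (H + E)), H),
                      matrix(rnorm(H * (H + E)), H), matrix(rnorm(H * (H + E)), H))
    st <- lstm_step(cell, rnorm(E), rnorm(H), rnorm(H))
    gates <- c(st$gates$f, st$gates$i, st$gates$o)
    expect_true(all(gates > 0 & gates < 1))
    expect_true(all(abs(st$h) < 1))
  }
})

test_that("hand-derived layer gradients match finite differences", {
  set.seed(21)
  variant <- variant_config("bert-idcnn-bilstm-crf", embed_dim = 8, hidden = 4,
                            dilations = c(1, 2), seed = 1)
  enc_cfg <- mlm_config(dim = 8, heads = 2, layers = 2, seed = 1)
  V <- 11; L <- 4; Tn <- 6
  params <- hichds:::encoder_param_init(V, enc_cfg)
  params <- c(params, hichds:::idcnn_init(variant$dilations, 8))
  params <- c(params, hichds:::bilstm_init(8, 4))
  params$out_W <- hichds:::init_mat(8, L, 0.3)
  params$out_b <- rnorm(L) * 0.1
  params$crf_trans <- matrix(rnorm(L * L) * 0.2, L, L)
  params$crf_start <- rnorm(L) * 0.1
  params$crf_stop <- rnorm(L) * 0.1
  ids <- sample.int(V, Tn, replace = TRUE)
  tags <- sample.int(L, Tn, replace = TRUE)
  lossfun <- function(params) {
    fw <- hichds:::ner_forward(params, ids, variant, enc_cfg)
    hichds:::crf_nll_grads(fw$emissions,
                           list(transitions = params$crf_trans,
                                start = params$crf_start, stop = params$crf_stop),
                           tags)$nll
  }
  fw <- hichds:::ner_forward(params, ids, variant, enc_cfg)
  cg <- hichds:::crf_nll_grads(fw$emissions,
                               list(transitions = params$crf_trans,
                                    start = params$crf_start, stop = params$crf_stop),
                               tags)
  grads <- hichds:::ner_backward(params, fw, cg$d_emissions, variant, enc_cfg)
  grads$crf_trans <- cg$d_transitions
  grads$crf_start <- cg$d_start
  grads$crf_stop <- cg$d_stop
  base <- lossfun(params)
  eps <- 1e-6
  for (nm in names(grads)) {
    p <- params[[nm]]
    for (k in sample.int(length(p), min(3, length(p)))) {
      p2 <- params
      p2[[nm]][k] <- p2[[nm]][k] + eps
      num <- (lossfun(p2) - base) / eps
      expect_equal(grads[[nm]][k], num, tolerance = 5e-3,
                   label = sprintf("gradient of %s[%d]", nm, k))
    }
  }
})
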