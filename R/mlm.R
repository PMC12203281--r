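# A small transformer encoder pretrained with a masked language model
# objective on the working corpus. It plays the role a large pretrained
# contextual encoder plays at full scale: the NER variants named "bert-*"
# start from its weights and fine-tune them end-to-end.

MLM_SPECIALS <- c("<unk>", "<mask>")

# numeric tokens share one shape token; NER needs the tag, not the value
norm_token <- function(tokens) {
  ifelse(grepl("^[0-9]+([./-][0-9]+)*$", tokens), "<num>", tokens)
}

build_vocab <- function(corpus, min_freq = 1) {
  toks <- norm_token(unlist(corpus, use.names = FALSE))
  tab <- table(toks)
  keep <- names(tab)[tab >= min_freq]
  c(MLM_SPECIALS, sort(keep))
}

tokens_to_ids <- function(tokens, vocab) {
  idx <- match(norm_token(tokens), vocab)
  idx[is.na(idx)] <- 1L  # <unk>
  idx
}

#' Configuration of the masked-LM encoder
#'
#' @param dim Model dimension (default 64).
#' @param heads Attention heads per layer (default 2; must divide `dim`).
#' @param layers Transformer layers (default 2).
#' @param epochs Pretraining epochs (default 8).
#' @param lr Adam learning rate.
#' @param mask_rate Fraction of positions masked per sentence (default 0.15,
#'   at least one position).
#' @param holdout_frac Fraction of sentences held out for the masked-token
#'   cross-entropy trace (default 0.1; a single-sentence corpus is its own
#'   holdout).
#' @param seed Integer seed.
#' @return List of class `mlm_config`.
#' @export
mlm_config <- function(dim = 64, heads = 2, layers = 2, epochs = 8, lr = 0.01,
                       mask_rate = 0.15, holdout_frac = 0.1, seed = 1) {
  if (dim %% heads != 0) {
    stop_hichds("dim must be divisible by heads", class = "hichds_config_error")
  }
  structure(list(dim = dim, heads = heads, layers = layers, epochs = epochs,
                 lr = lr, mask_rate = mask_rate, holdout_frac = holdout_frac,
                 seed = as.integer(seed)), class = "mlm_config")
}

encoder_param_init <- function(vocab_size, config) {
  params <- list(enc_emb = init_mat(vocab_size, config$dim, 0.3))
  for (l in seq_len(config$layers)) {
    params <- c(params, transformer_layer_init(config$dim, config$heads,
                                               prefix = sprintf("enc_l%d", l)))
  }
  params
}

encoder_forward <- function(params, ids, config) {
  X <- params$enc_emb[ids, , drop = FALSE] +
    0.1 * position_encoding(length(ids), config$dim)
  caches <- vector("list", config$layers)
  for (l in seq_len(config$layers)) {
    fw <- transformer_layer_forward(params, X, config$heads, sprintf("enc_l%d", l))
    X <- fw$out
    caches[[l]] <- fw$cache
  }
  # final layer normalization keeps the contextual features on a unit scale
  # for whatever stack consumes them
  ln <- layernorm_forward(X)
  list(out = ln$out, cache = list(ids = ids, caches = caches, ln = ln$cache,
                                  vocab_size = nrow(params$enc_emb)))
}

encoder_backward <- function(params, cache, dout, config) {
  grads <- list()
  dout <- layernorm_backward(cache$ln, dout)
  for (l in rev(seq_len(config$layers))) {
    bk <- transformer_layer_backward(params, cache$caches[[l]], dout,
                                     sprintf("enc_l%d", l))
    dout <- bk$dX
    grads <- c(grads, bk$grads)
  }
  grads$enc_emb <- embedding_backward(list(ids = cache$ids, V = cache$vocab_size), dout)
  grads
}

mlm_eval_loss <- function(params, docs_ids, config, mask_seed) {
  with_rng_seed(mask_seed, {
    total <- 0; nseq <- 0
    mask_id <- 2L
    for (ids in docs_ids) {
      n_mask <- max(1, round(config$mask_rate * length(ids)))
      pos <- sample.int(length(ids), n_mask)
      masked <- ids
      masked[pos] <- mask_id
      H <- encoder_forward(params, masked, config)$out
      logits <- sweep(H %*% params$out_W, 2, params$out_b, `+`)
      total <- total + softmax_xent_forward(logits, ids[pos], pos)$loss
      nseq <- nseq + 1
    }
    total / max(nseq, 1)
  })
}

#' Pretrain the masked-LM transformer encoder
#'
#' Randomly masks tokens of each sentence and trains the encoder to recover
#' them; deterministic given the config seed. The returned object records the
#' held-out masked-token cross-entropy before training (epoch 0) and after
#' each epoch.
#'
#' @param corpus List of token vectors.
#' @param config An [mlm_config()].
#' @return An object of class `mlm_encoder` with elements `vocab`, `params`,
#'   `config` and `trace` (epoch, holdout loss, training loss).
#' @export
pretrain_masked_lm <- function(corpus, config = mlm_config()) {
  if (length(corpus) == 0 || all(lengths(corpus) == 0)) {
    stop_hichds("masked-LM corpus is empty", class = "hichds_data_error")
  }
  vocab <- build_vocab(corpus)
  with_rng_seed(config$seed, {
    docs_ids <- lapply(corpus, tokens_to_ids, vocab = vocab)
    docs_ids <- docs_ids[lengths(docs_ids) > 0]
    n_hold <- if (length(docs_ids) == 1) 0 else
      max(1, floor(config$holdout_frac * length(docs_ids)))
    hold_idx <- if (n_hold > 0) sample.int(length(docs_ids), n_hold) else integer(0)
    hold <- if (n_hold > 0) docs_ids[hold_idx] else docs_ids
    train <- if (n_hold > 0) docs_ids[-hold_idx] else docs_ids
    params <- encoder_param_init(length(vocab), config)
    params$out_W <- init_mat(config$dim, length(vocab), 0.08)
    params$out_b <- numeric(length(vocab))
    opt <- adam_init(params)
    mask_seed <- derive_seed(config$seed, 5417)
    trace <- data.frame(epoch = 0, holdout_loss = mlm_eval_loss(params, hold, config, mask_seed),
                        train_loss = NA_real_)
    mask_id <- 2L
    for (ep in seq_len(config$epochs)) {
      ep_loss <- 0
      order_idx <- sample.int(length(train))
      for (d in order_idx) {
        ids <- train[[d]]
        n_mask <- max(1, round(config$mask_rate * length(ids)))
        pos <- sample.int(length(ids), n_mask)
        masked <- ids
        masked[pos] <- mask_id
        fw <- encoder_forward(params, masked, config)
        logits <- sweep(fw$out %*% params$out_W, 2, params$out_b, `+`)
        sm <- softmax_xent_forward(logits, ids[pos], pos)
        ep_loss <- ep_loss + sm$loss
        dH <- sm$dlogits %*% t(params$out_W)
        grads <- encoder_backward(params, fw$cache, dH, config)
        grads$out_W <- crossprod(fw$out, sm$dlogits)
        grads$out_b <- colSums(sm$dlogits)
        st <- adam_step(params, grads, opt, lr = config$lr)
        params <- st$params; opt <- st$state
      }
      trace <- rbind(trace, data.frame(
        epoch = ep,
        holdout_loss = mlm_eval_loss(params, hold, config, mask_seed),
        train_loss = ep_loss / length(train)))
    }
    structure(list(vocab = vocab, params = params, config = config, trace = trace),
              class = "mlm_encoder")
  })
}

#' @export
print.mlm_encoder <- function(x, ...) {
  cat(sprintf("Masked-LM transformer encoder: %d-dim, %d layer(s), %d head(s), vocab %d\n",
              x$config$dim, x$config$layers, x$config$heads, length(x$vocab)))
  n <- nrow(x$trace)
  cat(sprintf("Holdout masked-token loss: %.3f (epoch 0) -> %.3f (epoch %d)\n",
              x$trace$holdout_loss[1], x$trace$holdout_loss[n], x$trace$epoch[n]))
  invisible(x)
}
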