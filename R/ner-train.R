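# Composable NER sequence-labeling stacks. A variant is named by its
# component order -- e.g. "bert-idcnn-bilstm-crf" runs the pretrained
# transformer encoder, then the dilated-convolution stack, then the
# bidirectional LSTM, and always terminates in a CRF. The seven shipped
# variants are every combination the component grammar admits with at least
# one encoder.

NER_VARIANTS <- c("idcnn-crf", "bilstm-crf", "bilstm-idcnn-crf", "bert-crf",
                  "bert-idcnn-crf", "bert-bilstm-crf", "bert-idcnn-bilstm-crf")

#' The seven shipped NER variant names
#' @return Character vector of variant names.
#' @export
ner_variants <- function() NER_VARIANTS

#' Configuration of an NER variant
#'
#' @param name Variant name: dash-separated components from
#'   \{`bert`, `idcnn`, `bilstm`\} in application order, ending in `crf`.
#' @param embed_dim Embedding (and encoder) dimension, default 64.
#' @param hidden LSTM hidden size per direction, default 32.
#' @param dilations Dilation schedule of the convolution stack, default
#'   `c(1, 2, 4)` (kernel 3).
#' @param epochs,lr Training epochs and Adam learning rate.
#' @param seed Integer seed for initialization and data order.
#' @param mlm Optional [mlm_config()] overriding the encoder pretraining
#'   settings for `bert-*` variants (its `dim` is forced to `embed_dim`).
#' @return List of class `variant_config`.
#' @export
variant_config <- function(name = "bert-idcnn-bilstm-crf", embed_dim = 64,
                           hidden = 32, dilations = c(1, 2, 4), epochs = 8,
                           lr = 0.01, seed = 1, mlm = NULL) {
  parts <- strsplit(name, "-", fixed = TRUE)[[1]]
  if (length(parts) < 2 || parts[length(parts)] != "crf") {
    stop_hichds("variant '%s' must end in -crf", name, class = "hichds_config_error")
  }
  stack <- parts[-length(parts)]
  if (!length(stack) || !all(stack %in% c("bert", "idcnn", "bilstm"))) {
    stop_hichds("variant '%s' must use components bert/idcnn/bilstm", name,
                class = "hichds_config_error")
  }
  structure(list(name = name, stack = stack, embed_dim = embed_dim,
                 hidden = hidden, dilations = dilations, epochs = epochs,
                 lr = lr, seed = as.integer(seed), mlm = mlm),
            class = "variant_config")
}

# forward through the configured stack; returns emissions and caches
ner_forward <- function(params, ids, variant, enc_config) {
  caches <- list()
  if ("bert" %in% variant$stack) {
    fw <- encoder_forward(params, ids, enc_config)
    X <- fw$out
    caches$enc <- fw$cache
  } else {
    fw <- embedding_forward(params$emb, ids)
    X <- fw$out
    caches$emb <- fw$cache
  }
  for (comp in variant$stack) {
    if (comp == "idcnn") {
      fw <- idcnn_forward(params, X, variant$dilations)
      X <- fw$out
      caches$idcnn <- fw$cache
    } else if (comp == "bilstm") {
      fw <- bilstm_forward(params, X, variant$hidden)
      X <- fw$out
      caches$bilstm <- fw$cache
    }
  }
  emissions <- sweep(X %*% params$out_W, 2, params$out_b, `+`)
  list(emissions = emissions, X = X, caches = caches)
}

ner_backward <- function(params, fw, d_emissions, variant, enc_config) {
  grads <- list(out_W = crossprod(fw$X, d_emissions), out_b = colSums(d_emissions))
  dX <- d_emissions %*% t(params$out_W)
  for (comp in rev(variant$stack)) {
    if (comp == "bilstm") {
      bk <- bilstm_backward(params, fw$caches$bilstm, dX)
      dX <- bk$dX
      grads <- c(grads, bk$grads)
    } else if (comp == "idcnn") {
      bk <- idcnn_backward(params, fw$caches$idcnn, dX)
      dX <- bk$dX
      grads <- c(grads, bk$grads)
    }
  }
  if ("bert" %in% variant$stack) {
    grads <- c(grads, encoder_backward(params, fw$caches$enc, dX, enc_config))
  } else {
    grads$emb <- embedding_backward(fw$caches$emb, dX)
  }
  grads
}

ner_crf_params <- function(params, tag_names) {
  crf_params(params$crf_trans, params$crf_start, params$crf_stop, tags = tag_names)
}

#' Train an NER sequence labeler
#'
#' Trains the configured variant with Adam on per-sentence CRF negative
#' log-likelihood, records entity-level precision/recall/F1 on the dev split
#' after every epoch, and keeps the checkpoint with the best dev F1.
#'
#' @param train_docs,dev_docs Lists of `annotated_document` objects sharing
#'   one tag alphabet.
#' @param variant A [variant_config()].
#' @param encoder Optional pre-built [pretrain_masked_lm()] encoder for
#'   `bert-*` variants; pretrained on the training tokens when omitted.
#' @param alphabet Tag alphabet (default [tag_alphabet()]).
#' @param verbose Print per-epoch dev metrics.
#' @return An object of class `hich_ner` with the fitted parameters, the
#'   per-epoch metric `trace`, and the pretrained-encoder reference.
#' @export
train_ner <- function(train_docs, dev_docs, variant = variant_config(),
                      encoder = NULL, alphabet = tag_alphabet(), verbose = FALSE) {
  for (doc in c(train_docs, dev_docs)) {
    bad <- setdiff(doc$tags, alphabet)
    if (length(bad)) {
      stop_hichds("document %s uses tags outside the alphabet: %s", doc$doc_id,
                  paste(unique(bad), collapse = ", "), class = "hichds_data_error")
    }
  }
  use_bert <- "bert" %in% variant$stack
  enc_config <- NULL
  if (use_bert) {
    if (is.null(encoder)) {
      mlm_cfg <- variant$mlm %||% mlm_config(seed = variant$seed)
      mlm_cfg$dim <- variant$embed_dim
      encoder <- pretrain_masked_lm(lapply(train_docs, `[[`, "tokens"), mlm_cfg)
    }
    enc_config <- encoder$config
    vocab <- encoder$vocab
  } else {
    vocab <- build_vocab(lapply(train_docs, `[[`, "tokens"))
  }
  L <- length(alphabet)
  with_rng_seed(derive_seed(variant$seed, 101), {
    params <- list()
    dim_in <- variant$embed_dim
    if (use_bert) {
      params <- c(params, encoder$params[grep("^enc_", names(encoder$params))])
    } else {
      params$emb <- init_mat(length(vocab), variant$embed_dim, 0.08)
    }
    for (comp in variant$stack) {
      if (comp == "idcnn") {
        params <- c(params, idcnn_init(variant$dilations, dim_in))
      } else if (comp == "bilstm") {
        params <- c(params, bilstm_init(dim_in, variant$hidden))
        dim_in <- 2 * variant$hidden
      }
    }
    params$out_W <- init_mat(dim_in, L, 0.08)
    params$out_b <- numeric(L)
    params$crf_trans <- matrix(0, L, L)
    params$crf_start <- numeric(L)
    params$crf_stop <- numeric(L)
    opt <- adam_init(params)

    train_ids <- lapply(train_docs, function(d) tokens_to_ids(d$tokens, vocab))
    train_tags <- lapply(train_docs, function(d) match(d$tags, alphabet))
    model <- structure(list(variant = variant, vocab = vocab, alphabet = alphabet,
                            params = params, enc_config = enc_config,
                            trace = data.frame(), best_f1 = -Inf),
                       class = "hich_ner")
    eval_dev <- function(model) {
      pred <- lapply(dev_docs, function(d) extract_entities(model, d$tokens))
      gold <- lapply(dev_docs, function(d) tags_to_spans(d$tags, d$tokens))
      suppressWarnings(ner_metrics(gold, pred))
    }
    best_params <- params
    trace <- data.frame()
    for (ep in seq_len(variant$epochs)) {
      for (d in sample.int(length(train_docs))) {
        ids <- train_ids[[d]]
        fw <- ner_forward(params, ids, variant, enc_config)
        cg <- crf_nll_grads(fw$emissions,
                            list(transitions = params$crf_trans,
                                 start = params$crf_start, stop = params$crf_stop),
                            train_tags[[d]])
        grads <- ner_backward(params, fw, cg$d_emissions, variant, enc_config)
        grads$crf_trans <- cg$d_transitions
        grads$crf_start <- cg$d_start
        grads$crf_stop <- cg$d_stop
        st <- adam_step(params, grads, opt, lr = variant$lr)
        params <- st$params; opt <- st$state
      }
      model$params <- params
      m <- eval_dev(model)
      trace <- rbind(trace, data.frame(epoch = ep, split = "dev",
                                       precision = m[["precision"]],
                                       recall = m[["recall"]], f1 = m[["f1"]]))
      if (verbose) {
        message(sprintf("[%s] epoch %d dev P=%.2f R=%.2f F1=%.2f",
                        variant$name, ep, m[["precision"]], m[["recall"]], m[["f1"]]))
      }
      if (m[["f1"]] >= model$best_f1) {
        model$best_f1 <- m[["f1"]]
        best_params <- params
      }
    }
    model$params <- best_params
    model$trace <- trace
    model
  })
}

#' @export
print.hich_ner <- function(x, ...) {
  cat(sprintf("NER model '%s' (vocab %d, %d tags)\n",
              x$variant$name, length(x$vocab), length(x$alphabet)))
  if (nrow(x$trace)) {
    cat(sprintf("Best dev F1: %.2f after %d epoch(s)\n", x$best_f1, max(x$trace$epoch)))
  } else {
    cat("Untrained (0 epochs): parameters at initialization\n")
  }
  invisible(x)
}

#' Predict BIO tags for a token sequence
#'
#' @param object A fitted `hich_ner` model.
#' @param tokens Character vector of tokens (or an `annotated_document`).
#' @param ... Unused.
#' @return Character vector of predicted tags.
#' @export
predict.hich_ner <- function(object, tokens, ...) {
  if (inherits(tokens, "annotated_document")) tokens <- tokens$tokens
  ids <- tokens_to_ids(tokens, object$vocab)
  fw <- ner_forward(object$params, ids, object$variant, object$enc_config)
  path <- viterbi_decode(fw$emissions, ner_crf_params(object$params, object$alphabet))
  object$alphabet[path]
}

#' Decode BIO tags into entity spans
#'
#' `B-` starts a span; `I-` of the same type continues it; a dangling `I-`
#' (no compatible predecessor) is treated leniently as a span start, the
#' usual convention when decoding model output.
#'
#' @param tags Character vector of BIO tags.
#' @param tokens Optional tokens used to attach span text.
#' @return Data frame with `start`, `end`, `type` (and `text` if tokens given).
#' @export
tags_to_spans <- function(tags, tokens = NULL) {
  starts <- integer(0); ends <- integer(0); types <- character(0)
  cur_start <- NA_integer_; cur_type <- NA_character_
  close_span <- function(end) {
    if (!is.na(cur_start)) {
      starts <<- c(starts, cur_start); ends <<- c(ends, end); types <<- c(types, cur_type)
    }
  }
  for (i in seq_along(tags)) {
    tg <- tags[i]
    if (tg == "O") {
      close_span(i - 1L); cur_start <- NA_integer_
    } else if (startsWith(tg, "B-")) {
      close_span(i - 1L); cur_start <- i; cur_type <- substring(tg, 3)
    } else { # I-
      type <- substring(tg, 3)
      if (is.na(cur_start) || type != cur_type) {
        close_span(i - 1L); cur_start <- i; cur_type <- type
      }
    }
  }
  close_span(length(tags))
  out <- data.frame(start = starts, end = ends, type = types,
                    stringsAsFactors = FALSE)
  if (!is.null(tokens) && nrow(out)) {
    out$text <- vapply(seq_len(nrow(out)), function(i) {
      paste(tokens[out$start[i]:out$end[i]], collapse = " ")
    }, character(1))
  } else if (!is.null(tokens)) {
    out$text <- character(0)
  }
  out
}

#' Extract typed entity spans from a document
#'
#' @param model A fitted `hich_ner` model.
#' @param doc An `annotated_document` or a character vector of tokens.
#' @return Data frame of non-overlapping spans: `start`, `end`, `type`, `text`.
#' @export
extract_entities <- function(model, doc) {
  tokens <- if (inherits(doc, "annotated_document")) doc$tokens else doc
  tags_to_spans(predict(model, tokens), tokens)
}

#' Entity-level precision, recall and F1
#'
#' Counts a true positive for every exact (document, start, end, type) match
#' between gold and predicted spans; reports P, R, F1 on the 0-100 scale.
#' Zero denominators yield 0 with a warning (the CoNLL convention).
#'
#' @param gold,predicted Lists (one element per document) of span data frames
#'   as returned by [tags_to_spans()].
#' @return Named vector `precision`, `recall`, `f1`.
#' @export
ner_metrics <- function(gold, predicted) {
  if (length(gold) != length(predicted)) {
    stop_hichds("gold and predicted must cover the same documents",
                class = "hichds_contract_error")
  }
  key <- function(df, d) {
    if (!nrow(df)) return(character(0))
    sprintf("%d|%d|%d|%s", d, df$start, df$end, df$type)
  }
  tp <- 0; n_gold <- 0; n_pred <- 0
  for (d in seq_along(gold)) {
    gk <- key(gold[[d]], d); pk <- key(predicted[[d]], d)
    tp <- tp + length(intersect(gk, pk))
    n_gold <- n_gold + length(gk)
    n_pred <- n_pred + length(pk)
  }
  p <- if (n_pred > 0) 100 * tp / n_pred else { warning("no predicted entities; precision set to 0"); 0 }
  r <- if (n_gold > 0) 100 * tp / n_gold else { warning("no gold entities; recall set to 0"); 0 }
  c(precision = p, recall = r, f1 = f1_from_pr(p, r))
}

#' Save / load a fitted NER model
#'
#' Serializes the model together with a config manifest.
#'
#' @param model A `hich_ner` object.
#' @param path File path.
#' @return `path` (write) or the model (read).
#' @export
write_ner_model <- function(model, path) {
  saveRDS(list(manifest = list(format = 1L, variant = model$variant$name,
                               created = "hichds"),
               model = model), path)
  invisible(path)
}

#' @rdname write_ner_model
#' @export
read_ner_model <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$manifest) || obj$manifest$format != 1L) {
    stop_hichds("unrecognized model checkpoint format", class = "hichds_parse_error")
  }
  obj$model
}
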