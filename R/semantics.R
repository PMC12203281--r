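# Word-vector semantic layer: skip-gram-with-negative-sampling word vectors,
# weighted mean sentence vectors, cosine similarity, and text-to-text
# matching used for entity alignment and reasoning support.

#' Train word vectors by skip-gram with negative sampling
#'
#' Deterministic given the seed and corpus order. Every token at or above
#' `min_count` receives a vector.
#'
#' @param corpus List of token vectors (or a single token vector).
#' @param d Vector dimension (default 64).
#' @param window Symmetric context window (default 3).
#' @param negatives Negative samples per positive pair (default 5).
#' @param epochs Passes over the corpus (default 3).
#' @param lr Initial learning rate (default 0.05, linearly decayed).
#' @param min_count Frequency floor (default 1).
#' @param seed Integer seed.
#' @return Object of class `word_vectors`: `vocab`, `vectors`
#'   (|vocab| x d), `counts`, `total`, `d`, `seed`.
#' @export
train_word_vectors <- function(corpus, d = 64, window = 3, negatives = 5,
                               epochs = 3, lr = 0.05, min_count = 1, seed = 1) {
  if (!is.list(corpus)) corpus <- list(corpus)
  toks_all <- unlist(corpus, use.names = FALSE)
  if (!length(toks_all)) {
    stop_hichds("word-vector corpus is empty", class = "hichds_data_error")
  }
  if (d < 1) stop_hichds("dimension must be >= 1", class = "hichds_config_error")
  tab <- table(toks_all)
  vocab <- sort(names(tab)[tab >= min_count])
  counts <- as.integer(tab[vocab])
  with_rng_seed(seed, {
    V <- length(vocab)
    W_in <- matrix(stats::runif(V * d, -0.5, 0.5) / d, V, d)
    W_out <- matrix(0, V, d)
    # unigram^(3/4) negative-sampling distribution
    neg_prob <- counts^0.75
    neg_prob <- neg_prob / sum(neg_prob)
    ids_docs <- lapply(corpus, function(x) match(x, vocab))
    n_steps <- sum(lengths(ids_docs)) * epochs
    step <- 0
    for (ep in seq_len(epochs)) {
      for (ids in ids_docs) {
        n <- length(ids)
        for (i in seq_len(n)) {
          step <- step + 1
          cid <- ids[i]
          if (is.na(cid)) next
          cur_lr <- lr * max(1e-4, 1 - step / n_steps)
          lo <- max(1, i - window); hi <- min(n, i + window)
          ctx <- ids[setdiff(lo:hi, i)]
          ctx <- ctx[!is.na(ctx)]
          for (oid in ctx) {
            targets <- c(oid, sample.int(V, negatives, replace = TRUE, prob = neg_prob))
            labels <- c(1, numeric(negatives))
            Vt <- W_out[targets, , drop = FALSE]
            vc <- W_in[cid, ]
            g <- (labels - 1 / (1 + exp(-drop(Vt %*% vc)))) * cur_lr
            W_in[cid, ] <- vc + drop(crossprod(Vt, g))
            W_out[targets, ] <- Vt + outer(g, vc)
          }
        }
      }
    }
    structure(list(vocab = vocab, vectors = W_in, counts = counts,
                   total = sum(counts), d = d, seed = as.integer(seed)),
              class = "word_vectors")
  })
}

#' @export
print.word_vectors <- function(x, ...) {
  cat(sprintf("Word vectors: %d tokens x %d dimensions (seed %d)\n",
              length(x$vocab), x$d, x$seed))
  invisible(x)
}

# inverse-frequency token weight a / (a + relfreq); the shipped default
inv_freq_weight <- function(tokens, wv, a = 1e-3) {
  idx <- match(tokens, wv$vocab)
  rel <- wv$counts[idx] / wv$total
  a / (a + rel)
}

#' Weighted sentence vector
#'
#' `V_s = (sum_i V_i * e_w(i)) / m` over the m in-vocabulary tokens.
#' Out-of-vocabulary tokens are skipped and do not count toward m.
#'
#' @param tokens Character vector.
#' @param wv A [train_word_vectors()] object.
#' @param weights `"inverse_frequency"` (default: `a / (a + relfreq)` with
#'   `a = 1e-3`), `"uniform"`, or a numeric vector of per-token weights
#'   aligned with `tokens`.
#' @return Numeric vector of length `wv$d` with attributes `m` (contributing
#'   token count) and `weight_fn`.
#' @export
sentence_vector <- function(tokens, wv, weights = "inverse_frequency") {
  idx <- match(tokens, wv$vocab)
  keep <- !is.na(idx)
  if (!any(keep)) {
    stop_hichds("no token of the sentence is in the vocabulary", class = "hichds_coverage_error")
  }
  w <- if (is.numeric(weights)) {
    if (length(weights) != length(tokens)) {
      stop_hichds("numeric weights must align with tokens", class = "hichds_contract_error")
    }
    weights[keep]
  } else if (identical(weights, "uniform")) {
    rep(1, sum(keep))
  } else if (identical(weights, "inverse_frequency")) {
    inv_freq_weight(tokens[keep], wv)
  } else {
    stop_hichds("unknown weight function '%s'", weights, class = "hichds_config_error")
  }
  m <- sum(keep)
  vs <- colSums(wv$vectors[idx[keep], , drop = FALSE] * w) / m
  attr(vs, "m") <- m
  attr(vs, "weight_fn") <- if (is.numeric(weights)) "custom" else weights
  vs
}

#' Cosine similarity of two vectors
#'
#' `dot(a, b) / (|a| |b|)`; symmetric, in \[-1, 1\], scale-invariant under
#' positive rescaling. A zero vector is a contract error, not a silent 0.
#'
#' @param a,b Numeric vectors of equal length.
#' @return A single number in \[-1, 1\].
#' @examples
#' cosine_similarity(c(1, 2), c(2, 1)) # 0.8
#' @export
cosine_similarity <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) {
    stop_hichds("vectors differ in length (%d vs %d)", length(a), length(b),
                class = "hichds_shape_error")
  }
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop_hichds("cosine similarity of a zero vector is undefined", class = "hichds_contract_error")
  }
  sum(a * b) / (na * nb)
}

#' Rank candidate texts by sentence-vector cosine similarity to a query
#'
#' @param query Token vector.
#' @param candidates List of token vectors.
#' @param wv Word vectors.
#' @param threshold Candidates scoring strictly below are excluded
#'   (default `-Inf`: keep all).
#' @param weights Passed to [sentence_vector()].
#' @return Data frame `candidate` (index), `score`, sorted by descending
#'   score; stable for ties.
#' @export
match_text <- function(query, candidates, wv, threshold = -Inf,
                       weights = "inverse_frequency") {
  if (!length(candidates)) {
    stop_hichds("need at least one candidate", class = "hichds_contract_error")
  }
  qv <- sentence_vector(query, wv, weights)
  scores <- vapply(candidates, function(tk) {
    cosine_similarity(qv, sentence_vector(tk, wv, weights))
  }, numeric(1))
  keep <- which(scores >= threshold)
  ord <- keep[order(-scores[keep])]
  data.frame(candidate = ord, score = scores[ord])
}

#' Write / read word vectors in the standard text format
#'
#' First line `vocab_size dim`, then one line per token: the token followed
#' by its coordinates.
#'
#' @param wv A `word_vectors` object.
#' @param path File path.
#' @return `path` (write) or a `word_vectors` object (read; frequency counts
#'   are not part of the exchange format, so uniform counts are assumed).
#' @export
write_word_vectors <- function(wv, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(wv$vocab), wv$d), con)
  for (i in seq_along(wv$vocab)) {
    writeLines(paste(wv$vocab[i], paste(formatC(wv$vectors[i, ], format = "g", digits = 17),
                                        collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_word_vectors
#' @export
read_word_vectors <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- as.integer(strsplit(lines[1], " ", fixed = TRUE)[[1]])
  vocab <- character(hdr[1])
  vectors <- matrix(0, hdr[1], hdr[2])
  for (i in seq_len(hdr[1])) {
    parts <- strsplit(lines[i + 1], " ", fixed = TRUE)[[1]]
    vocab[i] <- parts[1]
    vectors[i, ] <- as.numeric(parts[-1])
  }
  structure(list(vocab = vocab, vectors = vectors,
                 counts = rep(1L, hdr[1]), total = hdr[1], d = hdr[2],
                 seed = NA_integer_), class = "word_vectors")
}
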