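test_that("masked-LM pretraining memorizes a single sentence and is deterministic", {
  corpus <- list(c("the", "cat", "sat", "on", "the", "mat"))
  cfg <- mlm_config(dim = 16, heads = 2, layers = 1, epochs = 15, seed = 3)
  enc <- pretrain_masked_lm(corpus, cfg)
  n <- nrow(enc$trace)
  expect_lt(enc$trace$train_loss[n], enc$trace$holdout_loss[1])
  expect_lt(enc$trace$holdout_loss[n], enc$trace$holdout_loss[1])
  enc2 <- pretrain_masked_lm(corpus, cfg)
  expect_identical(enc$trace, enc2$trace)
  expect_identical(enc$params, enc2$params)
  expect_error(pretrain_masked_lm(list(), cfg), class = "hichds_data_error")
})

test_that("masked-LM learns a deterministic bigram beyond the majority baseline", {
  set.seed(12)
  fillers <- c("u", "v", "w", "x", "y")
  corpus <- lapply(1:12, function(i) {
    s <- sample(fillers, 6, replace = TRUE)
    pos <- sample(1:5, 1)
    s[pos] <- "A"; s[pos + 1] <- "B"
    s
  })
  cfg <- mlm_config(dim = 16, heads = 2, layers = 1, epochs = 25, lr = 0.02,
                    holdout_frac = 0.001, seed = 9)
  enc <- pretrain_masked_lm(corpus, cfg)
  vocab <- enc$vocab
  # majority-class baseline from corpus counts
  counts <- table(unlist(corpus))
  majority <- max(counts) / sum(counts)
  hits <- 0; trials <- 0
  for (s in corpus) {
    pos_b <- which(s == "B")
    ids <- hichds:::tokens_to_ids(s, vocab)
    ids[pos_b] <- 2L  # mask B
    H <- hichds:::encoder_forward(enc$params, ids, enc$config)$out
    logits <- H[pos_b, ] %*% enc$params$out_W + enc$params$out_b
    hits <- hits + (vocab[which.max(logits)] == "B")
    trials <- trials + 1
  }
  expect_gt(hits / trials, majority)
})

test_that("training improves dev F1 and zero epochs returns the initialization", {
  corpus <- tiny_corpus()
  v <- small_variant("bilstm-crf", seed = 2, epochs = 3)
  m <- train_ner(corpus$docs[1:22], corpus$docs[23:30], v)
  expect_gt(m$trace$f1[nrow(m$trace)], m$trace$f1[1])
  expect_equal(nrow(m$trace), 3)
  m0a <- train_ner(corpus$docs[1:22], corpus$docs[23:30],
                   small_variant("bilstm-crf", seed = 2, epochs = 0))
  m0b <- train_ner(corpus$docs[1:22], corpus$docs[23:30],
                   small_variant("bilstm-crf", seed = 2, epochs = 0))
  expect_identical(m0a$params, m0b$params)
  expect_equal(nrow(m0a$trace), 0)
  m1 <- train_ner(corpus$docs[1:22], corpus$docs[23:30],
                  small_variant("bilstm-crf", seed = 2, epochs = 1))
  expect_false(identical(m0a$params$out_W, m1$params$out_W))
  # tag alphabet mismatch is a data error
  bad <- corpus$docs[[1]]
  bad$tags[2] <- "B-unknown-type"
  expect_error(train_ner(list(bad), corpus$docs[2], v), class = "hichds_data_error")
})

test_that("all seven variants train end-to-end on a smoke corpus", {
  corpus <- tiny_corpus()
  enc <- pretrain_masked_lm(lapply(corpus$docs[1:16], `[[`, "tokens"),
                            mlm_config(dim = 16, epochs = 2, seed = 1))
  for (nm in ner_variants()) {
    v <- small_variant(nm, seed = 1, epochs = 1)
    m <- train_ner(corpus$docs[1:16], corpus$docs[17:20], v, encoder = enc)
    expect_s3_class(m, "hich_ner")
    expect_equal(nrow(m$trace), 1)
    tags <- predict(m, corpus$docs[[21]])
    expect_length(tags, length(corpus$docs[[21]]$tokens))
    expect_true(all(tags %in% tag_alphabet()))
  }
})

test_that("span decoding handles gold reproduction, all-O, and adjacent entities", {
  corpus <- tiny_corpus()
  doc <- corpus$docs[[1]]
  gold <- tags_to_spans(doc$tags, doc$tokens)
  expect_identical(tags_to_spans(doc$tags, doc$tokens), gold)
  expect_equal(nrow(tags_to_spans(rep("O", 5))), 0)
  spans <- tags_to_spans(c("B-gcs", "B-gcs", "O"))
  expect_equal(nrow(spans), 2)
  expect_equal(spans$start, c(1, 2))
  # spans lie within bounds and never overlap
  expect_true(all(gold$start <= gold$end))
  expect_true(all(gold$end <= length(doc$tokens)))
  if (nrow(gold) > 1) expect_true(all(gold$start[-1] > gold$end[-nrow(gold)]))
  # a dangling I- from a decoder is treated as a span start
  expect_equal(tags_to_spans(c("O", "I-gcs", "I-gcs"))$start, 2)
})

test_that("entity metrics count exact span+type matches on the 0-100 scale", {
  g <- list(data.frame(start = c(1, 5), end = c(2, 6), type = c("gcs", "volume")))
  expect_equal(unname(ner_metrics(g, g)), c(100, 100, 100))
  p <- list(data.frame(start = c(1, 9), end = c(2, 9), type = c("gcs", "airway")))
  m <- ner_metrics(g, p)
  expect_equal(unname(m), c(50, 50, 50))
  expect_equal(f1_from_pr(92.03, 90.22), 91.11, tolerance = 0.005)
  expect_warning(m0 <- ner_metrics(g, list(data.frame())), "no predicted")
  expect_equal(unname(m0), c(0, 0, 0))
})

test_that("model checkpoints round-trip with their manifest", {
  corpus <- tiny_corpus()
  m <- train_ner(corpus$docs[1:10], corpus$docs[11:14],
                 small_variant("idcnn-crf", epochs = 1))
  path <- tempfile(fileext = ".rds")
  write_ner_model(m, path)
  back <- read_ner_model(path)
  expect_identical(back$params, m$params)
  expect_identical(predict(back, corpus$docs[[15]]), predict(m, corpus$docs[[15]]))
})
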