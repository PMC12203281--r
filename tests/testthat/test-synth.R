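test_that("profile sampling is seed-deterministic and honors degenerate configs", {
  expect_identical(sample_profile(seed = 7), sample_profile(seed = 7))
  cfg <- profile_config(gcs_total = dist_point(3))
  expect_equal(sample_profile(cfg, seed = 2)$gcs_total, 3)
  expect_error(profile_config(not_a_field = dist_point(1)), class = "hichds_config_error")
  expect_error(dist_cat(c("a", "b"), c(0.7, 0.7)), class = "hichds_config_error")
})

test_that("categorical prevalences are recovered within binomial error", {
  p_cereb <- 0.1
  cfg <- profile_config(hematoma_location = dist_cat(
    c("basal-ganglia", "thalamus", "lobar", "cerebellar", "brainstem"),
    c(0.5, 0.2, 0.1, p_cereb, 0.1)))
  n <- 10000
  profs <- sample_profiles(n, cfg, seed = 123)
  freq <- mean(vapply(profs, function(p) p$hematoma_location == "cerebellar", logical(1)))
  se <- sqrt(p_cereb * (1 - p_cereb) / n)
  expect_lt(abs(freq - p_cereb), 3 * se)
})

test_that("sampled profiles always satisfy the domain invariants", {
  profs <- sample_profiles(200, seed = 31)
  for (p in profs) expect_silent(validate_profile(p))
})

test_that("rendering verbalizes profile values as tagged spans", {
  p <- sample_profile(profile_config(gcs_total = dist_point(6)), seed = 4)
  doc <- render_emr(p, corruption = corruption_config(seed = 4))
  spans <- tags_to_spans(doc$tags, doc$tokens)
  gcs <- spans[spans$type == "gcs", ]
  expect_equal(nrow(gcs), 1)
  expect_true(grepl("\\b6\\b", gcs$text))
  vol <- spans[spans$type == "volume", ]
  expect_true(grepl(sprintf("\\b%d\\b", p$hematoma_volume), vol$text))
  expect_error(render_emr(p, template_bank = list()), class = "hichds_template_error")
  expect_error(render_emr(p, template_bank = list("no_such_slot")),
               class = "hichds_template_error")
})

test_that("zero corruption is the identity; full misspelling changes surface only", {
  p <- sample_profile(seed = 9)
  clean <- render_emr(p, corruption = corruption_config(0, 0, seed = 9))
  clean2 <- render_emr(p, corruption = corruption_config(0, 0, seed = 9))
  expect_identical(clean$text, clean2$text)
  noisy <- render_emr(p, corruption = corruption_config(1, 0, seed = 9))
  expect_identical(noisy$tags, clean$tags)
  expect_false(identical(noisy$tokens, clean$tokens))
  # corrupted positions keep their tags; entity spans unchanged
  expect_identical(tags_to_spans(noisy$tags), tags_to_spans(clean$tags))
})

test_that("rendered documents satisfy the BIO invariants for many seeds and rates", {
  for (s in 1:25) {
    p <- sample_profile(seed = 1000 + s)
    doc <- render_emr(p, corruption = corruption_config(
      misspell_rate = (s %% 5) / 5, abbreviation_rate = (s %% 3) / 3, seed = s))
    expect_silent(validate_document(doc))
  }
})

test_that("the preprocessor inverts the corrupter", {
  for (s in 1:20) {
    p <- sample_profile(seed = 2000 + s)
    clean <- render_emr(p, corruption = corruption_config(0, 0, seed = s))
    noisy <- render_emr(p, corruption = corruption_config(0.3, 0.5, seed = s))
    expect_identical(preprocess_text(noisy$text), preprocess_text(clean$text))
  }
})

test_that("preprocessing round-trips clean text and fixes known corruptions", {
  p <- sample_profile(seed = 77)
  clean <- render_emr(p, corruption = corruption_config(0, 0, seed = 77))
  expect_identical(preprocess_text(clean$text), clean$tokens)
  expect_identical(preprocess_text("pt with known HTN"),
                   c("patient", "with", "known", "hypertension"))
  # one injected edit-distance-1 misspelling of a lexicon word
  expect_identical(preprocess_text("longstanding hypertenson"),
                   c("longstanding", "hypertension"))
  # unknown tokens with no close neighbor pass through
  expect_identical(preprocess_text("zzzqqq"), "zzzqqq")
})

test_that("gold plans are invariant to rendering and corruption", {
  rs <- default_ruleset(); kg <- hich_kg()
  for (s in c(3, 14, 27)) {
    p <- sample_profile(seed = 3000 + s)
    gold <- decide_plan(profile_to_state(p), rs, kg)
    for (rates in list(c(0, 0), c(0.5, 0.5))) {
      doc <- render_emr(p, corruption = corruption_config(rates[1], rates[2], seed = s))
      st <- suppressWarnings(normalize_entities(tags_to_spans(doc$tags, doc$tokens),
                                                kg, structured = doc$meta))
      expect_identical(hichds:::plan_signature(decide_plan(st, rs, kg)),
                       hichds:::plan_signature(gold))
    }
  }
})

test_that("CoNLL round trip is lossless and malformed files are rejected by line", {
  corpus <- tiny_corpus()
  docs <- corpus$docs[1:10]
  path <- tempfile(fileext = ".conll")
  write_conll(docs, path)
  back <- read_conll(path)
  expect_equal(back, docs)
  # empty corpus -> empty file -> empty list
  path2 <- tempfile(fileext = ".conll")
  write_conll(list(), path2)
  expect_identical(read_conll(path2), list())
  # token without tag
  bad <- tempfile(fileext = ".conll")
  writeLines(c("# doc_id = d1", "token1\tO", "orphan"), bad)
  expect_error(read_conll(bad), "line 3", class = "hichds_parse_error")
  # dangling I- tag names its line
  bad2 <- tempfile(fileext = ".conll")
  writeLines(c("ok\tO", "oops\tI-gcs"), bad2)
  expect_error(read_conll(bad2), "line 2", class = "hichds_parse_error")
})
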