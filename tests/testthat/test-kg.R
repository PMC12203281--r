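test_that("the seed graph loads, round-trips, and collapses duplicates", {
  kg <- hich_kg()
  expect_gt(nrow(kg$triples), 100)
  path <- tempfile(fileext = ".tsv")
  kg_write(kg, path)
  expect_equal(kg_read(path)$triples, kg$triples)
  # duplicate triples count once
  dup <- tempfile(fileext = ".tsv")
  writeLines(c("a\tp\tb\tgeneral\tsrc", "a\tp\tb\tgeneral\tsrc"), dup)
  expect_equal(nrow(kg_read(dup)$triples), 1)
  # N-Triples round trip preserves the (s, p, o) set
  nt <- tempfile(fileext = ".nt")
  kg_write(kg, nt)
  back <- kg_read(nt)
  expect_setequal(paste(back$triples$subject, back$triples$predicate, back$triples$object),
                  paste(kg$triples$subject, kg$triples$predicate, kg$triples$object))
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("a\tp\tb\tgeneral\tsrc", "only-two\tfields"), bad)
  expect_error(kg_read(bad), "line 2", class = "hichds_parse_error")
})

test_that("seed graph tiers are the three knowledge dimensions with cited sources", {
  kg <- hich_kg()
  expect_true(all(kg$triples$tier %in% c("general", "subdomain", "subdomain-specific")))
  spec <- kg$triples[kg$triples$tier == "subdomain-specific", ]
  expect_true(all(nchar(spec$source) > 0))
  # synonym table values are entities present in the graph
  expect_true(all(kg$synonyms %in% kg$triples$subject))
})

test_that("queries match brute-force scans and join across shared variables", {
  kg <- hich_kg()
  # no-variable pattern matching an existing triple: one empty binding
  hit <- kg_query(kg, c("surgery", "part-of", "surgical-therapy"))
  expect_length(hit, 1)
  expect_length(hit[[1]], 0)
  expect_length(kg_query(kg, c("surgery", "part-of", "nowhere")), 0)
  # single-variable queries equal the linear-scan oracle
  pats <- list(c("?x", "supports", "surgery"),
               c("?x", "entity-type", "location"),
               c("hws-icp", "?p", "?o"),
               c("?s", "part-of", "?b"))
  for (pat in pats) {
    expect_identical(kg_query(kg, pat), scan_single_pattern(kg, pat))
  }
  # 2-pattern join on a 3-triple chain
  chain <- tempfile(fileext = ".tsv")
  writeLines(c("a\tnext\tb\tgeneral\t", "b\tnext\tc\tgeneral\t", "c\tnext\td\tgeneral\t"),
             chain)
  g <- kg_read(chain)
  sol <- kg_query(g, list(c("a", "next", "?m"), c("?m", "next", "?e")))
  expect_length(sol, 1)
  expect_identical(sol[[1]], c("?m" = "b", "?e" = "c"))
})

test_that("entity alignment: exact hits, synonym hits, thresholds, idempotence", {
  kg <- hich_kg()
  expect_equal(align_entity("loc-cerebellar", "location", kg), "loc-cerebellar")
  expect_equal(align_entity("GCS", "observation", kg), "obs-gcs")
  expect_equal(align_entity("left basal ganglia", "location", kg), "loc-basal-ganglia")
  # near-synonym below a strict threshold -> no match
  expect_true(is.na(align_entity("cerebellum region thing", "location", kg,
                                 threshold = 0.99)))
  # idempotence: aligning an aligned id returns itself
  ent <- align_entity("thalamic region", "location", kg)
  expect_equal(align_entity(ent, "location", kg), ent)
  # raising the threshold never adds matches
  mentions <- c("cerebelum", "pupls equal", "thalamus", "totally unrelated phrase")
  for (m in mentions) {
    lo <- align_entity(m, NULL, kg, threshold = 0.3)
    hi <- align_entity(m, NULL, kg, threshold = 0.9)
    if (!is.na(hi)) expect_false(is.na(lo))
  }
})

test_that("basis traces return cited triples in deterministic order", {
  kg <- hich_kg()
  tr <- basis_trace(kg, "hws-surg-supratentorial")
  expect_gte(nrow(tr), 2)
  expect_true(all(tr$subject == "hws-surg-supratentorial"))
  expect_false(is.unsorted(order(tr$predicate, tr$object)))
  expect_true(any(grepl("30 mL", tr$object)))
  # fired surgical rule traces to its guideline-source triple
  expect_true(all(nchar(tr$source) > 0))
  # entity with no supporting triples: empty with a warning
  expect_warning(out <- basis_trace(kg, "treatment-plan"), "no supporting")
  expect_equal(nrow(out), 0)
  expect_error(basis_trace(kg, "does-not-exist"), class = "hichds_lookup_error")
})

test_that("every surface phrase the renderer can produce aligns to its entity", {
  kg <- hich_kg()
  phrases <- hichds:::PHRASES
  check <- function(variants, type, expected) {
    for (v in variants) {
      got <- align_entity(paste(v, collapse = " "), type, kg)
      expect_equal(got, expected,
                   label = sprintf("alignment of '%s'", paste(v, collapse = " ")))
    }
  }
  for (loc in names(phrases$location)) {
    check(phrases$location[[loc]], "location", paste0("loc-", loc))
  }
  map_pupil <- c("bilateral-equal-reactive" = "pupil-equal",
                 "unilateral-dilated" = "pupil-unilateral-dilated",
                 "bilateral-dilated-fixed" = "pupil-fixed-dilated")
  for (p in names(phrases$pupil)) check(phrases$pupil[[p]], "pupil", unname(map_pupil[p]))
  for (a in names(phrases$airway)) check(phrases$airway[[a]], "airway", paste0("airway-", a))
  for (h in names(phrases$history)) check(phrases$history[[h]], "history", paste0("hx-", h))
  for (s in names(phrases$suspicion)) {
    check(phrases$suspicion[[s]], "suspicion", paste0("susp-", s))
  }
  check(phrases$ventcomp, "ventricular-finding", "vent-compression")
  check(phrases$ivh, "ventricular-finding", "vent-ivh")
})
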