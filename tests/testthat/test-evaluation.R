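test_that("classification metrics match hand arithmetic and flag undefined cases", {
  m <- classification_metrics(tp = 25, fp = 25, tn = 25, fn = 25)
  expect_true(all(m == 50))
  m <- classification_metrics(tp = 90, fn = 10, tn = 80, fp = 20)
  expect_equal(unname(m[c("sensitivity", "specificity", "accuracy")]), c(90, 80, 85))
  m <- classification_metrics(tp = 7, fp = 0, tn = 5, fn = 0)
  expect_true(all(m == 100))
  # zero denominator -> NA, not 0
  m <- classification_metrics(tp = 0, fp = 0, tn = 10, fn = 0)
  expect_true(is.na(m[["sensitivity"]]))
  expect_error(classification_metrics(0, 0, 0, 0), class = "hichds_contract_error")
})

test_that("roc_auc equals the all-pairs Mann-Whitney count", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(roc_auc(rep(1, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)), 0.5)
  set.seed(9)
  for (rep_i in 1:20) {
    n <- sample(4:12, 1)
    scores <- sample(1:5, n, replace = TRUE)  # ties on purpose
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    pos <- scores[labels]; neg <- scores[!labels]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(roc_auc(scores, labels), mean(pairs))
  }
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), class = "hichds_contract_error")
})

test_that("cohens_kappa matches direct p_o/p_e arithmetic and boundary cases", {
  expect_equal(cohens_kappa(diag(c(12, 30, 5))), 1)
  expect_equal(cohens_kappa(matrix(25, 2, 2)), 0)
  tab <- matrix(c(20, 10, 5, 15), 2)  # rows rater 1: (20,5),(10,15)
  p_o <- (20 + 15) / 50
  p_e <- (25 * 30 + 25 * 20) / 50^2
  expect_equal(cohens_kappa(tab), (p_o - p_e) / (1 - p_e))
  expect_error(cohens_kappa(matrix(c(10, 0, 0, 0), 2)), class = "hichds_contract_error")
})

test_that("f1_from_pr is the harmonic mean with the documented boundary", {
  expect_equal(f1_from_pr(77, 77), 77)
  expect_equal(f1_from_pr(0, 0), 0)
  set.seed(4)
  p <- runif(50, 0, 100); r <- runif(50, 0, 100)
  f <- f1_from_pr(p, r)
  expect_true(all(f >= pmin(p, r) - 1e-12 & f <= pmax(p, r) + 1e-12))
})

test_that("pooled_accuracy is the case-weighted mean and stays inside the range", {
  expect_equal(pooled_accuracy(10, 88.5), 88.5)
  expect_equal(pooled_accuracy(c(5, 5, 5), c(90, 80, 70)), 80)
  set.seed(11)
  for (i in 1:10) {
    n <- sample(1:500, 4)
    a <- runif(4, 50, 100)
    pooled <- pooled_accuracy(n, a)
    expect_gte(pooled, min(a))
    expect_lte(pooled, max(a))
  }
})

test_that("rubric scores award per-item shares and surgery all-or-nothing", {
  cfg <- rubric_config()
  corpus <- tiny_corpus()
  gold <- corpus$gold_plans[[1]]
  expect_equal(unname(rubric_score(gold, gold, cfg)[["total"]]), 100)
  flipped <- gold
  flipped$surgical <- !flipped$surgical
  expect_equal(unname(rubric_score(flipped, gold, cfg)[["total"]]), 60)
  # empty plan: surgery agreement depends on gold; categories below maximum
  empty <- structure(list(diagnostic = character(0), surgical = FALSE,
                          rescue = character(0), drugs = character(0)),
                     class = "treatment_plan")
  g_surg <- corpus$gold_plans[[which(vapply(corpus$gold_plans, `[[`, TRUE, "surgical"))[1]]]
  s <- rubric_score(empty, g_surg, cfg)
  expect_equal(unname(s[["surgical"]]), 0)
  expect_lt(s[["rescue"]], cfg$maxima[["rescue"]])
  expect_lt(s[["total"]], 100)
  # monotone: adding a correct item never lowers the total
  partial <- empty
  partial$rescue <- intersect(plan_items()$rescue, g_surg$rescue[1])
  expect_gte(rubric_score(partial, g_surg, cfg)[["total"]],
             rubric_score(empty, g_surg, cfg)[["total"]])
  expect_error(rubric_score(structure(list(diagnostic = "PET", surgical = FALSE,
                                           rescue = character(0), drugs = character(0)),
                                      class = "treatment_plan"), gold, cfg),
               class = "hichds_taxonomy_error")
})

test_that("score distributions use the <60 / 60-80 / >80 convention and sum to 100", {
  cfg <- rubric_config()
  expect_equal(unname(score_distribution(rep(100, 5), cfg)), c(0, 0, 100))
  d <- score_distribution(c(90, 70, 50), cfg)
  expect_equal(unname(d), rep(100 / 3, 3))
  expect_equal(sum(d), 100, tolerance = 0.01)
  # boundary membership: 60 and 80 fall in the middle bin
  d <- score_distribution(c(60, 80), cfg)
  expect_equal(unname(d), c(0, 100, 0))
  expect_error(score_distribution(numeric(0), cfg), class = "hichds_contract_error")
})
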