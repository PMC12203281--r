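# Plan- and classifier-level evaluation: confusion-matrix metrics, ROC/AUC by the
# Mann-Whitney rank formulation, Cohen's kappa, the 100-point plan rubric with
# score-bin distributions, and case-weighted pooling of per-center accuracies.

#' Confusion-matrix classification metrics
#'
#' Computes sensitivity, specificity, accuracy, positive predictive value and
#' negative predictive value from raw confusion counts, on the 0-100 scale used
#' in clinical reporting. A metric whose denominator is zero is returned as
#' `NA` (flagged undefined), never silently as 0.
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return Named numeric vector with elements `sensitivity`, `specificity`,
#'   `accuracy`, `ppv`, `npv`, each in \[0, 100\] or `NA` when undefined.
#' @examples
#' classification_metrics(tp = 90, fn = 10, tn = 80, fp = 20)
#' @export
classification_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop_hichds("confusion counts must be non-negative integers", class = "hichds_contract_error")
  }
  if (sum(counts) == 0) {
    stop_hichds("confusion counts are all zero; no data to evaluate", class = "hichds_contract_error")
  }
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  c(
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    accuracy    = ratio(tp + tn, tp + fp + tn + fn),
    ppv         = ratio(tp, tp + fp),
    npv         = ratio(tn, tn + fn)
  )
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' AUC as the probability that a randomly chosen positive case receives a
#' higher score than a randomly chosen negative case, with ties counted 1/2 —
#' computed from midranks, which is exactly the trapezoidal area under the
#' empirical ROC curve.
#'
#' @param scores Numeric vector of classifier scores (higher = more positive).
#' @param labels Logical (or 0/1) vector of true classes, same length.
#' @return A single number in \[0, 1\].
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.1), c(TRUE, TRUE, FALSE, FALSE)) # 1
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels)) {
    stop_hichds("scores and labels must be complete and of equal length", class = "hichds_contract_error")
  }
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop_hichds("roc_auc needs both classes present", class = "hichds_contract_error")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Cohen's kappa for a two-rater contingency table
#'
#' Chance-corrected agreement \eqn{(p_o - p_e)/(1 - p_e)} where \eqn{p_e} is
#' the expected agreement under independent raters with the observed margins.
#'
#' @param table Square numeric matrix of category counts (rows = rater 1,
#'   columns = rater 2).
#' @return Kappa, at most 1; 1 iff all mass is on the diagonal.
#' @examples
#' cohens_kappa(matrix(c(20, 10, 5, 15), 2)) # moderate agreement
#' @export
cohens_kappa <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != ncol(table) || any(table < 0)) {
    stop_hichds("rater table must be a square non-negative matrix", class = "hichds_contract_error")
  }
  n <- sum(table)
  if (n == 0) stop_hichds("rater table is empty", class = "hichds_contract_error")
  p_o <- sum(diag(table)) / n
  p_e <- sum(rowSums(table) * colSums(table)) / n^2
  if (1 - p_e < .Machine$double.eps^0.5) {
    stop_hichds("expected agreement is 1; kappa undefined", class = "hichds_contract_error")
  }
  (p_o - p_e) / (1 - p_e)
}

#' F1 score from precision and recall
#'
#' Harmonic mean \eqn{F_1 = 2PR/(P+R)} on the 0-100 scale.
#'
#' @param p,r Precision and recall, 0-100.
#' @return F1 on the same scale; 0 when both inputs are 0.
#' @examples
#' f1_from_pr(92.03, 90.22) # 91.11 to two decimals
#' @export
f1_from_pr <- function(p, r) {
  if (any(p < 0) || any(r < 0)) {
    stop_hichds("precision and recall must be non-negative", class = "hichds_contract_error")
  }
  ifelse(p + r == 0, 0, 2 * p * r / (p + r))
}

#' Case-weighted pooled accuracy across groups
#'
#' Pools per-group accuracies as \eqn{\sum n_i a_i / \sum n_i}, the accuracy
#' the combined case set would show.
#'
#' @param n Integer vector of group sizes.
#' @param accuracy Numeric vector of per-group accuracies (any common scale).
#' @return The pooled accuracy on the same scale as the input.
#' @examples
#' pooled_accuracy(c(216, 128), c(92.04, 91.93))
#' @export
pooled_accuracy <- function(n, accuracy) {
  if (length(n) != length(accuracy) || length(n) == 0 || any(n <= 0)) {
    stop_hichds("need matching positive group sizes and accuracies", class = "hichds_contract_error")
  }
  sum(n * accuracy) / sum(n)
}

#' Rubric configuration for treatment-plan scoring
#'
#' The 100-point plan rubric: 15 points for diagnostic measures and 85 for
#' therapeutic measures, the latter split 40 (surgical, all-or-nothing) +
#' 35 (rescue) + 10 (drug). Within the diagnostic, rescue and drug categories
#' each decisive item carries an equal share of the category maximum and is
#' awarded when predicted and gold agree on it (both present or both absent).
#'
#' @param diagnostic,surgical,rescue,drug Category maxima (defaults 15/40/35/10).
#' @param bin_edges Score-fraction cut points for [score_distribution()]
#'   (defaults `c(0.6, 0.8)`: the `<60%`, `60-80%`, `>80%` bins).
#' @return An object of class `rubric_config`.
#' @export
rubric_config <- function(diagnostic = 15, surgical = 40, rescue = 35, drug = 10,
                          bin_edges = c(0.6, 0.8)) {
  stopifnot(diagnostic >= 0, surgical >= 0, rescue >= 0, drug >= 0,
            length(bin_edges) >= 1, !is.unsorted(bin_edges))
  structure(
    list(
      maxima = c(diagnostic = diagnostic, surgical = surgical,
                 rescue = rescue, drug = drug),
      total = diagnostic + surgical + rescue + drug,
      bin_edges = bin_edges
    ),
    class = "rubric_config"
  )
}

#' Score a predicted treatment plan against a gold plan
#'
#' @param predicted,gold `treatment_plan` objects sharing the item taxonomy
#'   (see [decide_plan()]).
#' @param config A [rubric_config()].
#' @return Named numeric vector: per-category points and `total`.
#' @examples
#' cfg <- rubric_config()
#' @export
rubric_score <- function(predicted, gold, config = rubric_config()) {
  for (p in list(predicted, gold)) {
    if (!inherits(p, "treatment_plan")) {
      stop_hichds("rubric_score expects treatment_plan objects", class = "hichds_taxonomy_error")
    }
  }
  share_points <- function(items_pred, items_gold, universe, maximum) {
    bad <- setdiff(c(items_pred, items_gold), universe)
    if (length(bad)) {
      stop_hichds("unknown plan item(s): %s", paste(bad, collapse = ", "),
                  class = "hichds_taxonomy_error")
    }
    agree <- vapply(universe, function(it) {
      (it %in% items_pred) == (it %in% items_gold)
    }, logical(1))
    maximum * sum(agree) / length(universe)
  }
  m <- config$maxima
  diag_pts <- share_points(predicted$diagnostic, gold$diagnostic,
                           plan_items()$diagnostic, m[["diagnostic"]])
  surg_pts <- if (isTRUE(predicted$surgical) == isTRUE(gold$surgical)) m[["surgical"]] else 0
  resc_pts <- share_points(predicted$rescue, gold$rescue,
                           plan_items()$rescue, m[["rescue"]])
  drug_pts <- share_points(predicted$drugs, gold$drugs,
                           plan_items()$drugs, m[["drug"]])
  c(diagnostic = diag_pts, surgical = surg_pts, rescue = resc_pts,
    drug = drug_pts, total = diag_pts + surg_pts + resc_pts + drug_pts)
}

#' Distribution of rubric scores over bins
#'
#' Bins scores by fraction of the attainable maximum (default `<60%`,
#' `60-80%`, `>80%`) and reports the percentage of cases per bin.
#'
#' @param scores Numeric vector of rubric totals (or category scores).
#' @param config A [rubric_config()]; its `bin_edges` and `total` define bins.
#' @param maximum Attainable maximum for `scores` (default the config total).
#' @return Named numeric vector of percentages summing to 100.
#' @export
score_distribution <- function(scores, config = rubric_config(), maximum = config$total) {
  if (length(scores) == 0) {
    stop_hichds("score_distribution needs at least one score", class = "hichds_contract_error")
  }
  edges <- config$bin_edges * maximum
  k <- length(edges)
  labs <- character(k + 1)
  labs[1] <- sprintf("<%g", edges[1])
  if (k > 1) {
    for (i in seq_len(k - 1)) labs[i + 1] <- sprintf("%g-%g", edges[i], edges[i + 1])
  }
  labs[k + 1] <- sprintf(">%g", edges[k])
  # bottom bin open (< e1), interior bins closed (e_i <= s <= e_{i+1}, ties to
  # the lower bin), top bin open (> ek) -- the "<60 / 60-80 / >80" convention
  assign_bin <- function(s) {
    if (s < edges[1]) return(1L)
    if (s > edges[k]) return(k + 1L)
    if (k >= 2) for (i in 2:k) if (s <= edges[i]) return(i)
    2L
  }
  idx <- vapply(scores, assign_bin, integer(1))
  out <- 100 * tabulate(idx, nbins = k + 1) / length(scores)
  names(out) <- labs
  out
}
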