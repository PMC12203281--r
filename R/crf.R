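# Linear-chain conditional random field over the BIO tag alphabet.
#
# A tag path y_1..y_n is scored as
#   start[y_1] + sum_t emissions[t, y_t] + sum_t transitions[y_{t-1}, y_t] + stop[y_n]
# and P(Y|X) = exp(score) / R(X) with R(X) the sum of exp(score) over all L^n
# paths, computed by the forward recursion in log space. The start/stop vectors
# are the boundary terms for t = 1 and t = n + 1; they default to zero and are
# learned during NER training.

#' Parameters of a linear-chain CRF
#'
#' @param transitions L x L matrix of tag-to-tag transition scores
#'   (`transitions[i, j]` scores moving from tag i to tag j).
#' @param start,stop Length-L boundary score vectors for the first and the
#'   after-last position (default zero).
#' @param tags Optional character vector of tag names (row/column labels).
#' @return An object of class `crf_params`.
#' @export
crf_params <- function(transitions, start = NULL, stop = NULL, tags = NULL) {
  transitions <- as.matrix(transitions)
  L <- nrow(transitions)
  if (ncol(transitions) != L) {
    stop_hichds("transition matrix must be square", class = "hichds_shape_error")
  }
  start <- start %||% numeric(L)
  stop_ <- stop %||% numeric(L)
  if (length(start) != L || length(stop_) != L) {
    stop_hichds("boundary vectors must have length %d", L, class = "hichds_shape_error")
  }
  structure(list(transitions = transitions, start = start, stop = stop_,
                 tags = tags %||% rownames(transitions)),
            class = "crf_params")
}

check_emissions <- function(emissions, params) {
  emissions <- as.matrix(emissions)
  if (nrow(emissions) == 0) {
    stop_hichds("CRF requires a non-empty sequence", class = "hichds_contract_error")
  }
  if (ncol(emissions) != nrow(params$transitions)) {
    stop_hichds("emissions have %d columns but the tag alphabet has %d tags",
                ncol(emissions), nrow(params$transitions), class = "hichds_shape_error")
  }
  emissions
}

#' Log partition function of a linear-chain CRF
#'
#' The log of the normalizer R(X): the sum over all tag sequences of the
#' exponentiated path score, computed by the forward recursion in log space.
#'
#' @param emissions Numeric matrix, sequence length x alphabet size.
#' @param params A [crf_params()].
#' @return `log R(X)`, a single number.
#' @examples
#' p <- crf_params(matrix(0, 2, 2))
#' crf_partition(matrix(0, 3, 2), p) # 3 * log(2)
#' @export
crf_partition <- function(emissions, params) {
  emissions <- check_emissions(emissions, params)
  alpha <- params$start + emissions[1, ]
  n <- nrow(emissions)
  if (n > 1) {
    for (t in 2:n) {
      # alpha_t(j) = logsumexp_i(alpha_{t-1}(i) + trans[i,j]) + em[t,j]
      alpha <- apply(alpha + params$transitions, 2, logsumexp) + emissions[t, ]
    }
  }
  logsumexp(alpha + params$stop)
}

crf_path_score <- function(emissions, params, tags_idx) {
  n <- nrow(emissions)
  s <- params$start[tags_idx[1]] + sum(emissions[cbind(seq_len(n), tags_idx)]) +
    params$stop[tags_idx[n]]
  if (n > 1) {
    s <- s + sum(params$transitions[cbind(tags_idx[-n], tags_idx[-1])])
  }
  s
}

resolve_tag_indices <- function(tags, params, n) {
  if (length(tags) != n) {
    stop_hichds("tag sequence length %d does not match emissions length %d",
                length(tags), n, class = "hichds_label_error")
  }
  L <- nrow(params$transitions)
  if (is.character(tags)) {
    if (is.null(params$tags)) {
      stop_hichds("character tags given but crf_params has no tag names", class = "hichds_label_error")
    }
    idx <- match(tags, params$tags)
  } else {
    idx <- as.integer(tags)
  }
  if (anyNA(idx) || any(idx < 1) || any(idx > L)) {
    stop_hichds("tag outside the alphabet", class = "hichds_label_error")
  }
  idx
}

#' Log conditional likelihood of a tag sequence under a CRF
#'
#' `log P(Y|X)` = path score minus the log partition; always <= 0.
#'
#' @inheritParams crf_partition
#' @param tags Integer tag indices (1-based) or tag names, one per position.
#' @return A single non-positive number.
#' @export
crf_log_likelihood <- function(emissions, params, tags) {
  emissions <- check_emissions(emissions, params)
  idx <- resolve_tag_indices(tags, params, nrow(emissions))
  crf_path_score(emissions, params, idx) - crf_partition(emissions, params)
}

#' Maximum a-posteriori tag sequence (Viterbi decoding)
#'
#' Returns a tag path attaining the maximal score; exact ties are broken
#' toward the lowest tag index at the latest position where tied paths differ
#' (the behavior of first-argmax backtracking).
#'
#' @inheritParams crf_partition
#' @return Integer vector of 1-based tag indices (named with tag labels when
#'   `params$tags` is set).
#' @export
viterbi_decode <- function(emissions, params) {
  emissions <- check_emissions(emissions, params)
  n <- nrow(emissions)
  L <- ncol(emissions)
  delta <- params$start + emissions[1, ]
  psi <- matrix(0L, n, L)
  if (n > 1) {
    for (t in 2:n) {
      m <- delta + params$transitions           # m[i, j]
      psi[t, ] <- apply(m, 2, which.max)
      delta <- m[cbind(psi[t, ], seq_len(L))] + emissions[t, ]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta + params$stop)
  if (n > 1) for (t in n:2) path[t - 1] <- psi[t, path[t]]
  if (!is.null(params$tags)) names(path) <- params$tags[path]
  path
}

# Forward-backward quantities for training: node marginals, expected transition
# counts, and boundary marginals. Gradient of -logP wrt emissions is
# (marginal - onehot), wrt transitions is (expected - observed counts).
crf_forward_backward <- function(emissions, params) {
  emissions <- check_emissions(emissions, params)
  n <- nrow(emissions); L <- ncol(emissions)
  A <- params$transitions
  alpha <- matrix(0, n, L)
  alpha[1, ] <- params$start + emissions[1, ]
  if (n > 1) for (t in 2:n) {
    alpha[t, ] <- apply(alpha[t - 1, ] + A, 2, logsumexp) + emissions[t, ]
  }
  beta <- matrix(0, n, L)
  beta[n, ] <- params$stop
  if (n > 1) for (t in (n - 1):1) {
    beta[t, ] <- apply(sweep(A, 2, emissions[t + 1, ] + beta[t + 1, ], `+`), 1, logsumexp)
  }
  logZ <- logsumexp(alpha[n, ] + params$stop)
  marg <- exp(alpha + beta - logZ)                  # n x L node marginals
  pair <- matrix(0, L, L)                           # expected transition counts
  if (n > 1) for (t in 1:(n - 1)) {
    lp <- outer(alpha[t, ], emissions[t + 1, ] + beta[t + 1, ], `+`) + A - logZ
    pair <- pair + exp(lp)
  }
  list(logZ = logZ, marginals = marg, pair = pair,
       start_marg = marg[1, ], stop_marg = marg[n, ])
}
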