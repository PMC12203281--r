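# Independent oracles used across the suite. These deliberately avoid the
# implementation paths they check: brute-force enumeration for the CRF,
# direct support enumeration for receptive fields, and linear scans for the
# triple store.

# enumerate all L^n tag paths and score them directly
enumerate_paths <- function(n, L) {
  as.matrix(do.call(expand.grid, rep(list(seq_len(L)), n)))
}

brute_path_score <- function(emissions, params, path) {
  n <- nrow(emissions)
  s <- params$start[path[1]] + params$stop[path[n]]
  for (t in seq_len(n)) s <- s + emissions[t, path[t]]
  if (n > 1) for (t in 2:n) s <- s + params$transitions[path[t - 1], path[t]]
  s
}

brute_log_partition <- function(emissions, params) {
  paths <- enumerate_paths(nrow(emissions), ncol(emissions))
  scores <- apply(paths, 1, function(p) brute_path_score(emissions, params, p))
  m <- max(scores)
  m + log(sum(exp(scores - m)))
}

brute_best_score <- function(emissions, params) {
  paths <- enumerate_paths(nrow(emissions), ncol(emissions))
  max(apply(paths, 1, function(p) brute_path_score(emissions, params, p)))
}

random_crf_instance <- function(n, L) {
  list(emissions = matrix(stats::rnorm(n * L), n, L),
       params = crf_params(matrix(stats::rnorm(L * L), L, L),
                           start = stats::rnorm(L), stop = stats::rnorm(L)))
}

# receptive field by enumerating which input positions can influence output 0
enumerate_receptive_field <- function(kernel, dilations, layer) {
  half <- (kernel - 1) / 2
  support <- 0
  for (l in seq_len(layer)) {
    offs <- dilations[l] * (-half:half)
    support <- unique(as.vector(outer(support, offs, `+`)))
  }
  length(support)
}

# linear-scan evaluation of a single-pattern query (used as the query oracle)
scan_single_pattern <- function(graph, pat) {
  tr <- graph$triples
  cols <- c("subject", "predicate", "object")
  hits <- rep(TRUE, nrow(tr))
  for (k in 1:3) {
    if (!startsWith(pat[k], "?")) hits <- hits & tr[[cols[k]]] == pat[k]
  }
  out <- lapply(which(hits), function(row) {
    b <- character(0)
    for (k in 1:3) if (startsWith(pat[k], "?")) b[pat[k]] <- tr[[cols[k]]][row]
    b
  })
  # same shared-variable semantics as the engine: drop inconsistent rows
  ok <- vapply(out, function(b) !anyDuplicated(names(b)) ||
                 all(tapply(b, names(b), function(v) length(unique(v)) == 1)),
               logical(1))
  out <- out[ok]
  unique(out[order(vapply(out, function(b) paste(names(b), b, collapse = ";"), ""))])
}

# small corpus shared by several tests (built once per test run)
tiny_corpus <- local({
  cache <- NULL
  function(n = 30, seed = 42, misspell = 0.02, abbrev = 0.1) {
    key <- paste(n, seed, misspell, abbrev)
    if (is.null(cache) || !identical(attr(cache, "key"), key)) {
      out <- synth_corpus(n, seed, misspell = misspell, abbrev = abbrev)
      attr(out, "key") <- key
      cache <<- out
    }
    cache
  }
})

small_variant <- function(name, seed = 1, epochs = 2) {
  variant_config(name, embed_dim = 16, hidden = 8, epochs = epochs, seed = seed,
                 lr = 0.02, mlm = mlm_config(dim = 16, epochs = 2, seed = seed))
}
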