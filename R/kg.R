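# Provenance-tagged knowledge-graph triple store with conjunctive
# basic-graph-pattern queries and mention-to-entity alignment. The store is a
# plain triple table (subject, predicate, object, tier, source) with
# subject/predicate/object indexes and a synonym table derived from
# `has-synonym` triples; tiers follow the three knowledge dimensions
# (general, subdomain, subdomain-specific).

KG_TIERS <- c("general", "subdomain", "subdomain-specific")

kg_build <- function(triples) {
  triples <- unique(triples[, c("subject", "predicate", "object", "tier", "source")])
  if (any(triples$subject == "" | triples$predicate == "")) {
    stop_hichds("triples must have non-empty subject and predicate", class = "hichds_parse_error")
  }
  bad <- setdiff(triples$tier, KG_TIERS)
  if (length(bad)) {
    stop_hichds("unknown knowledge tier(s): %s", paste(bad, collapse = ", "),
                class = "hichds_parse_error")
  }
  ord <- order(triples$subject, triples$predicate, triples$object)
  triples <- triples[ord, , drop = FALSE]
  rownames(triples) <- NULL
  syn_rows <- triples$predicate == "has-synonym"
  synonyms <- triples$subject[syn_rows]
  names(synonyms) <- tolower(triples$object[syn_rows])
  structure(list(
    triples = triples,
    index = list(subject = split(seq_len(nrow(triples)), triples$subject),
                 predicate = split(seq_len(nrow(triples)), triples$predicate),
                 object = split(seq_len(nrow(triples)), triples$object)),
    synonyms = synonyms
  ), class = "hich_kg")
}

#' Load a knowledge graph from disk
#'
#' Accepts the 5-column TSV dialect (subject, predicate, object, tier,
#' source) or N-Triples (`.nt`, in which case tier defaults to `general` and
#' source is empty). Duplicate triples collapse to one (set semantics).
#'
#' @param path File path (`.tsv` or `.nt`).
#' @return An object of class `hich_kg`.
#' @export
kg_read <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines_keep <- which(!grepl("^\\s*(#|$)", lines))
  if (grepl("\\.nt$", path)) {
    rows <- lapply(lines_keep, function(ln) {
      m <- regmatches(lines[ln],
                      regexec("^<([^>]+)>\\s+<([^>]+)>\\s+(?:<([^>]+)>|\"([^\"]*)\")\\s*\\.\\s*$",
                              lines[ln]))[[1]]
      if (length(m) == 0 || m[1] == "") {
        stop_hichds("line %d: malformed N-Triples statement", ln, class = "hichds_parse_error")
      }
      obj <- if (m[4] != "") m[4] else m[5]
      data.frame(subject = m[2], predicate = m[3], object = obj,
                 tier = "general", source = "", stringsAsFactors = FALSE)
    })
  } else {
    rows <- lapply(lines_keep, function(ln) {
      parts <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
      if (length(parts) < 3) {
        stop_hichds("line %d: expected at least 3 tab-separated fields", ln,
                    class = "hichds_parse_error")
      }
      data.frame(subject = parts[1], predicate = parts[2], object = parts[3],
                 tier = if (length(parts) >= 4 && parts[4] != "") parts[4] else "general",
                 source = if (length(parts) >= 5) parts[5] else "",
                 stringsAsFactors = FALSE)
    })
  }
  kg_build(do.call(rbind, rows))
}

#' Save a knowledge graph to disk
#'
#' @param graph A `hich_kg`.
#' @param path Output path; `.nt` writes N-Triples (tier/source dropped, as
#'   the exchange format has no slot for them), anything else the 5-column TSV.
#' @return `path`, invisibly.
#' @export
kg_write <- function(graph, path) {
  tr <- graph$triples
  if (grepl("\\.nt$", path)) {
    is_lit <- grepl("[^A-Za-z0-9_:/.-]", tr$object) | grepl("^[0-9]", tr$object)
    obj <- ifelse(is_lit, sprintf("\"%s\"", tr$object), sprintf("<%s>", tr$object))
    writeLines(sprintf("<%s> <%s> %s .", tr$subject, tr$predicate, obj), path,
               useBytes = TRUE)
  } else {
    writeLines(paste(tr$subject, tr$predicate, tr$object, tr$tier, tr$source,
                     sep = "\t"), path, useBytes = TRUE)
  }
  invisible(path)
}

#' The shipped HICH seed knowledge graph
#'
#' About 120 triples encoding the plan taxonomy, canonical clinical entities
#' with their surface synonyms, and guideline-sourced indication links used
#' by the rule engine's explanation traces. The graph is data
#' (`inst/extdata/hich_kg_seed.tsv`), editable without code changes.
#'
#' @return A `hich_kg`.
#' @export
hich_kg <- function() {
  if (is.null(kg_cache$seed_graph)) {
    kg_cache$seed_graph <- kg_read(system.file("extdata", "hich_kg_seed.tsv",
                                               package = "hichds", mustWork = TRUE))
  }
  kg_cache$seed_graph
}

kg_cache <- new.env(parent = emptyenv())

is_var <- function(x) startsWith(x, "?")

#' Conjunctive basic-graph-pattern query
#'
#' Each pattern is a `(subject, predicate, object)` triple where any position
#' may be a variable (`?name`); variables shared across patterns join.
#' Returns every binding satisfying all patterns, in deterministic order
#' (sorted by binding values).
#'
#' @param graph A `hich_kg`.
#' @param pattern A single length-3 character vector, or a list of them.
#' @return A list of named character vectors (one per solution); a pattern
#'   set with no variables yields one empty binding per full match.
#' @examples
#' \dontrun{kg_query(hich_kg(), c("?x", "part-of", "diagnostic-measures"))}
#' @export
kg_query <- function(graph, pattern) {
  if (!is.list(pattern)) pattern <- list(pattern)
  if (!length(pattern) || !all(lengths(pattern) == 3)) {
    stop_hichds("query needs at least one (s, p, o) pattern", class = "hichds_contract_error")
  }
  tr <- graph$triples
  bindings <- list(structure(character(0), names = character(0)))
  for (pat in pattern) {
    new_bindings <- list()
    for (b in bindings) {
      resolved <- vapply(pat, function(x) {
        if (is_var(x) && x %in% names(b)) b[[x]] else x
      }, character(1))
      hits <- rep(TRUE, nrow(tr))
      cols <- c("subject", "predicate", "object")
      for (k in 1:3) {
        if (!is_var(resolved[k])) hits <- hits & tr[[cols[k]]] == resolved[k]
      }
      for (row in which(hits)) {
        nb <- b
        ok <- TRUE
        for (k in 1:3) {
          if (is_var(resolved[k])) {
            v <- resolved[k]
            val <- tr[[cols[k]]][row]
            if (v %in% names(nb) && nb[[v]] != val) { ok <- FALSE; break }
            nb[v] <- val
          }
        }
        if (ok) new_bindings[[length(new_bindings) + 1]] <- nb
      }
    }
    bindings <- unique(new_bindings)
  }
  if (length(bindings) > 1) {
    keyfun <- function(b) paste(names(b), b, sep = "=", collapse = ";")
    bindings <- bindings[order(vapply(bindings, keyfun, character(1)))]
  }
  bindings
}

# character-bigram Dice coefficient; the default mention similarity
bigram_dice <- function(a, b) {
  grams <- function(s) {
    s <- tolower(s)
    if (nchar(s) < 2) return(s)
    substring(s, 1:(nchar(s) - 1), 2:nchar(s))
  }
  ga <- grams(a); gb <- grams(b)
  if (!length(ga) || !length(gb)) return(0)
  2 * length(intersect(ga, gb)) / (length(unique(ga)) + length(unique(gb)))
}

# canonical entity ids of a given entity type (via entity-type triples)
kg_entities_of_type <- function(graph, type) {
  tr <- graph$triples
  sort(tr$subject[tr$predicate == "entity-type" & tr$object == type])
}

kg_entity_names <- function(graph, entity) {
  tr <- graph$triples
  syn <- tr$object[tr$subject == entity & tr$predicate == "has-synonym"]
  unique(c(entity, syn))
}

# laterality and filler words stripped before synonym lookup
strip_mention <- function(mention) {
  toks <- tolower(tokenize_text(mention))
  toks <- toks[!toks %in% c("left", "right")]
  paste(toks, collapse = " ")
}

#' Align a textual mention to a canonical knowledge-graph entity
#'
#' An exact synonym-table hit (after lowercasing and laterality stripping)
#' short-circuits similarity computation; otherwise the most similar entity
#' of the matching type is returned when its score reaches the threshold,
#' ties broken lexicographically by entity id.
#'
#' @param mention Mention text.
#' @param type Entity type restricting candidates (an `entity-type` object in
#'   the graph); `NULL` searches all typed entities.
#' @param graph A `hich_kg`.
#' @param similarity Symmetric similarity with self-similarity 1 (default:
#'   character-bigram Dice).
#' @param threshold Minimum similarity in \[0, 1\] (default 0.8).
#' @return Canonical entity id, or `NA_character_` when nothing qualifies.
#' @export
align_entity <- function(mention, type = NULL, graph, similarity = bigram_dice,
                         threshold = 0.8) {
  key <- strip_mention(mention)
  hit <- graph$synonyms[key]
  if (!is.na(hit)) return(unname(hit))
  if (key %in% graph$triples$subject) return(key)  # already canonical
  cands <- if (is.null(type)) {
    sort(unique(graph$triples$subject[graph$triples$predicate == "entity-type"]))
  } else {
    kg_entities_of_type(graph, type)
  }
  if (!length(cands)) return(NA_character_)
  best <- NA_character_; best_score <- -Inf
  for (ent in cands) {
    sc <- max(vapply(kg_entity_names(graph, ent), similarity, numeric(1), b = key))
    if (sc > best_score + 1e-12) { best <- ent; best_score <- sc }
  }
  if (best_score >= threshold) best else NA_character_
}

#' Supporting triples for an entity or rule reference
#'
#' Every triple whose subject is the reference, with its source citation, in
#' deterministic (predicate, object) order. An entity present in the graph
#' but with no supporting triples yields an empty list with a warning; an
#' unknown reference is a lookup error.
#'
#' @param graph A `hich_kg`.
#' @param ref Entity or rule-concept identifier.
#' @return Data frame of triples (subject, predicate, object, tier, source).
#' @export
basis_trace <- function(graph, ref) {
  tr <- graph$triples
  known <- ref %in% tr$subject | ref %in% tr$object
  if (!known) {
    stop_hichds("unknown knowledge-graph reference '%s'", ref, class = "hichds_lookup_error")
  }
  out <- tr[tr$subject == ref, , drop = FALSE]
  out <- out[order(out$predicate, out$object), , drop = FALSE]
  rownames(out) <- NULL
  if (!nrow(out)) warning(sprintf("no supporting triples for '%s'", ref))
  out
}

#' @export
print.hich_kg <- function(x, ...) {
  cat(sprintf("HICH knowledge graph: %d triples (%s), %d synonyms\n",
              nrow(x$triples),
              paste(sprintf("%s: %d", KG_TIERS, vapply(KG_TIERS, function(t) {
                sum(x$triples$tier == t)
              }, 1L)), collapse = ", "),
              length(x$synonyms)))
  invisible(x)
}
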