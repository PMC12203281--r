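# CoNLL-style corpus persistence: token TAB tag, one per line, blank line
# between documents; document identity and the structured header fields are
# carried in `# key = value` comment lines so the round trip is lossless.

#' Write annotated documents to a CoNLL-style file
#'
#' @param docs List of `annotated_document` objects.
#' @param path Output file path (UTF-8).
#' @return `path`, invisibly.
#' @export
write_conll <- function(docs, path) {
  lines <- character(0)
  for (doc in docs) {
    validate_document(doc)
    hdr <- c(sprintf("# doc_id = %s", doc$doc_id))
    if (!is.null(doc$meta$age)) hdr <- c(hdr, sprintf("# age = %s", doc$meta$age))
    if (!is.null(doc$meta$sex)) hdr <- c(hdr, sprintf("# sex = %s", doc$meta$sex))
    if (!is.null(doc$profile_ref)) {
      hdr <- c(hdr, sprintf("# profile_ref = %s", doc$profile_ref))
    }
    lines <- c(lines, hdr, paste(doc$tokens, doc$tags, sep = "\t"), "")
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read annotated documents from a CoNLL-style file
#'
#' Errors, with the offending line number, on malformed lines (token without
#' a tag) and on BIO violations such as a dangling `I-` tag.
#'
#' @param path Input file path.
#' @param alphabet Tag alphabet used for validation (default [tag_alphabet()]).
#' @return List of `annotated_document` objects.
#' @export
read_conll <- function(path, alphabet = tag_alphabet()) {
  lines <- readLines(path, encoding = "UTF-8")
  docs <- list()
  cur <- list(tokens = character(0), tags = character(0), lines = integer(0),
              doc_id = NULL, meta = list(), profile_ref = NULL)
  flush_doc <- function(cur) {
    if (!length(cur$tokens)) return(NULL)
    doc <- structure(
      list(doc_id = cur$doc_id %||% sprintf("doc-%03d", length(docs) + 1),
           text = detokenize(cur$tokens), tokens = cur$tokens, tags = cur$tags,
           meta = cur$meta, profile_ref = cur$profile_ref),
      class = "annotated_document")
    # re-validate with line context for dangling I- tags
    for (i in seq_along(cur$tags)) {
      tg <- cur$tags[i]
      if (startsWith(tg, "I-")) {
        prev <- if (i == 1) "O" else cur$tags[i - 1]
        type <- substring(tg, 3)
        if (!(prev %in% paste0(c("B-", "I-"), type))) {
          stop_hichds("line %d: dangling %s tag", cur$lines[i], tg,
                      class = "hichds_parse_error")
        }
      }
      if (!(tg %in% alphabet)) {
        stop_hichds("line %d: tag '%s' outside alphabet", cur$lines[i], tg,
                    class = "hichds_parse_error")
      }
    }
    doc
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (line == "") {
      doc <- flush_doc(cur)
      if (!is.null(doc)) docs[[length(docs) + 1]] <- doc
      cur <- list(tokens = character(0), tags = character(0), lines = integer(0),
                  doc_id = NULL, meta = list(), profile_ref = NULL)
    } else if (startsWith(line, "# ")) {
      kv <- regmatches(line, regexec("^# ([a-z_]+) = (.*)$", line))[[1]]
      if (length(kv) == 3) {
        if (kv[2] == "doc_id") cur$doc_id <- kv[3]
        else if (kv[2] == "age") cur$meta$age <- as.integer(kv[3])
        else if (kv[2] == "sex") cur$meta$sex <- kv[3]
        else if (kv[2] == "profile_ref") cur$profile_ref <- kv[3]
      }
    } else {
      parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(parts) != 2 || parts[1] == "" || parts[2] == "") {
        stop_hichds("line %d: expected 'token<TAB>tag', got '%s'", ln, line,
                    class = "hichds_parse_error")
      }
      cur$tokens <- c(cur$tokens, parts[1])
      cur$tags <- c(cur$tags, parts[2])
      cur$lines <- c(cur$lines, ln)
    }
  }
  doc <- flush_doc(cur)
  if (!is.null(doc)) docs[[length(docs) + 1]] <- doc
  docs
}
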