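# Text preprocessing: tokenization, abbreviation expansion, and misspelling
# correction against the lexicon -- the inverse of the synthesizer's corrupter.

#' Tokenize EMR-like text
#'
#' Splits on whitespace and separates punctuation, while keeping numeric
#' compounds (`185/100`, `12.5`) and alphanumeric terms (`SpO2`, `T2-FLAIR`)
#' as single tokens.
#'
#' @param text A character scalar.
#' @return Character vector of tokens.
#' @export
tokenize_text <- function(text) {
  m <- gregexpr("[[:alnum:]]+(?:[./-][[:alnum:]]+)*|[^[:space:]]", text, perl = TRUE)
  regmatches(text, m)[[1]]
}

# pick the edit-distance-1 lexicon entry; ties broken by frequency (desc),
# then lexicographically
spell_correct <- function(token, lexicon) {
  d <- utils::adist(token, names(lexicon))[1, ]
  cand <- which(d == 1)
  if (!length(cand)) return(token)
  words <- names(lexicon)[cand]
  freqs <- lexicon[cand]
  ord <- order(-freqs, words)
  words[ord[1]]
}

#' Preprocess raw note text into clean tokens
#'
#' Tokenizes, expands registered single-token abbreviations, and corrects
#' unknown alphabetic tokens (length >= 4) to their unique edit-distance-1
#' lexicon neighbor when one exists. Unknown tokens with no close neighbor
#' pass through unchanged.
#'
#' @param text Character scalar (raw note text).
#' @param lexicon Named frequency vector, see [emr_lexicon()].
#' @param abbreviations Named character vector mapping abbreviation ->
#'   expansion (default the shipped single-token pairs).
#' @return Character vector of cleaned tokens.
#' @examples
#' preprocess_text("pt with known HTN")
#' @export
preprocess_text <- function(text, lexicon = emr_lexicon(), abbreviations = ABBREV_MAP) {
  tokens <- tokenize_text(text)
  preprocess_tokens(tokens, lexicon, abbreviations)
}

# same pipeline starting from tokens (used on mention spans)
preprocess_tokens <- function(tokens, lexicon = emr_lexicon(), abbreviations = ABBREV_MAP) {
  hit <- tokens %in% names(abbreviations)
  tokens[hit] <- abbreviations[tokens[hit]]
  fix <- grepl("^[A-Za-z]+$", tokens) & nchar(tokens) >= 4 & !(tokens %in% names(lexicon))
  if (any(fix)) {
    tokens[fix] <- vapply(tokens[fix], spell_correct, character(1), lexicon = lexicon)
  }
  tokens
}
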