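# Rendering synthetic profiles into EMR-like annotated text.
#
# Notes are assembled token-by-token from templates and phrase tables, so the
# BIO tags are correct by construction (no span search against rendered text).
# Corruption (misspelling, single-token abbreviation) is applied after
# assembly, strictly one token for one token, so tags never move; every
# injected misspelling is verified to be uniquely recoverable by the
# edit-distance-1 corrector before it is accepted.

ENTITY_TYPES <- c("chief-complaint", "vital-sign", "gcs", "pupil", "airway",
                  "location", "nature", "volume", "midline-shift",
                  "ventricular-compression", "history-item", "suspicion-item")

#' BIO tag alphabet over the configured entity types
#'
#' @param types Character vector of entity types (default the 12 shipped
#'   types covering clinical/CT manifestations and quantitative hematoma
#'   parameters).
#' @return Character vector: `O` plus `B-`/`I-` tags per type.
#' @export
tag_alphabet <- function(types = ENTITY_TYPES) {
  c("O", as.vector(rbind(paste0("B-", types), paste0("I-", types))))
}

#' Entity types of the shipped annotation scheme
#' @return Character vector of the 12 entity types.
#' @export
entity_types <- function() ENTITY_TYPES

# single-token abbreviation pairs: corruption replaces expansion -> key,
# preprocessing replaces key -> expansion (strictly 1:1 so tags stay aligned)
ABBREV_MAP <- c(HTN = "hypertension", hx = "history", pt = "patient",
                sat = "saturation", HA = "headache", HD = "hemodialysis")

# ---- phrase tables ---------------------------------------------------------
# Each variant is a token vector; <placeholders> are filled by the renderer.

PHRASES <- list(
  chief_complaint = list(
    c("sudden", "headache", "and", "vomiting"),
    c("acute", "loss", "of", "consciousness"),
    c("sudden", "weakness", "of", "the", "right", "limbs"),
    c("severe", "headache", "with", "nausea")
  ),
  location = list(
    "basal-ganglia" = list(c("left", "basal", "ganglia"), c("right", "basal", "ganglia"),
                           c("basal", "ganglia", "region")),
    "thalamus" = list(c("left", "thalamus"), c("right", "thalamus"), c("thalamic", "region")),
    "lobar" = list(c("left", "temporal", "lobe"), c("right", "frontal", "lobe"),
                   c("left", "parietal", "lobe"), c("right", "occipital", "lobe")),
    "cerebellar" = list(c("left", "cerebellar", "hemisphere"),
                        c("right", "cerebellar", "hemisphere"), c("cerebellum")),
    "brainstem" = list(c("brainstem"), c("pons"))
  ),
  nature = list(
    c("acute", "hyperdense", "hematoma"),
    c("fresh", "hemorrhage"),
    c("hyperdense", "lesion")
  ),
  pupil = list(
    "bilateral-equal-reactive" = list(c("pupils", "equal", "and", "reactive", "to", "light"),
                                      c("pupils", "equal", "round", "and", "reactive")),
    "unilateral-dilated" = list(c("left", "pupil", "dilated"), c("right", "pupil", "dilated"),
                                c("unilateral", "pupillary", "dilation")),
    "bilateral-dilated-fixed" = list(c("both", "pupils", "dilated", "and", "fixed"),
                                     c("bilateral", "fixed", "dilated", "pupils"))
  ),
  airway = list(
    "patent" = list(c("airway", "patent"), c("airway", "clear")),
    "obstructed" = list(c("airway", "obstructed"), c("airway", "compromised")),
    "arrest" = list(c("respiratory", "arrest"), c("apneic"))
  ),
  history = list(
    "hypertension" = list(c("history", "of", "hypertension"), c("known", "hypertension"),
                          c("longstanding", "hypertension")),
    "anticoagulant-use" = list(c("on", "anticoagulant", "therapy"), c("taking", "warfarin"),
                               c("on", "oral", "anticoagulation")),
    "hemophilia" = list(c("history", "of", "hemophilia"), c("known", "hemophilia")),
    "hemodialysis" = list(c("on", "maintenance", "hemodialysis"), c("chronic", "hemodialysis"))
  ),
  suspicion = list(
    "vascular-lesion" = list(c("suspected", "vascular", "malformation"),
                             c("possible", "aneurysm"),
                             c("suspected", "arteriovenous", "malformation")),
    "tumor" = list(c("possible", "underlying", "tumor"), c("suspected", "neoplasm"))
  ),
  ventcomp = list(
    c("compression", "of", "the", "lateral", "ventricle"),
    c("lateral", "ventricle", "compressed")
  ),
  ivh = list(
    c("intraventricular", "extension"),
    c("blood", "in", "the", "ventricular", "system")
  )
)

seg <- function(tokens, type = NA_character_) {
  list(tokens = as.character(tokens), type = type)
}

pick <- function(variants) variants[[sample.int(length(variants), 1)]]

# ---- slot renderers --------------------------------------------------------
# Each returns a list of segments (entity or literal); sentence punctuation
# and connectives live here so templates stay simple.

slot_renderers <- list(
  demographics = function(p) {
    list(seg(c("The", "patient", "is", "a", p$age, "year", "old", p$sex, ".")))
  },
  chief_complaint = function(p) {
    list(seg(c("presented", "with")), seg(pick(PHRASES$chief_complaint), "chief-complaint"),
         seg("."))
  },
  vitals = function(p) {
    bp <- pick(list(c("BP", sprintf("%d/%d", p$sbp, p$dbp), "mmHg"),
                    c("blood", "pressure", sprintf("%d/%d", p$sbp, p$dbp), "mmHg")))
    sp <- pick(list(c("SpO2", p$spo2, "%"), c("oxygen", "saturation", p$spo2, "%")))
    list(seg(c("On", "arrival")), seg(bp, "vital-sign"), seg(","),
         seg(sp, "vital-sign"), seg("."))
  },
  neuro = function(p) {
    g <- pick(list(c("GCS", p$gcs_total), c("GCS", "score", "of", p$gcs_total),
                   c("Glasgow", "Coma", "Score", p$gcs_total)))
    list(seg(c("Neurological", "examination", ":")), seg(g, "gcs"), seg(","),
         seg(pick(PHRASES$pupil[[p$pupils]]), "pupil"), seg(","),
         seg(pick(PHRASES$airway[[p$airway]]), "airway"), seg("."))
  },
  history = function(p) {
    if (length(p$history) == 0) {
      return(list(seg(c("No", "significant", "past", "medical", "history", "."))))
    }
    out <- list(seg(c("Past", "history", ":")))
    for (i in seq_along(p$history)) {
      if (i > 1) out <- c(out, list(seg(if (i == length(p$history)) "and" else ",")))
      out <- c(out, list(seg(pick(PHRASES$history[[p$history[i]]]), "history-item")))
    }
    c(out, list(seg(".")))
  },
  ct = function(p) {
    vol <- pick(list(c(p$hematoma_volume, "mL"),
                     c("about", p$hematoma_volume, "mL"),
                     c("approximately", p$hematoma_volume, "mL")))
    list(seg(c("Head", "CT", "shows", "a")), seg(pick(PHRASES$nature), "nature"),
         seg(c("in", "the")), seg(pick(PHRASES$location[[p$hematoma_location]]), "location"),
         seg(c(",", "estimated", "volume")), seg(vol, "volume"), seg("."))
  },
  midline = function(p) {
    m <- if (p$midline_shift == 0) {
      pick(list(c("no", "midline", "shift"), c("without", "midline", "shift")))
    } else {
      pick(list(c("midline", "shift", "of", p$midline_shift, "mm"),
                c(p$midline_shift, "mm", "midline", "shift")))
    }
    list(seg(c("There", "is")), seg(m, "midline-shift"), seg("."))
  },
  ventricles = function(p) {
    segs <- list()
    if (isTRUE(p$ventricular_compression)) {
      segs <- c(segs, list(seg(pick(PHRASES$ventcomp), "ventricular-compression")))
    }
    if (isTRUE(p$intraventricular_extension)) {
      if (length(segs)) segs <- c(segs, list(seg("with")))
      segs <- c(segs, list(seg(pick(PHRASES$ivh), "ventricular-compression")))
    }
    if (!length(segs)) {
      return(list(seg(c("The", "ventricular", "system", "appears", "normal", "."))))
    }
    c(list(seg(c("CT", "also", "demonstrates"))), segs, list(seg(".")))
  },
  suspicion = function(p) {
    if (length(p$suspicion) == 0) return(list())
    out <- list(seg(c("Impression", ":")))
    for (i in seq_along(p$suspicion)) {
      if (i > 1) out <- c(out, list(seg("and")))
      out <- c(out, list(seg(pick(PHRASES$suspicion[[p$suspicion[i]]]), "suspicion-item")))
    }
    c(out, list(seg(".")))
  }
)

#' The shipped note template bank
#'
#' Three English note skeletons differing in section order and framing. A
#' template is a character vector of slot names resolved by the internal slot
#' renderers; every slot verbalizes one or more profile fields as tagged
#' entity spans.
#'
#' @return List of templates (character vectors of slot names).
#' @export
emr_templates <- function() {
  list(
    c("demographics", "chief_complaint", "vitals", "neuro", "history",
      "ct", "midline", "ventricles", "suspicion"),
    c("demographics", "chief_complaint", "history", "vitals", "neuro",
      "ct", "ventricles", "midline", "suspicion"),
    c("demographics", "history", "chief_complaint", "neuro", "vitals",
      "ct", "midline", "ventricles", "suspicion")
  )
}

#' Corruption configuration for the synthesizer
#'
#' The corrupter injects exactly what the preprocessor is specified to undo:
#' per-token misspellings (single character edit, only accepted when the
#' edit-distance-1 corrector uniquely recovers the original) and registered
#' single-token abbreviations.
#'
#' @param misspell_rate,abbreviation_rate Per-token probabilities in \[0, 1\].
#' @param seed Integer seed driving phrasing choice and corruption.
#' @return An object of class `corruption_config`.
#' @export
corruption_config <- function(misspell_rate = 0, abbreviation_rate = 0, seed = 1) {
  if (misspell_rate < 0 || misspell_rate > 1 || abbreviation_rate < 0 || abbreviation_rate > 1) {
    stop_hichds("corruption rates must be in [0, 1]", class = "hichds_config_error")
  }
  structure(list(misspell_rate = misspell_rate, abbreviation_rate = abbreviation_rate,
                 seed = as.integer(seed)), class = "corruption_config")
}

# vocabulary of the template bank with frequencies; the corrector's lexicon
lexicon_cache <- new.env(parent = emptyenv())

#' The synthesizer lexicon
#'
#' All alphabetic surface tokens the template bank can produce, with their
#' frequency across the phrase tables; used by [preprocess_text()] for
#' edit-distance-1 misspelling correction.
#'
#' @return Named integer vector (token -> frequency).
#' @export
emr_lexicon <- function() {
  if (!is.null(lexicon_cache$lex)) return(lexicon_cache$lex)
  toks <- character(0)
  harvest <- function(x) {
    if (is.list(x)) lapply(x, harvest) else toks <<- c(toks, as.character(x))
  }
  harvest(PHRASES)
  toks <- c(toks,
            "The", "patient", "is", "a", "year", "old", "male", "female",
            "presented", "with", "On", "arrival", "BP", "blood", "pressure",
            "mmHg", "SpO2", "oxygen", "saturation", "Neurological", "examination",
            "GCS", "score", "of", "Glasgow", "Coma", "Score", "No", "significant",
            "past", "medical", "history", "Past", "and", "Head", "CT", "shows",
            "in", "the", "estimated", "volume", "mL", "about", "approximately",
            "There", "midline", "shift", "mm", "no", "without", "also",
            "demonstrates", "ventricular", "system", "appears", "normal",
            "Impression", "compression")
  toks <- toks[grepl("^[A-Za-z]+$", toks)]
  lex <- sort(table(toks), decreasing = TRUE)
  out <- as.integer(lex)
  names(out) <- names(lex)
  lexicon_cache$lex <- out
  out
}

# one random character edit (substitution, deletion or insertion)
random_edit <- function(token) {
  chars <- strsplit(token, "")[[1]]
  op <- sample(c("sub", "del", "ins"), 1)
  pos <- sample.int(length(chars), 1)
  letter <- sample(letters, 1)
  if (op == "sub") {
    if (chars[pos] == letter) return(NULL)
    chars[pos] <- letter
  } else if (op == "del") {
    chars <- chars[-pos]
  } else {
    chars <- append(chars, letter, after = pos)
  }
  paste(chars, collapse = "")
}

# accept a misspelling only if the full preprocessing path maps it straight
# back (same gates the corrector applies at read time)
corrupt_token <- function(token, lexicon) {
  for (attempt in 1:8) {
    cand <- random_edit(token)
    if (is.null(cand) || cand %in% names(lexicon) || cand %in% names(ABBREV_MAP)) next
    if (identical(preprocess_tokens(cand, lexicon), token)) return(cand)
  }
  token
}

apply_corruption <- function(tokens, corruption, lexicon = emr_lexicon()) {
  inv_abbrev <- names(ABBREV_MAP)
  names(inv_abbrev) <- ABBREV_MAP  # expansion -> abbreviation key
  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    if (tok %in% names(inv_abbrev) && stats::runif(1) < corruption$abbreviation_rate) {
      tokens[i] <- inv_abbrev[[tok]]
      next
    }
    eligible <- grepl("^[A-Za-z]+$", tok) && nchar(tok) >= 4 &&
      tok %in% names(lexicon) && !(tok %in% ABBREV_MAP)
    if (eligible && stats::runif(1) < corruption$misspell_rate) {
      tokens[i] <- corrupt_token(tok, lexicon)
    }
  }
  tokens
}

# join tokens into display text; closing punctuation attaches to the left
detokenize <- function(tokens) {
  out <- tokens[1]
  if (length(tokens) > 1) {
    for (tok in tokens[-1]) {
      sep <- if (tok %in% c(".", ",", ";", ":", "?", "%")) "" else " "
      out <- paste0(out, sep, tok)
    }
  }
  out
}

#' Render a profile into an annotated EMR-like note
#'
#' Chooses a template and phrasings deterministically from the corruption
#' seed, assembles tokens and BIO tags jointly, then applies token-for-token
#' corruption. Corruption can change surface forms but never tag boundaries.
#'
#' @param profile A `patient_profile`.
#' @param template_bank Template list as from [emr_templates()].
#' @param corruption A [corruption_config()].
#' @param doc_id Document identifier (default derived from the seed).
#' @return An `annotated_document`: `doc_id`, `text`, `tokens`, `tags`,
#'   structured `meta` (age/sex, as an EMR header would carry), `profile_ref`.
#' @examples
#' doc <- render_emr(sample_profile(seed = 7), corruption = corruption_config(seed = 7))
#' head(cbind(doc$tokens, doc$tags))
#' @export
render_emr <- function(profile, template_bank = emr_templates(),
                       corruption = corruption_config(), doc_id = NULL) {
  validate_profile(profile)
  if (length(template_bank) == 0) {
    stop_hichds("template bank is empty", class = "hichds_template_error")
  }
  with_rng_seed(corruption$seed, {
    template <- template_bank[[sample.int(length(template_bank), 1)]]
    unknown <- setdiff(template, names(slot_renderers))
    if (length(unknown)) {
      stop_hichds("template references unknown slot(s): %s",
                  paste(unknown, collapse = ", "), class = "hichds_template_error")
    }
    tokens <- character(0)
    tags <- character(0)
    for (slot in template) {
      for (s in slot_renderers[[slot]](profile)) {
        n <- length(s$tokens)
        tokens <- c(tokens, s$tokens)
        tags <- c(tags, if (is.na(s$type)) rep("O", n) else
          c(paste0("B-", s$type), rep(paste0("I-", s$type), n - 1)))
      }
    }
    tokens <- apply_corruption(tokens, corruption)
    doc <- structure(
      list(doc_id = doc_id %||% sprintf("doc-%d", corruption$seed),
           text = detokenize(tokens), tokens = tokens, tags = tags,
           meta = list(age = profile$age, sex = profile$sex),
           profile_ref = attr(profile, "profile_id")),
      class = "annotated_document")
    validate_document(doc)
    doc
  })
}

#' Validate an annotated document's BIO structure
#'
#' Checks token/tag alignment, membership in the tag alphabet, and that every
#' `I-` tag continues a span of the same type.
#'
#' @param doc An `annotated_document`.
#' @param alphabet Tag alphabet (default [tag_alphabet()]).
#' @return The document, invisibly; errors on violation.
#' @export
validate_document <- function(doc, alphabet = tag_alphabet()) {
  if (length(doc$tokens) != length(doc$tags)) {
    stop_hichds("document %s: %d tokens but %d tags", doc$doc_id,
                length(doc$tokens), length(doc$tags), class = "hichds_parse_error")
  }
  bad <- setdiff(doc$tags, alphabet)
  if (length(bad)) {
    stop_hichds("document %s: tags outside alphabet: %s", doc$doc_id,
                paste(unique(bad), collapse = ", "), class = "hichds_parse_error")
  }
  for (i in seq_along(doc$tags)) {
    tg <- doc$tags[i]
    if (startsWith(tg, "I-")) {
      prev <- if (i == 1) "O" else doc$tags[i - 1]
      type <- substring(tg, 3)
      if (!(prev %in% paste0(c("B-", "I-"), type))) {
        stop_hichds("document %s: dangling %s at position %d", doc$doc_id, tg, i,
                    class = "hichds_parse_error")
      }
    }
  }
  invisible(doc)
}
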