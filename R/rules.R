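# The weighted decision engine: normalize extracted mentions into a
# knowledge-graph-aligned patient state, fire weighted guideline rules, and
# emit a four-branch treatment plan where every selected item carries a
# machine-readable basis (fired rule, filled explanation text, supporting
# knowledge-graph triples).
#
# The shipped default ruleset R0 (inst/extdata/ruleset_r0.yaml) is a
# reconstruction from the cited guideline tradition (supratentorial volume
# >= 30 mL, cerebellar >= 10 mL or ventricular compression, midline shift
# >= 5 mm, GCS <= 8 for airway protection, SBP >= 150 for antihypertensives);
# it is data, not code, and every threshold is editable.

#' The treatment-plan item taxonomy
#'
#' @return Named list of the four branches and their items.
#' @export
plan_items <- function() {
  list(
    diagnostic = c("repeat-head-CT", "CTA", "MRA", "DSA", "multimodal-MRI",
                   "coagulation-panel"),
    surgical = "surgery",
    rescue = c("vital-sign-monitoring", "venous-access", "CPR",
               "airway-clearance", "tracheal-intubation", "ventilator"),
    drugs = c("antihypertensive", "ICP-lowering", "anti-GI-bleeding")
  )
}

STATE_FIELDS <- list(
  numeric = c("age", "gcs_total", "sbp", "dbp", "spo2", "hematoma_volume",
              "midline_shift"),
  category = c("sex", "pupils", "airway", "hematoma_location"),
  flag = c("ventricular_compression", "intraventricular_extension"),
  flagset = c("history", "suspicion")
)

NUMERIC_RANGES <- list(age = c(10, 80), gcs_total = c(3, 15), sbp = c(0, 400),
                       dbp = c(0, 300), spo2 = c(0, 100),
                       hematoma_volume = c(0, Inf), midline_shift = c(0, Inf))

state_field_names <- function() unlist(STATE_FIELDS, use.names = FALSE)

new_state_field <- function(value = NULL, source = NA_character_,
                            entity = NA_character_, confidence = "missing") {
  list(value = value, source = source, entity = entity, confidence = confidence)
}

#' An all-missing patient state
#' @return Object of class `patient_state` with every field missing.
#' @export
patient_state <- function() {
  fields <- lapply(state_field_names(), function(f) new_state_field())
  names(fields) <- state_field_names()
  structure(list(fields = fields, conflicts = list()), class = "patient_state")
}

st_value <- function(state, field) {
  f <- state$fields[[field]]
  if (is.null(f) || f$confidence == "missing") NULL else f$value
}

set_state_field <- function(state, field, value, source, entity,
                            confidence = "explicit") {
  prev <- state$fields[[field]]
  if (!is.null(prev) && prev$confidence == "explicit" && confidence == "explicit" &&
      !identical(prev$value, value)) {
    # duplicate-mention conflict: the later mention wins, logged
    state$conflicts[[length(state$conflicts) + 1]] <-
      list(field = field, kept = value, dropped = prev$value, source = source)
  }
  state$fields[[field]] <- new_state_field(value, source, entity, confidence)
  state
}

canonical_entity <- list(
  hematoma_location = function(v) paste0("loc-", v),
  pupils = function(v) c("bilateral-equal-reactive" = "pupil-equal",
                         "unilateral-dilated" = "pupil-unilateral-dilated",
                         "bilateral-dilated-fixed" = "pupil-fixed-dilated")[[v]],
  airway = function(v) paste0("airway-", v),
  age = function(v) "obs-age", sex = function(v) "obs-sex",
  gcs_total = function(v) "obs-gcs", sbp = function(v) "obs-bp",
  dbp = function(v) "obs-bp", spo2 = function(v) "obs-spo2",
  hematoma_volume = function(v) "obs-volume",
  midline_shift = function(v) "obs-midline-shift",
  ventricular_compression = function(v) "vent-compression",
  intraventricular_extension = function(v) "vent-ivh",
  history = function(v) paste0("hx-", v),
  suspicion = function(v) paste0("susp-", v)
)

#' Convert a ground-truth profile to a fully explicit patient state
#'
#' Used to derive gold treatment plans and as the oracle comparison point for
#' the extraction pipeline.
#'
#' @param profile A `patient_profile`.
#' @return A `patient_state` with every field explicit.
#' @export
profile_to_state <- function(profile) {
  state <- patient_state()
  for (f in state_field_names()) {
    v <- profile[[f]]
    ent <- NA_character_
    if (f %in% STATE_FIELDS$flagset) {
      ent <- if (length(v)) paste(canonical_entity[[f]](v), collapse = ",") else ""
    } else if (f %in% names(canonical_entity)) {
      ent <- canonical_entity[[f]](v)
    }
    state <- set_state_field(state, f, v, "structured input", ent, "explicit")
  }
  state
}

first_number <- function(tokens) {
  hit <- grep("^[0-9]+(\\.[0-9]+)?$", tokens, value = TRUE)
  if (length(hit)) as.numeric(hit[1]) else NA_real_
}

#' Normalize extracted entity mentions into a patient state
#'
#' Mentions are processed in document order; each is cleaned with the
#' preprocessor (undoing corrupted surface forms), aligned to a canonical
#' knowledge-graph entity, and parsed for numeric values with units (mL, mm,
#' mmHg, %). Conflicting duplicate values are resolved in favor of the later
#' mention (CT reports supersede triage notes) and logged on the state.
#' Flag-type fields with no mention are closed-world `FALSE`/empty with
#' confidence `"inferred"` when the document yielded any mention at all; an
#' empty mention list yields an all-missing state. Unparseable numerics are
#' recorded as missing with a warning, never an error.
#'
#' @param mentions Data frame with columns `start`, `end`, `type`, `text`
#'   (as from [extract_entities()]).
#' @param graph A `hich_kg`.
#' @param structured Optional named list of structured header fields
#'   (`age`, `sex`).
#' @param threshold Alignment similarity threshold (see [align_entity()]).
#' @return A `patient_state`.
#' @export
normalize_entities <- function(mentions, graph = hich_kg(), structured = NULL,
                               threshold = 0.8) {
  state <- patient_state()
  if (!is.null(structured)) {
    if (!is.null(structured$age)) {
      state <- set_state_field(state, "age", as.numeric(structured$age),
                               "structured input", "obs-age")
    }
    if (!is.null(structured$sex)) {
      state <- set_state_field(state, "sex", structured$sex, "structured input", "obs-sex")
    }
  }
  any_mention <- !is.null(mentions) && nrow(mentions) > 0
  hist_flags <- character(0); susp_flags <- character(0)
  saw <- list(history = FALSE, suspicion = FALSE, vent = FALSE)
  if (any_mention) {
    mentions <- mentions[order(mentions$start), , drop = FALSE]
    for (i in seq_len(nrow(mentions))) {
      mtype <- mentions$type[i]
      raw <- strsplit(mentions$text[i], " ", fixed = TRUE)[[1]]
      toks <- preprocess_tokens(raw)
      text <- paste(toks, collapse = " ")
      low <- tolower(toks)
      set_num <- function(state, field, value, entity) {
        if (is.na(value)) {
          warning(sprintf("unparseable %s mention '%s'; field left missing", mtype, text))
          return(state)
        }
        rng <- NUMERIC_RANGES[[field]]
        if (value < rng[1] || value > rng[2]) {
          warning(sprintf("%s value %s outside plausible range; field left missing",
                          field, value))
          return(state)
        }
        set_state_field(state, field, value, text, entity)
      }
      if (mtype == "gcs") {
        state <- set_num(state, "gcs_total", first_number(toks), "obs-gcs")
      } else if (mtype == "vital-sign") {
        bp <- grep("^[0-9]+/[0-9]+$", toks, value = TRUE)
        if (length(bp)) {
          parts <- as.numeric(strsplit(bp[1], "/", fixed = TRUE)[[1]])
          state <- set_num(state, "sbp", parts[1], "obs-bp")
          state <- set_num(state, "dbp", parts[2], "obs-bp")
        } else {
          state <- set_num(state, "spo2", first_number(toks), "obs-spo2")
        }
      } else if (mtype == "volume") {
        state <- set_num(state, "hematoma_volume", first_number(toks), "obs-volume")
      } else if (mtype == "midline-shift") {
        v <- if (any(low %in% c("no", "without"))) 0 else first_number(toks)
        state <- set_num(state, "midline_shift", v, "obs-midline-shift")
      } else if (mtype == "location") {
        ent <- align_entity(text, "location", graph, threshold = threshold)
        if (!is.na(ent)) {
          state <- set_state_field(state, "hematoma_location", sub("^loc-", "", ent),
                                   text, ent)
        } else warning(sprintf("unresolvable location mention '%s'", text))
      } else if (mtype == "pupil") {
        ent <- align_entity(text, "pupil", graph, threshold = threshold)
        val <- c("pupil-equal" = "bilateral-equal-reactive",
                 "pupil-unilateral-dilated" = "unilateral-dilated",
                 "pupil-fixed-dilated" = "bilateral-dilated-fixed")[ent]
        if (!is.na(ent) && !is.na(val)) {
          state <- set_state_field(state, "pupils", unname(val), text, ent)
        }
      } else if (mtype == "airway") {
        ent <- align_entity(text, "airway", graph, threshold = threshold)
        if (!is.na(ent)) {
          state <- set_state_field(state, "airway", sub("^airway-", "", ent), text, ent)
        }
      } else if (mtype == "ventricular-compression") {
        ent <- align_entity(text, "ventricular-finding", graph, threshold = threshold)
        saw$vent <- TRUE
        if (identical(ent, "vent-compression")) {
          state <- set_state_field(state, "ventricular_compression", TRUE, text, ent)
        } else if (identical(ent, "vent-ivh")) {
          state <- set_state_field(state, "intraventricular_extension", TRUE, text, ent)
        }
      } else if (mtype == "history-item") {
        ent <- align_entity(text, "history", graph, threshold = threshold)
        saw$history <- TRUE
        if (!is.na(ent)) hist_flags <- union(hist_flags, sub("^hx-", "", ent))
      } else if (mtype == "suspicion-item") {
        ent <- align_entity(text, "suspicion", graph, threshold = threshold)
        saw$suspicion <- TRUE
        if (!is.na(ent)) susp_flags <- union(susp_flags, sub("^susp-", "", ent))
      }
      # chief-complaint and nature mentions carry no decision-relevant state
    }
    # closed-world completion of flag-type fields
    conf_h <- if (saw$history || length(hist_flags)) "explicit" else "inferred"
    state$fields$history <- new_state_field(
      intersect(PROFILE_HISTORY, hist_flags), "document",
      paste(paste0("hx-", hist_flags), collapse = ","), conf_h)
    conf_s <- if (saw$suspicion || length(susp_flags)) "explicit" else "inferred"
    state$fields$suspicion <- new_state_field(
      intersect(PROFILE_SUSPICION, susp_flags), "document",
      paste(paste0("susp-", susp_flags), collapse = ","), conf_s)
    if (state$fields$ventricular_compression$confidence == "missing") {
      state$fields$ventricular_compression <- new_state_field(FALSE, "document",
                                                              "vent-compression", "inferred")
    }
    if (state$fields$intraventricular_extension$confidence == "missing") {
      state$fields$intraventricular_extension <- new_state_field(FALSE, "document",
                                                                 "vent-ivh", "inferred")
    }
  }
  state
}

#' @export
print.patient_state <- function(x, ...) {
  cat("Patient state:\n")
  for (f in state_field_names()) {
    fd <- x$fields[[f]]
    val <- if (fd$confidence == "missing") "<missing>" else
      paste(format(fd$value), collapse = ", ")
    cat(sprintf("  %-26s %s (%s)\n", f, val, fd$confidence))
  }
  if (length(x$conflicts)) cat(sprintf("  [%d resolved conflict(s)]\n", length(x$conflicts)))
  invisible(x)
}

# ---- ruleset ---------------------------------------------------------------

RULE_OPS <- c(">=", "<=", ">", "<", "==", "in", "is-true", "is-false",
              "missing", "not-missing", "flag-has", "flag-not-has")

#' Read a weighted ruleset from a YAML file
#'
#' Validates at load time that every antecedent references a declared patient
#' state field with a known operator, that weights are non-negative, and
#' that every consequent is a plan item of the taxonomy.
#'
#' @param path YAML file path.
#' @return Object of class `hich_ruleset`: `rules` (list), `activation`
#'   (named item thresholds, default 1 point).
#' @export
read_ruleset <- function(path) {
  spec <- yaml::read_yaml(path)
  items <- unlist(plan_items(), use.names = FALSE)
  activation <- rep(1, length(items))
  names(activation) <- items
  for (nm in names(spec$activation %||% list())) {
    if (!nm %in% items) {
      stop_hichds("activation threshold for unknown item '%s'", nm,
                  class = "hichds_ruleset_error")
    }
    activation[nm] <- spec$activation[[nm]]
  }
  fields <- state_field_names()
  rules <- lapply(spec$rules, function(r) {
    if (is.null(r$id) || is.null(r$adds)) {
      stop_hichds("every rule needs an id and consequents", class = "hichds_ruleset_error")
    }
    for (cond in r$when %||% list()) {
      if (!cond$field %in% fields) {
        stop_hichds("rule %s references unknown field '%s'", r$id, cond$field,
                    class = "hichds_ruleset_error")
      }
      if (!cond$op %in% RULE_OPS) {
        stop_hichds("rule %s uses unknown operator '%s'", r$id, cond$op,
                    class = "hichds_ruleset_error")
      }
    }
    bad <- setdiff(unlist(r$adds), items)
    if (length(bad)) {
      stop_hichds("rule %s asserts unknown plan item(s): %s", r$id,
                  paste(bad, collapse = ", "), class = "hichds_ruleset_error")
    }
    if ((r$weight %||% 1) < 0) {
      stop_hichds("rule %s has negative weight", r$id, class = "hichds_ruleset_error")
    }
    list(id = r$id, when = r$when %||% list(), weight = r$weight %||% 1,
         adds = unlist(r$adds), tier = r$tier %||% "subdomain",
         source = r$source %||% "", kg_ref = r$kg_ref %||% NA_character_,
         basis = r$basis %||% r$id)
  })
  ids <- vapply(rules, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop_hichds("duplicate rule id(s): %s", paste(unique(ids[duplicated(ids)]), collapse = ", "),
                class = "hichds_ruleset_error")
  }
  structure(list(rules = rules, activation = activation), class = "hich_ruleset")
}

ruleset_cache <- new.env(parent = emptyenv())

#' The shipped default ruleset R0
#'
#' A reconstruction of the guideline-tradition thresholds (see the package
#' vignette); shipped as data in `inst/extdata/ruleset_r0.yaml`.
#'
#' @return A `hich_ruleset`.
#' @export
default_ruleset <- function() {
  if (is.null(ruleset_cache$r0)) {
    ruleset_cache$r0 <- read_ruleset(system.file("extdata", "ruleset_r0.yaml",
                                                 package = "hichds", mustWork = TRUE))
  }
  ruleset_cache$r0
}

eval_condition <- function(cond, state) {
  v <- st_value(state, cond$field)
  known <- !is.null(v)
  switch(cond$op,
    "missing" = !known,
    "not-missing" = known,
    ">=" = known && v >= cond$value,
    "<=" = known && v <= cond$value,
    ">" = known && v > cond$value,
    "<" = known && v < cond$value,
    "==" = known && identical(as.character(v), as.character(cond$value)),
    "in" = known && as.character(v) %in% unlist(cond$value),
    "is-true" = known && isTRUE(v),
    "is-false" = known && identical(v, FALSE),
    "flag-has" = known && cond$value %in% v,
    "flag-not-has" = !known || !(cond$value %in% v)
  )
}

rule_fires <- function(rule, state) {
  for (cond in rule$when) if (!eval_condition(cond, state)) return(FALSE)
  TRUE
}

fill_basis <- function(template, state) {
  slots <- regmatches(template, gregexpr("\\{[a-z_]+\\}", template))[[1]]
  for (s in slots) {
    field <- substring(s, 2, nchar(s) - 1)
    v <- st_value(state, field)
    rep_str <- if (is.null(v)) "undocumented" else paste(format(v), collapse = ", ")
    template <- sub(s, rep_str, template, fixed = TRUE)
  }
  template
}

# ---- plan construction -----------------------------------------------------

#' Apply the weighted ruleset to a patient state
#'
#' Evaluates every rule on the state; a plan item is selected iff the summed
#' weight of rules asserting it reaches the item's activation threshold
#' (default 1 point). Every selected item carries its bases: the fired rules
#' with filled explanation texts, source citations, and supporting
#' knowledge-graph triples. Plan invariants (tracheal intubation implies
#' airway clearance, CPR implies vital-sign monitoring) are enforced by
#' [resolve_conflicts()]. Deterministic: identical state and ruleset always
#' give the identical plan.
#'
#' @param state A `patient_state`.
#' @param ruleset A `hich_ruleset` (default R0).
#' @param graph A `hich_kg` for basis traces (default the seed graph).
#' @return An object of class `treatment_plan` with branches `diagnostic`,
#'   `surgical` (flag), `rescue`, `drugs`, the `bases` of selected items,
#'   per-item summed weights (`item_scores`), and a `rule_log`.
#' @examples
#' \dontrun{
#' plan <- decide_plan(profile_to_state(sample_profile(seed = 7)))
#' print(plan)
#' }
#' @export
decide_plan <- function(state, ruleset = default_ruleset(), graph = hich_kg()) {
  items <- plan_items()
  all_items <- unlist(items, use.names = FALSE)
  scores <- rep(0, length(all_items))
  names(scores) <- all_items
  fired_bases <- stats::setNames(vector("list", length(all_items)), all_items)
  rule_log <- data.frame(rule_id = character(0), fired = logical(0),
                         weight = numeric(0), stringsAsFactors = FALSE)
  rule_items <- list()
  for (rule in ruleset$rules) {
    fired <- rule_fires(rule, state)
    rule_log <- rbind(rule_log, data.frame(rule_id = rule$id, fired = fired,
                                           weight = rule$weight, stringsAsFactors = FALSE))
    rule_items[[rule$id]] <- rule$adds
    if (!fired) next
    trace <- if (!is.na(rule$kg_ref)) {
      tryCatch(suppressWarnings(basis_trace(graph, rule$kg_ref)),
               error = function(e) NULL)
    } else NULL
    for (item in rule$adds) {
      scores[item] <- scores[item] + rule$weight
      fired_bases[[item]] <- c(fired_bases[[item]], list(list(
        rule_id = rule$id, weight = rule$weight,
        text = fill_basis(rule$basis, state), source = rule$source,
        kg_trace = trace)))
    }
  }
  selected <- names(scores)[scores >= ruleset$activation[names(scores)]]
  plan <- structure(list(
    diagnostic = intersect(items$diagnostic, selected),
    surgical = "surgery" %in% selected,
    rescue = intersect(items$rescue, selected),
    drugs = intersect(items$drugs, selected),
    bases = fired_bases[intersect(all_items, selected)],
    fired_bases = fired_bases[vapply(fired_bases, length, 1L) > 0],
    item_scores = scores,
    rule_log = rule_log,
    rule_items = rule_items
  ), class = "treatment_plan")
  resolve_conflicts(plan)
}

#' Enforce treatment-plan coherence invariants
#'
#' Applies the implication closure (tracheal intubation requires a cleared
#' airway; CPR requires vital-sign monitoring), attaching an implication
#' basis to any added item. Idempotent.
#'
#' @param plan A `treatment_plan`.
#' @return The closed plan.
#' @export
resolve_conflicts <- function(plan) {
  implications <- list(
    c("tracheal-intubation", "airway-clearance",
      "Airway clearance must precede tracheal intubation"),
    c("CPR", "vital-sign-monitoring",
      "Cardiopulmonary resuscitation entails continuous vital-sign monitoring")
  )
  for (imp in implications) {
    if (imp[1] %in% plan$rescue && !(imp[2] %in% plan$rescue)) {
      plan$rescue <- intersect(plan_items()$rescue, c(plan$rescue, imp[2]))
      plan$bases[[imp[2]]] <- c(plan$bases[[imp[2]]], list(list(
        rule_id = "plan-invariant", weight = 0, text = imp[3],
        source = "plan coherence invariant", kg_trace = NULL)))
    }
  }
  plan
}

#' Branch views of the decision engine
#'
#' Convenience wrappers over [decide_plan()] restricted to one branch; the
#' returned bases include every fired rule for the branch, so a negative
#' surgical indication still cites the rule that kept it off (for example the
#' conservative brainstem default).
#'
#' @inheritParams decide_plan
#' @return `surgical_indication`: list `indicated` (flag) and `bases`;
#'   `rescue_triggers`/`diagnostic_triggers`: list `items` and `bases`.
#' @export
surgical_indication <- function(state, ruleset = default_ruleset(), graph = hich_kg()) {
  plan <- decide_plan(state, ruleset, graph)
  list(indicated = plan$surgical, bases = plan$fired_bases[["surgery"]] %||% list())
}

#' @rdname surgical_indication
#' @export
rescue_triggers <- function(state, ruleset = default_ruleset(), graph = hich_kg()) {
  plan <- decide_plan(state, ruleset, graph)
  list(items = plan$rescue,
       bases = plan$bases[intersect(names(plan$bases), plan$rescue)])
}

#' @rdname surgical_indication
#' @export
diagnostic_triggers <- function(state, ruleset = default_ruleset(), graph = hich_kg()) {
  plan <- decide_plan(state, ruleset, graph)
  list(items = plan$diagnostic,
       bases = plan$bases[intersect(names(plan$bases), plan$diagnostic)])
}

#' @export
print.treatment_plan <- function(x, ...) {
  cat("Treatment plan\n")
  cat(sprintf("  Diagnostic: %s\n", if (length(x$diagnostic)) paste(x$diagnostic, collapse = ", ") else "(none)"))
  cat(sprintf("  Surgical:   %s\n", if (x$surgical) "surgery indicated" else "not indicated"))
  cat(sprintf("  Rescue:     %s\n", if (length(x$rescue)) paste(x$rescue, collapse = ", ") else "(none)"))
  cat(sprintf("  Drugs:      %s\n", if (length(x$drugs)) paste(x$drugs, collapse = ", ") else "(none)"))
  invisible(x)
}

plan_signature <- function(plan) {
  list(diagnostic = plan$diagnostic, surgical = plan$surgical,
       rescue = plan$rescue, drugs = plan$drugs)
}

#' Structured explanation report for a plan
#'
#' Lists every selected item with its filled basis texts and source
#' citations; branches with nothing selected render as explicit
#' "not indicated" sections showing the strongest rule that did not fire.
#' The JSON-serializable structure and the Markdown rendering
#' ([explain_markdown()]) agree item for item.
#'
#' @param plan A `treatment_plan` from [decide_plan()].
#' @return A nested list report (class `plan_explanation`).
#' @export
explain <- function(plan) {
  items <- plan_items()
  report <- list()
  branch_items <- list(diagnostic = plan$diagnostic,
                       surgical = if (plan$surgical) "surgery" else character(0),
                       rescue = plan$rescue, drugs = plan$drugs)
  not_fired <- plan$rule_log[!plan$rule_log$fired, , drop = FALSE]
  for (br in names(items)) {
    sel <- branch_items[[br]]
    if (length(sel)) {
      report[[br]] <- list(status = "indicated", items = lapply(sel, function(it) {
        list(item = it, bases = lapply(plan$bases[[it]], function(b) {
          list(rule_id = b$rule_id, text = b$text, source = b$source,
               citations = if (!is.null(b$kg_trace) && nrow(b$kg_trace)) {
                 unique(b$kg_trace$source[b$kg_trace$source != ""])
               } else character(0))
        }))
      }))
    } else {
      cand <- not_fired[vapply(not_fired$rule_id, function(id) {
        any(plan$rule_items[[id]] %in% items[[br]])
      }, logical(1)), , drop = FALSE]
      strongest <- if (nrow(cand)) {
        cand$rule_id[order(-cand$weight, cand$rule_id)][1]
      } else NA_character_
      report[[br]] <- list(status = "not indicated", items = list(),
                           strongest_non_fired_rule = strongest)
    }
  }
  structure(report, class = "plan_explanation")
}

#' Render an explanation report as Markdown
#'
#' @param report A `plan_explanation` from [explain()].
#' @return Character vector of Markdown lines.
#' @export
explain_markdown <- function(report) {
  lines <- "# Treatment plan explanation"
  for (br in names(report)) {
    sec <- report[[br]]
    lines <- c(lines, sprintf("## %s (%s)", br, sec$status))
    for (it in sec$items) {
      lines <- c(lines, sprintf("- **%s**", it$item))
      for (b in it$bases) {
        src <- if (nchar(b$source)) sprintf(" [%s]", b$source) else ""
        lines <- c(lines, sprintf("  - %s (rule `%s`)%s", b$text, b$rule_id, src))
      }
    }
    if (identical(sec$status, "not indicated") && !is.na(sec$strongest_non_fired_rule)) {
      lines <- c(lines, sprintf("  - strongest rule not fired: `%s`",
                                sec$strongest_non_fired_rule))
    }
  }
  lines
}

#' Write / read a treatment plan as canonical JSON
#'
#' Serialization is deterministic (fixed key order, no environment-dependent
#' formatting), so identical plans are byte-identical on disk.
#'
#' @param plan A `treatment_plan`.
#' @param path File path.
#' @return `path` (write) or a plain plan list (read).
#' @export
write_plan <- function(plan, path) {
  payload <- list(
    diagnostic = as.list(plan$diagnostic),
    surgical = plan$surgical,
    rescue = as.list(plan$rescue),
    drugs = as.list(plan$drugs),
    item_scores = as.list(plan$item_scores),
    bases = lapply(plan$bases, function(bl) lapply(bl, function(b) {
      list(rule_id = b$rule_id, weight = b$weight, text = b$text, source = b$source)
    }))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
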