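# Hand-traced firings of the default ruleset R0. States are built from the
# structured profile path so each scenario is explicit.

state_from <- function(...) {
  base <- list(age = 65, sex = "male", gcs_total = 14, sbp = 170, dbp = 95,
               spo2 = 97, pupils = "bilateral-equal-reactive", airway = "patent",
               hematoma_location = "basal-ganglia", hematoma_volume = 10,
               midline_shift = 0, ventricular_compression = FALSE,
               intraventricular_extension = FALSE,
               history = "hypertension", suspicion = character(0))
  mods <- list(...)
  base[names(mods)] <- mods
  profile_to_state(structure(base, class = "patient_profile"))
}

test_that("ruleset R0 loads, validates, and rejects malformed rulesets", {
  rs <- default_ruleset()
  expect_s3_class(rs, "hich_ruleset")
  expect_gt(length(rs$rules), 25)
  expect_true(all(vapply(rs$rules, function(r) r$weight >= 0, logical(1))))
  bad <- tempfile(fileext = ".yaml")
  writeLines(c("rules:", "  - id: broken", "    when:",
               "      - {field: no_such_field, op: '>=', value: 1}",
               "    adds: [surgery]"), bad)
  expect_error(read_ruleset(bad), class = "hichds_ruleset_error")
  bad2 <- tempfile(fileext = ".yaml")
  writeLines(c("rules:", "  - id: broken2", "    adds: [transplant]"), bad2)
  expect_error(read_ruleset(bad2), class = "hichds_ruleset_error")
})

test_that("surgical indications follow the reconstructed thresholds", {
  # cerebellar 15 mL with ventricular compression -> surgery, cerebellar rule cited
  s <- state_from(hematoma_location = "cerebellar", hematoma_volume = 15,
                  ventricular_compression = TRUE)
  res <- surgical_indication(s)
  expect_true(res$indicated)
  expect_true("surg-cerebellar-volume" %in%
                vapply(res$bases, `[[`, character(1), "rule_id"))
  # supratentorial 40 mL, GCS 9, midline 8 mm -> indicated
  s <- state_from(hematoma_volume = 40, gcs_total = 9, midline_shift = 8)
  expect_true(surgical_indication(s)$indicated)
  # brainstem: never indicated by default, but the conservative rule is cited
  s <- state_from(hematoma_location = "brainstem", hematoma_volume = 60)
  res <- surgical_indication(s)
  expect_false(res$indicated)
  expect_true("surg-brainstem-conservative" %in%
                vapply(res$bases, `[[`, character(1), "rule_id"))
  # zero volume never triggers the volume rules
  s <- state_from(hematoma_volume = 0, midline_shift = 0)
  expect_false(surgical_indication(s)$indicated)
})

test_that("mild supratentorial case gets monitoring, access and antihypertensives only", {
  s <- state_from(gcs_total = 15, hematoma_volume = 5, sbp = 170)
  plan <- decide_plan(s)
  expect_false(plan$surgical)
  expect_setequal(plan$rescue, c("vital-sign-monitoring", "venous-access"))
  expect_setequal(plan$drugs, "antihypertensive")
})

test_that("an all-missing state yields the minimal safe plan with missing-data bases", {
  plan <- decide_plan(patient_state())
  expect_setequal(plan$diagnostic, "repeat-head-CT")
  expect_setequal(plan$rescue, "vital-sign-monitoring")
  expect_false(plan$surgical)
  expect_length(plan$drugs, 0)
  expect_true("dx-missing-ct" %in%
                vapply(plan$bases[["repeat-head-CT"]], `[[`, character(1), "rule_id"))
})

test_that("rescue triggers follow airway state, GCS and oxygenation", {
  res <- rescue_triggers(state_from(airway = "arrest", spo2 = 60, gcs_total = 6))
  expect_true(all(c("CPR", "vital-sign-monitoring", "airway-clearance",
                    "tracheal-intubation", "ventilator") %in% res$items))
  res <- rescue_triggers(state_from(gcs_total = 6, spo2 = 88, airway = "obstructed"))
  expect_true(all(c("airway-clearance", "tracheal-intubation", "ventilator") %in% res$items))
  res <- rescue_triggers(state_from(gcs_total = 15, airway = "patent", spo2 = 99))
  expect_false(any(c("airway-clearance", "tracheal-intubation", "ventilator",
                     "CPR") %in% res$items))
})

test_that("diagnostic triggers cover coagulopathy and atypical presentations", {
  res <- diagnostic_triggers(state_from(history = c("hypertension", "anticoagulant-use")))
  expect_true("coagulation-panel" %in% res$items)
  # young lobar bleed without hypertension: CTA + multimodal MRI activate at
  # weight 1; MRA/DSA stay at 0.5 points, below the 1-point threshold
  s <- state_from(age = 25, hematoma_location = "lobar", history = character(0))
  res <- diagnostic_triggers(s)
  expect_true(all(c("CTA", "multimodal-MRI") %in% res$items))
  expect_false(any(c("MRA", "DSA") %in% res$items))
  # suspicion + atypical: the 0.5-point MRA/DSA rules sum to the threshold
  s <- state_from(age = 25, hematoma_location = "lobar", history = character(0),
                  suspicion = "vascular-lesion")
  res <- diagnostic_triggers(s)
  expect_true(all(c("CTA", "MRA", "DSA") %in% res$items))
  # typical hypertensive basal-ganglia bleed: no vascular imaging
  res <- diagnostic_triggers(state_from())
  expect_setequal(res$items, "repeat-head-CT")
})

test_that("plan coherence closure is enforced and idempotent", {
  plan <- decide_plan(state_from(gcs_total = 6))
  expect_true("tracheal-intubation" %in% plan$rescue)
  expect_true("airway-clearance" %in% plan$rescue)
  expect_identical(hichds:::plan_signature(resolve_conflicts(plan)),
                   hichds:::plan_signature(plan))
  # manual closure: intubation without clearance, CPR without monitoring
  broken <- plan
  broken$rescue <- c("CPR", "tracheal-intubation")
  fixed <- resolve_conflicts(broken)
  expect_true(all(c("airway-clearance", "vital-sign-monitoring") %in% fixed$rescue))
  expect_gte(length(fixed$bases[["airway-clearance"]]), 1)
})

test_that("plans are deterministic and every basis replays true on the state", {
  rs <- default_ruleset(); kg <- hich_kg()
  for (s in c(5, 17)) {
    st <- profile_to_state(sample_profile(seed = 4000 + s))
    p1 <- decide_plan(st, rs, kg)
    p2 <- decide_plan(st, rs, kg)
    expect_identical(p1[names(p1) != "rule_log"], p2[names(p2) != "rule_log"])
    rules_by_id <- stats::setNames(rs$rules, vapply(rs$rules, `[[`, "", "id"))
    for (item in names(p1$bases)) {
      expect_gte(length(p1$bases[[item]]), 1)
      for (b in p1$bases[[item]]) {
        if (b$rule_id == "plan-invariant") next
        expect_true(hichds:::rule_fires(rules_by_id[[b$rule_id]], st),
                    label = sprintf("replay of %s for %s", b$rule_id, item))
      }
    }
  }
})

test_that("surgical indication is monotone in volume and midline shift", {
  set.seed(55)
  for (i in 1:30) {
    st <- profile_to_state(sample_profile(seed = 5000 + i))
    base <- surgical_indication(st)$indicated
    bigger <- st
    bigger$fields$hematoma_volume$value <- st$fields$hematoma_volume$value + runif(1, 0, 80)
    expect_true(surgical_indication(bigger)$indicated >= base)
    shifted <- st
    shifted$fields$midline_shift$value <- st$fields$midline_shift$value + runif(1, 0, 20)
    expect_true(surgical_indication(shifted)$indicated >= base)
  }
})

test_that("dropping any single field never drops vital-sign monitoring", {
  st <- profile_to_state(sample_profile(seed = 606))
  for (f in names(st$fields)) {
    st2 <- st
    st2$fields[[f]] <- hichds:::new_state_field()
    plan <- decide_plan(st2)
    expect_true("vital-sign-monitoring" %in% plan$rescue,
                label = sprintf("monitoring survives missing %s", f))
  }
})

test_that("normalization parses units, resolves duplicate mentions, and warns on junk", {
  kg <- hich_kg()
  # two volume mentions: the later one wins and the conflict is logged
  m <- data.frame(start = c(1, 10), end = c(2, 11), type = "volume",
                  text = c("25 mL", "30 mL"), stringsAsFactors = FALSE)
  st <- normalize_entities(m, kg)
  expect_equal(st$fields$hematoma_volume$value, 30)
  expect_length(st$conflicts, 1)
  expect_equal(st$conflicts[[1]]$dropped, 25)
  # unparseable quantitative mention -> missing with a warning, no crash
  m <- data.frame(start = 1, end = 2, type = "volume", text = "unknown amount",
                  stringsAsFactors = FALSE)
  expect_warning(st <- normalize_entities(m, kg), "unparseable")
  expect_null(hichds:::st_value(st, "hematoma_volume"))
  # empty mention list -> all-missing state
  st <- normalize_entities(data.frame(), kg)
  expect_true(all(vapply(st$fields, function(f) f$confidence == "missing", logical(1))))
  # fully covered document -> fully explicit core fields
  p <- sample_profile(seed = 909)
  doc <- render_emr(p, corruption = corruption_config(seed = 909))
  st <- normalize_entities(tags_to_spans(doc$tags, doc$tokens), kg,
                           structured = doc$meta)
  core <- c("age", "sex", "gcs_total", "sbp", "spo2", "hematoma_location",
            "hematoma_volume", "midline_shift", "pupils", "airway")
  for (f in core) expect_equal(st$fields[[f]]$confidence, "explicit", label = f)
})

test_that("explanations cover every selected item and report empty branches", {
  plan <- decide_plan(state_from(hematoma_volume = 45, gcs_total = 7, spo2 = 85))
  rep <- explain(plan)
  n_items <- length(plan$diagnostic) + plan$surgical + length(plan$rescue) +
    length(plan$drugs)
  expect_equal(sum(vapply(rep, function(b) length(b$items), 1L)), n_items)
  expect_true("surg-supratentorial-volume" %in%
                unlist(lapply(rep$surgical$items[[1]]$bases, `[[`, "rule_id")))
  md <- explain_markdown(rep)
  for (br in names(rep)) {
    for (it in rep[[br]]$items) expect_true(any(grepl(it$item, md, fixed = TRUE)))
  }
  # a plan with an empty branch names the strongest non-fired rule
  plan2 <- decide_plan(state_from())  # no surgery
  rep2 <- explain(plan2)
  expect_equal(rep2$surgical$status, "not indicated")
  expect_false(is.na(rep2$surgical$strongest_non_fired_rule))
  expect_equal(rep2$drugs$status, "indicated")
})
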