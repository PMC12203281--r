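# Seeded synthetic HICH patient profiles. A profile is the structured ground
# truth a note is rendered from; the prevalence configuration is data, so any
# field can be fixed or re-weighted (degenerate configs included) without code
# changes. Clinically linked fields (airway vs GCS, hematoma volume vs
# location, midline shift vs volume) are sampled conditionally.

PROFILE_LOCATIONS <- c("basal-ganglia", "thalamus", "lobar", "cerebellar", "brainstem")
PROFILE_PUPILS <- c("bilateral-equal-reactive", "unilateral-dilated", "bilateral-dilated-fixed")
PROFILE_AIRWAYS <- c("patent", "obstructed", "arrest")
PROFILE_HISTORY <- c("hypertension", "anticoagulant-use", "hemophilia", "hemodialysis")
PROFILE_SUSPICION <- c("vascular-lesion", "tumor")

#' Distribution helpers for the prevalence configuration
#'
#' `dist_point` fixes a field, `dist_cat` draws a category with given
#' probabilities, `dist_norm_int` draws a rounded, clipped normal integer.
#'
#' @param value Fixed value for a point mass.
#' @param values,prob Categories and probabilities (must sum to 1).
#' @param mean,sd,min,max Parameters of the clipped discrete normal.
#' @return A distribution spec (list) for [profile_config()].
#' @export
dist_point <- function(value) list(dist = "point", value = value)

#' @rdname dist_point
#' @export
dist_cat <- function(values, prob) {
  if (length(values) != length(prob) || any(prob < 0) || abs(sum(prob) - 1) > 1e-8) {
    stop_hichds("categorical distribution needs matching values and probabilities summing to 1",
                class = "hichds_config_error")
  }
  list(dist = "cat", values = values, prob = prob)
}

#' @rdname dist_point
#' @export
dist_norm_int <- function(mean, sd, min, max) {
  if (min > max || sd < 0) {
    stop_hichds("invalid support for discrete normal", class = "hichds_config_error")
  }
  list(dist = "norm_int", mean = mean, sd = sd, min = min, max = max)
}

#' Default prevalence configuration for synthetic HICH profiles
#'
#' The defaults describe a plausible emergency-room HICH case mix (deep
#' supratentorial bleeds dominate, most patients hypertensive) and are tuned
#' so that roughly a third of profiles meet the default surgical criteria --
#' a balance chosen so both plan branches are exercised, not an
#' epidemiological claim. Any entry can be overridden, e.g.
#' `profile_config(gcs_total = dist_point(3))`.
#'
#' @param ... Named overrides; each must be a distribution spec
#'   ([dist_point()], [dist_cat()], [dist_norm_int()]) or, for linked fields,
#'   a list with the documented parameters.
#' @return A named list of field distribution specs, class `profile_config`.
#' @export
profile_config <- function(...) {
  cfg <- list(
    age = dist_norm_int(mean = 60, sd = 13, min = 10, max = 80),
    sex = dist_cat(c("male", "female"), c(0.62, 0.38)),
    gcs_total = dist_cat(3:15, c(0.02, 0.03, 0.04, 0.05, 0.05, 0.06,
                                 0.07, 0.08, 0.09, 0.10, 0.12, 0.13, 0.16)),
    sbp = dist_norm_int(mean = 186, sd = 22, min = 110, max = 260),
    # dbp follows sbp with noise
    dbp = list(dist = "linked_sbp", coef = 0.55, sd = 7, min = 55, max = 150),
    # pupil and airway prevalences depend on the GCS band (<=8 / 9-12 / >=13)
    pupils = list(dist = "cat_by_gcs", values = PROFILE_PUPILS,
                  low = c(0.45, 0.35, 0.20), mid = c(0.80, 0.17, 0.03),
                  high = c(0.97, 0.03, 0.00)),
    airway = list(dist = "cat_by_gcs", values = PROFILE_AIRWAYS,
                  low = c(0.45, 0.47, 0.08), mid = c(0.85, 0.15, 0.00),
                  high = c(0.99, 0.01, 0.00)),
    # oxygen saturation depends on the airway state
    spo2 = list(dist = "norm_int_by_airway",
                patent = c(mean = 97, sd = 1.5), obstructed = c(mean = 89, sd = 4),
                arrest = c(mean = 70, sd = 8), min = 40, max = 100),
    hematoma_location = dist_cat(PROFILE_LOCATIONS, c(0.47, 0.16, 0.15, 0.13, 0.09)),
    # log-normal volume whose scale depends on the compartment
    hematoma_volume = list(dist = "lognorm_by_location",
                           meanlog = c("basal-ganglia" = log(21), "thalamus" = log(16),
                                       "lobar" = log(24), "cerebellar" = log(8),
                                       "brainstem" = log(4)),
                           sdlog = 0.65, min = 1, max = 120),
    # supratentorial mass effect scales with volume; infratentorial bleeds
    # rarely shift the midline
    midline_shift = list(dist = "linked_volume", coef = 1 / 6.5, intercept = -3.2,
                         sd = 1.4, min = 0, max = 25),
    ventricular_compression = list(dist = "logit_volume", intercept = -3.2, slope = 0.09,
                                   location_offset = c("cerebellar" = 1.6, "thalamus" = 0.8)),
    intraventricular_extension = list(dist = "bern_by_location",
                                      p = c("basal-ganglia" = 0.18, "thalamus" = 0.38,
                                            "lobar" = 0.06, "cerebellar" = 0.10,
                                            "brainstem" = 0.10)),
    history = list(dist = "flags", p = c("hypertension" = 0.84, "anticoagulant-use" = 0.08,
                                         "hemophilia" = 0.01, "hemodialysis" = 0.03)),
    suspicion = list(dist = "flags", p = c("vascular-lesion" = 0.05, "tumor" = 0.04))
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop_hichds("unknown profile field(s): %s", paste(unknown, collapse = ", "),
                class = "hichds_config_error")
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "profile_config")
}

with_rng_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

draw_simple <- function(spec, field) {
  switch(spec$dist,
    point = spec$value,
    cat = {
      if (length(spec$values) == 1) spec$values else sample(spec$values, 1, prob = spec$prob)
    },
    norm_int = min(spec$max, max(spec$min, round(stats::rnorm(1, spec$mean, spec$sd)))),
    stop_hichds("field '%s': unsupported distribution '%s'", field, spec$dist,
                class = "hichds_config_error")
  )
}

gcs_band <- function(gcs) if (gcs <= 8) "low" else if (gcs <= 12) "mid" else "high"

#' Sample one synthetic patient profile
#'
#' Deterministic given `seed`; the returned profile always satisfies the
#' domain invariants (GCS in 3-15, age in 10-80, non-negative volume and
#' midline shift, SpO2 in 0-100).
#'
#' @param config A [profile_config()].
#' @param seed Integer seed.
#' @return A `patient_profile` (named list).
#' @examples
#' p <- sample_profile(seed = 7)
#' p$gcs_total
#' @export
sample_profile <- function(config = profile_config(), seed) {
  with_rng_seed(seed, sample_profile_impl(config))
}

sample_profile_impl <- function(config) {
  draw_maybe_simple <- function(field, linked_dists, linked_fun) {
    spec <- config[[field]]
    if (spec$dist %in% c("point", "cat", "norm_int")) draw_simple(spec, field)
    else if (spec$dist %in% linked_dists) linked_fun(spec)
    else stop_hichds("field '%s': unsupported distribution '%s'", field, spec$dist,
                     class = "hichds_config_error")
  }
  p <- list()
  p$age <- draw_simple(config$age, "age")
  p$sex <- draw_simple(config$sex, "sex")
  p$gcs_total <- draw_simple(config$gcs_total, "gcs_total")
  p$sbp <- draw_simple(config$sbp, "sbp")
  p$dbp <- draw_maybe_simple("dbp", "linked_sbp", function(s) {
    min(s$max, max(s$min, round(s$coef * p$sbp + stats::rnorm(1, 0, s$sd))))
  })
  band <- gcs_band(p$gcs_total)
  cat_by_gcs <- function(s) {
    pr <- s[[band]]
    if (abs(sum(pr) - 1) > 1e-8) {
      stop_hichds("cat_by_gcs probabilities must sum to 1", class = "hichds_config_error")
    }
    sample(s$values, 1, prob = pr)
  }
  p$pupils <- draw_maybe_simple("pupils", "cat_by_gcs", cat_by_gcs)
  p$airway <- draw_maybe_simple("airway", "cat_by_gcs", cat_by_gcs)
  p$spo2 <- draw_maybe_simple("spo2", "norm_int_by_airway", function(s) {
    pars <- s[[p$airway]]
    min(s$max, max(s$min, round(stats::rnorm(1, pars[["mean"]], pars[["sd"]]))))
  })
  p$hematoma_location <- draw_simple(config$hematoma_location, "hematoma_location")
  p$hematoma_volume <- draw_maybe_simple("hematoma_volume", "lognorm_by_location", function(s) {
    ml <- s$meanlog[[p$hematoma_location]]
    min(s$max, max(s$min, round(stats::rlnorm(1, ml, s$sdlog))))
  })
  p$midline_shift <- draw_maybe_simple("midline_shift", "linked_volume", function(s) {
    if (p$hematoma_location %in% c("cerebellar", "brainstem")) return(0)
    min(s$max, max(s$min, round(s$coef * p$hematoma_volume + s$intercept +
                                  stats::rnorm(1, 0, s$sd))))
  })
  p$ventricular_compression <- draw_maybe_simple(
    "ventricular_compression", "logit_volume", function(s) {
      off <- s$location_offset[p$hematoma_location]
      off <- if (is.na(off)) 0 else off
      stats::runif(1) < stats::plogis(s$intercept + s$slope * p$hematoma_volume + off)
    })
  p$intraventricular_extension <- draw_maybe_simple(
    "intraventricular_extension", "bern_by_location", function(s) {
      stats::runif(1) < s$p[[p$hematoma_location]]
    })
  draw_flags <- function(field, universe) {
    spec <- config[[field]]
    if (spec$dist == "point") return(spec$value)
    if (spec$dist != "flags") {
      stop_hichds("field '%s' needs a 'flags' or 'point' distribution", field,
                  class = "hichds_config_error")
    }
    present <- names(spec$p)[stats::runif(length(spec$p)) < spec$p]
    intersect(universe, present)
  }
  p$history <- draw_flags("history", PROFILE_HISTORY)
  p$suspicion <- draw_flags("suspicion", PROFILE_SUSPICION)
  p <- structure(p, class = "patient_profile")
  validate_profile(p)
  p
}

#' Validate a patient profile against its domain invariants
#'
#' @param profile A `patient_profile`.
#' @return The profile, invisibly; errors on violation.
#' @export
validate_profile <- function(profile) {
  chk <- function(ok, msg) if (!ok) {
    stop_hichds("invalid profile: %s", msg, class = "hichds_config_error")
  }
  chk(profile$gcs_total >= 3 && profile$gcs_total <= 15, "GCS must be in 3..15")
  chk(profile$age >= 10 && profile$age <= 80, "age must be in 10..80")
  chk(profile$hematoma_volume >= 0, "hematoma volume must be >= 0")
  chk(profile$midline_shift >= 0, "midline shift must be >= 0")
  chk(profile$spo2 >= 0 && profile$spo2 <= 100, "SpO2 must be in 0..100")
  chk(profile$hematoma_location %in% PROFILE_LOCATIONS, "unknown hematoma location")
  chk(profile$pupils %in% PROFILE_PUPILS, "unknown pupil state")
  chk(profile$airway %in% PROFILE_AIRWAYS, "unknown airway state")
  chk(all(profile$history %in% PROFILE_HISTORY), "unknown history flag")
  chk(all(profile$suspicion %in% PROFILE_SUSPICION), "unknown suspicion flag")
  invisible(profile)
}

#' Sample many profiles with per-profile derived seeds
#'
#' @param n Number of profiles.
#' @inheritParams sample_profile
#' @return List of `patient_profile` objects.
#' @export
sample_profiles <- function(n, config = profile_config(), seed) {
  lapply(seq_len(n), function(i) sample_profile(config, derive_seed(seed, i)))
}
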