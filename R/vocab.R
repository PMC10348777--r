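# Controlled vocabularies and default raw-code maps.
#
# The analysis vocabularies mirror how California trauma-system variables are
# usually categorized; the raw-code maps translate the administrative dialect
# (lower-case strings in the discharge files) into those vocabularies. Both
# are configurable because administrative code sets drift between data years.

#' Controlled vocabularies used by the re-triage analysis
#'
#' @return A named list of character vectors: trauma levels, facility types,
#'   RTCC labels, and the coded analysis covariates (age bands, sex, race,
#'   ethnicity, insurance, injury mechanism, body region, injury-severity
#'   bands). The first element of each covariate vector is its reference
#'   level in the regression model.
#' @export
retriage_vocabulary <- function() {
  list(
    trauma_level  = c("NONTRAUMA", "LEVEL_I", "LEVEL_II", "LEVEL_III", "LEVEL_IV"),
    facility_type = c("SHORT_TERM_ACUTE", "REHAB", "PSYCH", "LONG_TERM", "OTHER"),
    rtcc          = c("NORTH", "BAY_AREA", "CENTRAL", "SOUTH_EAST", "SOUTH_WEST"),
    age_band      = c("18-24", "25-34", "35-44", "45-54", "55-64",
                      "65-74", "75-84", "85-89"),
    sex           = c("MALE", "FEMALE"),
    race          = c("WHITE", "BLACK", "ASIAN", "OTHER"),
    ethnicity     = c("NON_HISPANIC", "HISPANIC"),
    insurance     = c("SELF_PAY", "PRIVATE", "MEDICARE", "MEDICAID",
                      "MANAGED_CARE_UNSPECIFIED", "OTHER"),
    mechanism     = c("ALL_TRANSPORT", "FALL", "STRUCK", "OTHER"),
    body_region   = c("TORSO", "TBI", "OTHER_HEAD_FACE_NECK", "EXTREMITIES", "OTHER"),
    riss_band     = c("16-25", ">25")
  )
}

# trauma levels counted as "low level" (eligible senders / suboptimal receivers)
low_trauma_levels <- function() c("NONTRAUMA", "LEVEL_III", "LEVEL_IV")
high_trauma_levels <- function() c("LEVEL_I", "LEVEL_II")

#' Covariate vocabulary for effect specifications
#'
#' Names accepted in `covariate_effects` (simulation) and `true_betas`
#' (GLMM simulation) take the form `"variable=LEVEL"`, e.g. `"sex=FEMALE"`
#' or `"rtcc_id=SOUTH_WEST"`. `"(Intercept)"` is always accepted.
#'
#' @param rtccs RTCC labels in use (defaults to the five California regions).
#' @return Character vector of all valid effect names.
#' @export
covariate_effect_names <- function(rtccs = retriage_vocabulary()$rtcc) {
  v <- retriage_vocabulary()
  vars <- list(
    age_band = v$age_band, sex = v$sex, race = v$race, ethnicity = v$ethnicity,
    insurance = v$insurance, mechanism = v$mechanism, body_region = v$body_region,
    riss_band = v$riss_band, rtcc_id = rtccs
  )
  c("(Intercept)",
    unlist(lapply(names(vars), function(nm) paste0(nm, "=", vars[[nm]])),
           use.names = FALSE))
}

#' Default raw-code maps for covariate encoding
#'
#' Maps the administrative (lower-case) codes emitted by the synthetic
#' generator -- and typical of discharge abstracts -- onto the analysis
#' vocabularies. Managed-care codes map to PRIVATE except the unspecified
#' managed-care plans (HMO/PPO/POS reported without a payer), which are kept
#' as their own MANAGED_CARE_UNSPECIFIED category rather than being subsumed
#' under Medicare or private coverage.
#'
#' @return Named list of named character vectors (`insurance`, `race`,
#'   `mechanism`), raw code -> coded level.
#' @export
default_code_maps <- function() {
  list(
    insurance = c(
      "self-pay"                       = "SELF_PAY",
      "commercial insurance company"   = "PRIVATE",
      "blue cross blue shield"         = "PRIVATE",
      "exclusive provider organization" = "PRIVATE",
      "managed care - commercial"      = "PRIVATE",
      "medicare part a"                = "MEDICARE",
      "medicare part b"                = "MEDICARE",
      "medicare risk"                  = "MEDICARE",
      "medicare hmo"                   = "MEDICARE",
      "medi-cal"                       = "MEDICAID",
      "hmo-unspecified"                = "MANAGED_CARE_UNSPECIFIED",
      "ppo-unspecified"                = "MANAGED_CARE_UNSPECIFIED",
      "pos-unspecified"                = "MANAGED_CARE_UNSPECIFIED",
      "workers compensation"           = "OTHER",
      "federal"                        = "OTHER",
      "county indigent"                = "OTHER",
      "other"                          = "OTHER"
    ),
    race = c(
      "white"            = "WHITE",
      "black"            = "BLACK",
      "african american" = "BLACK",
      "asian"            = "ASIAN",
      "native american"  = "OTHER",
      "pacific islander" = "OTHER",
      "other"            = "OTHER",
      "unknown"          = "OTHER"
    ),
    mechanism = c(
      "motor vehicle traffic" = "ALL_TRANSPORT",
      "motorcycle"            = "ALL_TRANSPORT",
      "pedestrian"            = "ALL_TRANSPORT",
      "pedal cyclist"         = "ALL_TRANSPORT",
      "fall"                  = "FALL",
      "struck by or against"  = "STRUCK",
      "firearm"               = "OTHER",
      "machinery"             = "OTHER",
      "other"                 = "OTHER",
      "unspecified"           = "OTHER"
    )
  )
}

#' Default receiving-center discharge-disposition collapse map
#'
#' Collapses raw discharge-disposition codes at the receiving hospital into
#' the four analysis groups: HOME, DIED, SHORT_TERM_ACUTE (transferred onward
#' to a third short-term acute-care general hospital), and POST_ACUTE
#' (skilled nursing, rehabilitation, long-term or residential care).
#' Left-against-medical-advice discharges return to the community and are
#' grouped with HOME by default; the map is replaceable.
#'
#' @return Named character vector, raw code -> group.
#' @export
default_disposition_map <- function() {
  c(
    "routine home"                              = "HOME",
    "home health service"                       = "HOME",
    "left against medical advice"               = "HOME",
    "expired"                                   = "DIED",
    "transfer to short-term general hospital"   = "SHORT_TERM_ACUTE",
    "skilled nursing facility"                  = "POST_ACUTE",
    "intermediate care facility"                = "POST_ACUTE",
    "inpatient rehabilitation facility"         = "POST_ACUTE",
    "long-term care hospital"                   = "POST_ACUTE",
    "residential care facility"                 = "POST_ACUTE"
  )
}

#' Sending-ED dispositions that exclude an encounter from the cohort
#'
#' Patients who died in the sending ED, left against medical advice, or were
#' discharged to inpatient rehabilitation with a planned acute-care
#' readmission are not re-triage candidates.
#'
#' @return Character vector of raw ED disposition codes.
#' @export
default_excluded_ed_dispositions <- function() {
  c("expired",
    "left against medical advice",
    "inpatient rehabilitation with planned readmission")
}

# body-region precedence when several regions are flagged on one encounter:
# traumatic brain injury dominates, then torso, other head/face/neck,
# extremities, and finally other.
body_region_precedence <- function() {
  c("TBI", "TORSO", "OTHER_HEAD_FACE_NECK", "EXTREMITIES", "OTHER")
}
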