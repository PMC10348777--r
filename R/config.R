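# Simulation configuration.
#
# Defaults reproduce the statewide study conditions wherever the source
# system reports them: ten data years (2009-2018), a 20.6% probability that
# an under-triaged patient is re-triaged within one day (8,882 of 43,066
# low-level presentations), per-RTCC suboptimality probabilities equal to the
# pooled observed regional rates, ~25% of ED encounters (and ~12.5% of
# inpatient encounters) missing the record linkage number, and covariate
# marginals close to the published cohort table. Values the system does not
# report (duplicate rate, edge-case injection rates, length-of-stay law) are
# fixed once at realistic magnitudes; see the methods vignette.

#' Simulation configuration for the synthetic administrative data generator
#'
#' @param n_patients Number of seriously injured patients to simulate.
#' @param years Inclusive range of calendar years in the simulation horizon.
#' @param n_hospitals Named integer vector of short-term acute-care hospital
#'   counts **per RTCC** by trauma level (names from
#'   `retriage_vocabulary()$trauma_level`).
#' @param n_nonacute Number of non-acute facilities (rehab/psych/long-term)
#'   per RTCC, used to exercise the receiving-facility exclusion.
#' @param n_lemsas_per_rtcc Number of local EMS agencies per RTCC.
#' @param rtccs RTCC labels; defaults to the five California regions, but
#'   synthetic labels are accepted (each then receives a generated bounding
#'   box).
#' @param p_undertriage_to_low Probability a patient first presents to a
#'   nontrauma or level III/IV center (the remainder are field-triaged
#'   directly to level I/II and excluded downstream).
#' @param p_retriage_within_1day Probability an under-triaged patient is
#'   transferred within the 1-day window.
#' @param p_suboptimal_given_retriage Scalar or per-RTCC named vector of
#'   probabilities that the receiving center is again nontrauma/III/IV.
#' @param p_missing_rln,p_missing_rln_inpatient Probability an ED (resp.
#'   inpatient) record lacks a record linkage number.
#' @param p_duplicate Probability a record row is emitted twice verbatim.
#' @param covariate_effects Optional named numeric vector of log-odds shifts
#'   applied to the suboptimality assignment, names of the form
#'   `"variable=LEVEL"` (see [covariate_effect_names()]).
#' @param center_sigma,year_sigma Standard deviations of the sending-center
#'   and year random intercepts entering the suboptimality logit.
#' @param p_interfacility Probability a transferred patient moves with a gap
#'   of 2+ days (an interfacility transfer, not a re-triage).
#' @param p_elective Probability the receiving admission is coded elective.
#' @param p_nonacute_receiving Probability the receiving facility is a
#'   rehab/psych/long-term facility.
#' @param p_excluded_disposition Probability the sending-ED disposition is
#'   one of the excluded codes (expired / AMA / rehab with planned
#'   readmission).
#' @param p_age_out,p_low_riss,p_burn,p_no_injury_dx Probabilities of the
#'   remaining exclusion edge cases (age outside 18-89, injury-severity
#'   score of 15 or less, burn injury, no injury diagnosis).
#' @param p_die_receiving Probability of in-hospital death at the receiving
#'   center.
#' @param p_transfer_third Probability of onward transfer to a third
#'   short-term acute hospital.
#' @param p_post_acute Probability of discharge to post-acute care.
#' @param p_readmit Probability a surviving re-triaged patient is readmitted
#'   within 70 days.
#' @param los_lambda Poisson mean of the receiving length of stay in days
#'   (median ~4 days at the default).
#' @param covariate_marginals Named list of probability vectors for the coded
#'   covariates (see [default_covariate_marginals()]).
#' @param surgery_probs Probabilities of the receiving-center surgery classes
#'   (NONE/DIAGNOSTIC/MINOR_THERAPEUTIC/MAJOR_THERAPEUTIC); must sum to 1.
#' @param level_changes Optional data frame (`facility_id`, `year`, `level`)
#'   re-designating a facility from `year` onward.
#' @param seed Integer seed; fully determines all generator output.
#' @return A validated list of class `retriage_sim_config`.
#' @seealso [generate_hospital_directory()], [generate_encounters()]
#' @export
sim_config <- function(n_patients = 5000,
                       years = 2009:2018,
                       n_hospitals = c(NONTRAUMA = 8L, LEVEL_I = 1L, LEVEL_II = 2L,
                                       LEVEL_III = 2L, LEVEL_IV = 1L),
                       n_nonacute = 2L,
                       n_lemsas_per_rtcc = 6L,
                       rtccs = retriage_vocabulary()$rtcc,
                       p_undertriage_to_low = 0.85,
                       p_retriage_within_1day = 0.206,
                       p_suboptimal_given_retriage = c(
                         NORTH = 0.220, BAY_AREA = 0.375, CENTRAL = 0.104,
                         SOUTH_EAST = 0.202, SOUTH_WEST = 0.688),
                       p_missing_rln = 0.25,
                       p_missing_rln_inpatient = 0.125,
                       p_duplicate = 0.05,
                       covariate_effects = NULL,
                       center_sigma = 0,
                       year_sigma = 0,
                       p_interfacility = 0.03,
                       p_elective = 0.01,
                       p_nonacute_receiving = 0.01,
                       p_excluded_disposition = 0.02,
                       p_age_out = 0.01,
                       p_low_riss = 0.05,
                       p_burn = 0.01,
                       p_no_injury_dx = 0.01,
                       p_die_receiving = 0.05,
                       p_transfer_third = 0.04,
                       p_post_acute = 0.15,
                       p_readmit = 0.15,
                       los_lambda = 4,
                       covariate_marginals = default_covariate_marginals(),
                       surgery_probs = c(NONE = 0.80, DIAGNOSTIC = 0.02,
                                         MINOR_THERAPEUTIC = 0.08,
                                         MAJOR_THERAPEUTIC = 0.10),
                       level_changes = NULL,
                       seed = 1L) {
  if (length(p_suboptimal_given_retriage) == 1L && is.null(names(p_suboptimal_given_retriage))) {
    p_suboptimal_given_retriage <- setNames(rep(p_suboptimal_given_retriage, length(rtccs)), rtccs)
  }
  cfg <- structure(
    list(
      n_patients = as.integer(n_patients), years = as.integer(years),
      n_hospitals = n_hospitals, n_nonacute = as.integer(n_nonacute),
      n_lemsas_per_rtcc = as.integer(n_lemsas_per_rtcc), rtccs = rtccs,
      p_undertriage_to_low = p_undertriage_to_low,
      p_retriage_within_1day = p_retriage_within_1day,
      p_suboptimal_given_retriage = p_suboptimal_given_retriage,
      p_missing_rln = p_missing_rln,
      p_missing_rln_inpatient = p_missing_rln_inpatient,
      p_duplicate = p_duplicate,
      covariate_effects = covariate_effects,
      center_sigma = center_sigma, year_sigma = year_sigma,
      p_interfacility = p_interfacility, p_elective = p_elective,
      p_nonacute_receiving = p_nonacute_receiving,
      p_excluded_disposition = p_excluded_disposition,
      p_age_out = p_age_out, p_low_riss = p_low_riss, p_burn = p_burn,
      p_no_injury_dx = p_no_injury_dx,
      p_die_receiving = p_die_receiving, p_transfer_third = p_transfer_third,
      p_post_acute = p_post_acute, p_readmit = p_readmit,
      los_lambda = los_lambda,
      covariate_marginals = covariate_marginals,
      surgery_probs = surgery_probs,
      level_changes = level_changes,
      seed = as.integer(seed)
    ),
    class = "retriage_sim_config"
  )
  validate_sim_config(cfg)
}

#' @export
print.retriage_sim_config <- function(x, ...) {
  cat("<retriage_sim_config>\n")
  cat("  patients:", x$n_patients, " years:", min(x$years), "-", max(x$years),
      " seed:", x$seed, "\n")
  cat("  hospitals/RTCC:", paste(names(x$n_hospitals), x$n_hospitals,
                                 sep = "=", collapse = " "), "\n")
  cat("  P(retriage<=1d):", x$p_retriage_within_1day,
      " P(suboptimal):", paste(sprintf("%s=%.3f", names(x$p_suboptimal_given_retriage),
                                       x$p_suboptimal_given_retriage), collapse = " "), "\n")
  invisible(x)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "retriage_sim_config"))
  probs <- c(cfg$p_undertriage_to_low, cfg$p_retriage_within_1day,
             cfg$p_suboptimal_given_retriage, cfg$p_missing_rln,
             cfg$p_missing_rln_inpatient, cfg$p_duplicate, cfg$p_interfacility,
             cfg$p_elective, cfg$p_nonacute_receiving, cfg$p_excluded_disposition,
             cfg$p_age_out, cfg$p_low_riss, cfg$p_burn, cfg$p_no_injury_dx,
             cfg$p_die_receiving, cfg$p_transfer_third, cfg$p_post_acute,
             cfg$p_readmit)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities in a simulation config must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$center_sigma < 0 || cfg$year_sigma < 0) {
    stop("random-intercept standard deviations must be nonnegative", call. = FALSE)
  }
  if (!all(names(cfg$n_hospitals) %in% retriage_vocabulary()$trauma_level)) {
    stop("names of n_hospitals must be trauma levels", call. = FALSE)
  }
  if (!setequal(names(cfg$p_suboptimal_given_retriage), cfg$rtccs)) {
    stop("p_suboptimal_given_retriage must be a scalar or named per RTCC", call. = FALSE)
  }
  if (abs(sum(cfg$surgery_probs) - 1) > 1e-8) {
    stop("surgery_probs must sum to 1", call. = FALSE)
  }
  if (!is.null(cfg$covariate_effects)) {
    bad <- setdiff(names(cfg$covariate_effects), covariate_effect_names(cfg$rtccs))
    if (length(bad)) {
      stop("unknown covariate effect name(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  if (!is.null(cfg$level_changes)) {
    stopifnot(all(c("facility_id", "year", "level") %in% names(cfg$level_changes)))
  }
  cfg
}

#' Default coded covariate marginals
#'
#' Rough frequencies of the coded covariates in the statewide re-triage
#' cohort (predominantly elderly, ~59% male, ~74% white, falls the dominant
#' mechanism, traumatic brain injury the dominant body region). These are
#' realistic defaults for generating administrative records, not a claim of
#' demographic fidelity; every entry is replaceable.
#'
#' @return Named list of probability vectors keyed by coded covariate.
#' @export
default_covariate_marginals <- function() {
  list(
    age_band = c("18-24" = 0.047, "25-34" = 0.059, "35-44" = 0.060,
                 "45-54" = 0.091, "55-64" = 0.141, "65-74" = 0.167,
                 "75-84" = 0.240, "85-89" = 0.195),
    sex = c(MALE = 0.592, FEMALE = 0.408),
    race = c(WHITE = 0.743, BLACK = 0.046, ASIAN = 0.070, OTHER = 0.141),
    ethnicity = c(NON_HISPANIC = 0.784, HISPANIC = 0.216),
    insurance = c(SELF_PAY = 0.071, PRIVATE = 0.074, MEDICARE = 0.576,
                  MEDICAID = 0.111, MANAGED_CARE_UNSPECIFIED = 0.131,
                  OTHER = 0.037),
    mechanism = c(ALL_TRANSPORT = 0.152, FALL = 0.643, STRUCK = 0.057,
                  OTHER = 0.148),
    body_region = c(TORSO = 0.046, TBI = 0.878, OTHER_HEAD_FACE_NECK = 0.029,
                    EXTREMITIES = 0.020, OTHER = 0.027),
    riss_band = c("16-25" = 0.919, ">25" = 0.081)
  )
}

# Per-RTCC coordinate bounding boxes (lat_min, lat_max, lon_min, lon_max).
# The five California regions get geography-shaped boxes; synthetic RTCC
# labels get a deterministic grid of 2x2-degree boxes.
rtcc_bounding_boxes <- function(rtccs) {
  known <- list(
    NORTH      = c(lat_min = 38.8, lat_max = 42.0, lon_min = -124.4, lon_max = -119.9),
    BAY_AREA   = c(lat_min = 36.9, lat_max = 38.8, lon_min = -123.1, lon_max = -121.2),
    CENTRAL    = c(lat_min = 35.0, lat_max = 38.0, lon_min = -121.5, lon_max = -118.0),
    SOUTH_EAST = c(lat_min = 32.5, lat_max = 34.6, lon_min = -117.2, lon_max = -114.1),
    SOUTH_WEST = c(lat_min = 32.8, lat_max = 35.0, lon_min = -120.6, lon_max = -117.2)
  )
  out <- vector("list", length(rtccs))
  names(out) <- rtccs
  grid_i <- 0L
  for (r in rtccs) {
    if (!is.null(known[[r]])) {
      out[[r]] <- known[[r]]
    } else {
      out[[r]] <- c(lat_min = 30 + 2.5 * grid_i, lat_max = 32 + 2.5 * grid_i,
                    lon_min = -100, lon_max = -98)
      grid_i <- grid_i + 1L
    }
  }
  out
}
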