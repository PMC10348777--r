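# Synthetic administrative data with known ground truth.
#
# The generator emulates linked statewide ED / inpatient discharge files:
# pseudonymous record linkage numbers (RLN), date-only stamps, raw
# administrative covariate codes, duplicate rows, missing identifiers, and
# every downstream exclusion edge case (interfacility transfers, elective
# admissions, non-acute receiving facilities, excluded ED dispositions,
# out-of-range age, low injury severity, burns, missing injury diagnosis).
# Every patient's true re-triage status and optimality label are recorded so
# the whole pipeline can be validated without any real data.

#' Generate a synthetic hospital directory
#'
#' Creates `sum(config$n_hospitals) + config$n_nonacute` facilities per RTCC,
#' with coordinates drawn uniformly inside a per-RTCC bounding box, a LEMSA
#' membership, a facility type, and an annual trauma-level designation for
#' every year of the simulation horizon. Optional `config$level_changes`
#' re-designate a facility from a given year onward.
#'
#' @param config A [sim_config()].
#' @return A tibble of class `retriage_directory` with one row per
#'   facility-year: `facility_id`, `name`, `latitude`, `longitude`,
#'   `facility_type`, `lemsa_id`, `rtcc_id`, `year`, `level`.
#'   A directory without any level I/II center is permitted (it exercises the
#'   optimizer's no-alternative path) and is flagged by [summary()].
#' @export
generate_hospital_directory <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$seed)
  boxes <- rtcc_bounding_boxes(config$rtccs)
  rows <- list()
  idx <- 0L
  for (r in config$rtccs) {
    lemsas <- sprintf("%s_L%02d", r, seq_len(config$n_lemsas_per_rtcc))
    lv <- rep(names(config$n_hospitals), times = config$n_hospitals)
    types <- rep("SHORT_TERM_ACUTE", length(lv))
    if (config$n_nonacute > 0L) {
      lv <- c(lv, rep("NONTRAUMA", config$n_nonacute))
      types <- c(types, rep_len(c("REHAB", "PSYCH", "LONG_TERM"), config$n_nonacute))
    }
    k <- length(lv)
    if (k == 0L) next
    b <- boxes[[r]]
    ids <- sprintf("H%04d", idx + seq_len(k))
    rows[[r]] <- tibble::tibble(
      facility_id = ids,
      name = paste("Hospital", ids),
      latitude = runif(k, b[["lat_min"]], b[["lat_max"]]),
      longitude = runif(k, b[["lon_min"]], b[["lon_max"]]),
      base_level = lv,
      facility_type = types,
      lemsa_id = sample(lemsas, k, replace = TRUE),
      rtcc_id = r
    )
    idx <- idx + k
  }
  base <- dplyr::bind_rows(rows)
  nyear <- length(config$years)
  dir <- base[rep(seq_len(nrow(base)), each = nyear), , drop = FALSE]
  dir$year <- rep(config$years, times = nrow(base))
  dir$level <- dir$base_level
  if (!is.null(config$level_changes)) {
    ch <- config$level_changes
    for (i in seq_len(nrow(ch))) {
      if (!any(dir$facility_id == ch$facility_id[i])) {
        stop("level_changes references unknown facility_id: ", ch$facility_id[i],
             call. = FALSE)
      }
      sel <- dir$facility_id == ch$facility_id[i] & dir$year >= ch$year[i]
      dir$level[sel] <- ch$level[i]
    }
  }
  dir$base_level <- NULL
  dir <- tibble::as_tibble(dir)
  class(dir) <- c("retriage_directory", class(dir))
  dir
}

#' @export
summary.retriage_directory <- function(object, ...) {
  acute <- object[object$facility_type == "SHORT_TERM_ACUTE", ]
  first_year <- object[object$year == min(object$year), ]
  tab <- table(first_year$rtcc_id, first_year$level)
  no_high <- !any(object$level %in% high_trauma_levels() &
                    object$facility_type == "SHORT_TERM_ACUTE")
  out <- list(
    n_facilities = length(unique(object$facility_id)),
    n_short_term_acute = length(unique(acute$facility_id)),
    years = range(object$year),
    levels_by_rtcc_first_year = tab,
    no_high_level_centers = no_high
  )
  cat("<retriage_directory> ", out$n_facilities, " facilities (",
      out$n_short_term_acute, " short-term acute), years ",
      out$years[1], "-", out$years[2], "\n", sep = "")
  print(tab)
  if (no_high) {
    cat("NOTE: directory contains no operating level I/II trauma center;\n",
        "      every re-triage will be suboptimal and the destination\n",
        "      optimizer will report resolvable = FALSE.\n", sep = "")
  }
  invisible(out)
}

# inverse raw-code pools: coded level -> administrative code strings that
# encode_covariates() maps back to the same level
raw_code_pools <- function() {
  list(
    insurance = list(
      SELF_PAY = "self-pay",
      PRIVATE = c("commercial insurance company", "blue cross blue shield",
                  "exclusive provider organization"),
      MEDICARE = c("medicare part a", "medicare part b", "medicare risk",
                   "medicare hmo"),
      MEDICAID = "medi-cal",
      MANAGED_CARE_UNSPECIFIED = c("hmo-unspecified", "ppo-unspecified",
                                   "pos-unspecified"),
      OTHER = c("workers compensation", "federal", "other")
    ),
    race = list(
      WHITE = "white", BLACK = c("black", "african american"), ASIAN = "asian",
      OTHER = c("native american", "pacific islander", "other", "unknown")
    ),
    mechanism = list(
      ALL_TRANSPORT = c("motor vehicle traffic", "motorcycle", "pedestrian",
                        "pedal cyclist"),
      FALL = "fall", STRUCK = "struck by or against",
      OTHER = c("firearm", "machinery", "other", "unspecified")
    )
  )
}

raw_from_coded <- function(coded, pools) {
  out <- character(length(coded))
  for (lvl in unique(coded)) {
    i <- coded == lvl
    pool <- pools[[lvl]]
    out[i] <- if (length(pool) == 1L) pool else sample(pool, sum(i), replace = TRUE)
  }
  out
}

#' Generate linked synthetic ED and inpatient encounter records
#'
#' Simulates one ED encounter per patient at a sending center; with
#' probability `p_retriage_within_1day` (for patients presenting to a
#' nontrauma/III/IV center) a receiving inpatient record follows at a gap of
#' 0 or 1 day, at a facility whose level is drawn from the configured
#' suboptimality model (per-RTCC base rate + covariate log-odds + sending
#' center and year random intercepts on the logit scale). Exclusion edge
#' cases, duplicate rows, missing RLNs, and later readmission records are
#' injected at the configured rates. All output is deterministic under
#' `config$seed`.
#'
#' @param config A [sim_config()]. Covariate effect names outside the
#'   vocabulary of [covariate_effect_names()] are rejected.
#' @param directory A [generate_hospital_directory()] result.
#' @return A list with tibbles `ed`, `inpatient` (the two record files,
#'   duplicates and missing RLNs included) and `truth` (one row per patient:
#'   `patient_id`, `rln`, sending/receiving facility, `gap_days`,
#'   `transferred`, `retriaged_within_1day`, `true_retriage` -- the patient
#'   would survive the full inclusion/exclusion cascade -- and `true_label`).
#' @export
generate_encounters <- function(config, directory) {
  config <- validate_sim_config(config)
  if (!is.data.frame(directory) || nrow(directory) == 0L) {
    stop("directory must be a nonempty hospital directory", call. = FALSE)
  }
  set.seed(config$seed + 1L)
  n <- config$n_patients
  years <- config$years
  marg <- config$covariate_marginals
  pools <- raw_code_pools()
  draw <- function(p, k) sample(names(p), k, replace = TRUE, prob = p)

  pat <- tibble::tibble(
    patient_id = sprintf("P%06d", seq_len(n)),
    rln = sprintf("RLN%06d", seq_len(n)),
    age_band = draw(marg$age_band, n),
    sex = draw(marg$sex, n),
    race_coded = draw(marg$race, n),
    ethnicity = draw(marg$ethnicity, n),
    insurance_coded = draw(marg$insurance, n),
    mechanism_coded = draw(marg$mechanism, n),
    body_region_coded = draw(marg$body_region, n),
    riss_band = draw(marg$riss_band, n)
  )
  lo <- as.integer(sub("-.*", "", pat$age_band))
  hi <- as.integer(sub(".*-", "", pat$age_band))
  pat$age <- lo + floor(runif(n) * (hi - lo + 1L))
  pat$riss <- ifelse(pat$riss_band == ">25",
                     26L + floor(runif(n) * 16), 16L + floor(runif(n) * 10))
  pat$race <- raw_from_coded(pat$race_coded, pools$race)
  pat$insurance <- raw_from_coded(pat$insurance_coded, pools$insurance)
  pat$mechanism <- raw_from_coded(pat$mechanism_coded, pools$mechanism)

  # multi-region encounters: append a strictly lower-precedence secondary
  # region so the precedence rule recovers the primary
  prec <- body_region_precedence()
  pat$body_region <- pat$body_region_coded
  multi <- which(runif(n) < 0.10)
  for (i in multi) {
    pos <- match(pat$body_region_coded[i], prec)
    if (pos < length(prec)) {
      rest <- prec[(pos + 1L):length(prec)]
      sec <- if (length(rest) == 1L) rest else sample(rest, 1L)
      pat$body_region[i] <- paste(pat$body_region_coded[i], sec, sep = ";")
    }
  }

  # exclusion edge cases on the patient
  pat$age_out <- runif(n) < config$p_age_out
  if (any(pat$age_out)) {
    pat$age[pat$age_out] <- sample(c(15:17, 90:99), sum(pat$age_out), replace = TRUE)
  }
  pat$low_riss <- runif(n) < config$p_low_riss
  if (any(pat$low_riss)) {
    pat$riss[pat$low_riss] <- sample(1:15, sum(pat$low_riss), replace = TRUE)
  }
  pat$burn_flag <- runif(n) < config$p_burn
  pat$injury_dx <- runif(n) >= config$p_no_injury_dx

  # presentation dates (date-only, per the administrative format)
  d0 <- as.Date(sprintf("%d-01-01", min(years)))
  d1 <- as.Date(sprintf("%d-12-31", max(years)))
  pat$ed_date <- d0 + floor(runif(n) * (as.integer(d1 - d0) + 1L))
  pat$year <- as.integer(format(pat$ed_date, "%Y"))

  # facility pools by year (and RTCC) from the directory
  fac <- directory
  stac <- fac[fac$facility_type == "SHORT_TERM_ACUTE", ]
  is_low <- stac$level %in% low_trauma_levels()
  is_high <- stac$level %in% high_trauma_levels()
  keyr <- paste(stac$year, stac$rtcc_id, sep = "|")
  low_set <- split(stac$facility_id[is_low], keyr[is_low])
  high_set <- split(stac$facility_id[is_high], keyr[is_high])
  low_by_year <- split(stac$facility_id[is_low], stac$year[is_low])
  high_by_year <- split(stac$facility_id[is_high], stac$year[is_high])
  nonacute <- fac[fac$facility_type != "SHORT_TERM_ACUTE", ]
  nonacute_by_year <- split(nonacute$facility_id, nonacute$year)

  pat$low_sender <- runif(n) < config$p_undertriage_to_low
  pat$sending_facility_id <- NA_character_
  for (y in years) {
    ykey <- as.character(y)
    pool_low <- low_by_year[[ykey]] %||% character(0)
    pool_high <- high_by_year[[ykey]] %||% character(0)
    if (length(pool_high) == 0L) pool_high <- pool_low
    if (length(pool_low) == 0L) {
      stop("directory has no low-level short-term acute facility in year ", y,
           call. = FALSE)
    }
    il <- which(pat$year == y & pat$low_sender)
    if (length(il)) pat$sending_facility_id[il] <- sample(pool_low, length(il), replace = TRUE)
    ih <- which(pat$year == y & !pat$low_sender)
    if (length(ih)) pat$sending_facility_id[ih] <- sample(pool_high, length(ih), replace = TRUE)
  }
  fac_year <- fac[, c("facility_id", "year", "level", "facility_type",
                      "lemsa_id", "rtcc_id")]
  pat <- dplyr::left_join(
    pat,
    dplyr::rename(fac_year, sending_level = "level",
                  sending_facility_type = "facility_type"),
    by = c("sending_facility_id" = "facility_id", "year" = "year")
  )

  # transfer structure
  pat$transferred <- pat$low_sender & (runif(n) < config$p_retriage_within_1day)
  pat$interfacility <- pat$transferred & (runif(n) < config$p_interfacility)
  u_gap <- runif(n)
  pat$gap_days <- ifelse(pat$interfacility, 2L + floor(u_gap * 9),
                         as.integer(u_gap < 0.5))
  pat$gap_days[!pat$transferred] <- NA_integer_

  # suboptimality assignment on the logit scale
  b_center <- setNames(rnorm(length(unique(stac$facility_id)), 0, config$center_sigma),
                       unique(stac$facility_id))
  b_year <- setNames(rnorm(length(years), 0, config$year_sigma), as.character(years))
  eta <- qlogis(unname(config$p_suboptimal_given_retriage[pat$rtcc_id])) +
    b_center[pat$sending_facility_id] + b_year[as.character(pat$year)]
  if (!is.null(config$covariate_effects)) {
    colmap <- c(age_band = "age_band", sex = "sex", race = "race_coded",
                ethnicity = "ethnicity", insurance = "insurance_coded",
                mechanism = "mechanism_coded", body_region = "body_region_coded",
                riss_band = "riss_band", rtcc_id = "rtcc_id")
    for (nm in names(config$covariate_effects)) {
      bval <- config$covariate_effects[[nm]]
      if (nm == "(Intercept)") {
        eta <- eta + bval
      } else {
        parts <- strsplit(nm, "=", fixed = TRUE)[[1]]
        eta <- eta + bval * (pat[[colmap[[parts[1]]]]] == parts[2])
      }
    }
  }
  pat$suboptimal_intent <- pat$transferred & (runif(n) < plogis(eta))
  pat$nonacute_recv <- pat$transferred & (runif(n) < config$p_nonacute_receiving)
  pat$elective <- pat$transferred & (runif(n) < config$p_elective)

  # receiving facility: same-RTCC candidates preferred, never the sender
  sample_receiving <- function(pool_r, pool_all, sending) {
    vapply(sending, function(s) {
      cand <- setdiff(pool_r, s)
      if (!length(cand)) cand <- setdiff(pool_all, s)
      if (!length(cand)) return(NA_character_)
      if (length(cand) == 1L) cand else sample(cand, 1L)
    }, character(1), USE.NAMES = FALSE)
  }
  pat$receiving_facility_id <- NA_character_
  for (y in years) {
    ykey <- as.character(y)
    pool_low_all <- low_by_year[[ykey]] %||% character(0)
    pool_high_all <- high_by_year[[ykey]] %||% character(0)
    pool_na_all <- nonacute_by_year[[ykey]] %||% character(0)
    for (r in config$rtccs) {
      k <- paste(y, r, sep = "|")
      sel <- pat$transferred & pat$year == y & pat$rtcc_id == r
      i_na <- which(sel & pat$nonacute_recv)
      if (length(i_na)) {
        pool_na_r <- nonacute$facility_id[nonacute$year == y & nonacute$rtcc_id == r]
        if (length(pool_na_all)) {
          pat$receiving_facility_id[i_na] <-
            sample_receiving(pool_na_r, pool_na_all, pat$sending_facility_id[i_na])
        } else {
          pat$nonacute_recv[i_na] <- FALSE  # no non-acute facility exists
        }
      }
      i_sub <- which(sel & !pat$nonacute_recv & pat$suboptimal_intent)
      if (length(i_sub)) {
        pat$receiving_facility_id[i_sub] <-
          sample_receiving(low_set[[k]] %||% character(0), pool_low_all,
                           pat$sending_facility_id[i_sub])
      }
      i_opt <- which(sel & !pat$nonacute_recv & !pat$suboptimal_intent)
      if (length(i_opt)) {
        pool_h <- high_set[[k]] %||% character(0)
        pool_h_all <- pool_high_all
        if (!length(pool_h_all)) {  # no level I/II anywhere: forced low
          pool_h <- low_set[[k]] %||% character(0)
          pool_h_all <- pool_low_all
        }
        pat$receiving_facility_id[i_opt] <-
          sample_receiving(pool_h, pool_h_all, pat$sending_facility_id[i_opt])
      }
    }
  }
  pat$transferred[pat$transferred & is.na(pat$receiving_facility_id)] <- FALSE

  # keep receiving admissions inside the data horizon
  over <- which(pat$transferred & (pat$ed_date + pat$gap_days) > d1)
  if (length(over)) {
    pat$ed_date[over] <- d1 - pat$gap_days[over]
    pat$year[over] <- as.integer(format(pat$ed_date[over], "%Y"))
  }
  pat$recv_admit <- pat$ed_date + pat$gap_days
  pat$recv_year <- ifelse(pat$transferred,
                          as.integer(format(pat$recv_admit, "%Y")), NA_integer_)
  pat <- dplyr::left_join(
    pat,
    dplyr::select(fac_year, "facility_id", "year",
                  receiving_level = "level", receiving_facility_type = "facility_type"),
    by = c("receiving_facility_id" = "facility_id", "recv_year" = "year")
  )

  # receiving hospital course
  los <- rpois(n, config$los_lambda)
  pat$recv_discharge <- pat$recv_admit + los
  u_disp <- runif(n)
  recv_dispo <- ifelse(
    u_disp < config$p_die_receiving, "expired",
    ifelse(u_disp < config$p_die_receiving + config$p_transfer_third,
           "transfer to short-term general hospital",
           ifelse(u_disp < config$p_die_receiving + config$p_transfer_third +
                    config$p_post_acute,
                  "skilled nursing facility", "routine home")))
  surgery <- sample(names(config$surgery_probs), n, replace = TRUE,
                    prob = config$surgery_probs)

  # sending ED disposition, with excluded codes injected
  ed_dispo <- ifelse(pat$transferred, "transfer to short-term general hospital",
                     sample(c("admitted as inpatient", "routine home"), n,
                            replace = TRUE))
  pat$bad_dispo <- runif(n) < config$p_excluded_disposition
  if (any(pat$bad_dispo)) {
    ed_dispo[pat$bad_dispo] <- sample(default_excluded_ed_dispositions(),
                                      sum(pat$bad_dispo), replace = TRUE)
  }

  # ground truth: would this patient survive the full cascade?
  pat$retriaged_within_1day <- pat$transferred & !pat$interfacility
  truth_eligible <- pat$retriaged_within_1day & pat$low_sender &
    !pat$elective & !pat$nonacute_recv & !pat$bad_dispo &
    !pat$age_out & !pat$low_riss & !pat$burn_flag & pat$injury_dx
  true_label <- ifelse(
    !truth_eligible, NA_character_,
    ifelse(pat$receiving_level %in% low_trauma_levels(), "SUBOPTIMAL", "OPTIMAL"))

  ed <- tibble::tibble(
    rln = pat$rln, facility_id = pat$sending_facility_id, record_kind = "ED",
    admit_date = pat$ed_date, discharge_date = pat$ed_date,
    disposition = ed_dispo, admission_type = "EMERGENT",
    age = as.integer(pat$age), sex = pat$sex, race = pat$race,
    ethnicity = pat$ethnicity, insurance = pat$insurance,
    riss = as.integer(pat$riss), mechanism = pat$mechanism,
    body_region = pat$body_region, burn_flag = pat$burn_flag,
    injury_dx = pat$injury_dx, year = pat$year,
    surgery_class = NA_character_
  )
  it <- which(pat$transferred)
  ip <- tibble::tibble(
    rln = pat$rln[it], facility_id = pat$receiving_facility_id[it],
    record_kind = "INPATIENT", admit_date = pat$recv_admit[it],
    discharge_date = pat$recv_discharge[it], disposition = recv_dispo[it],
    admission_type = ifelse(pat$elective[it], "ELECTIVE", "EMERGENT"),
    age = as.integer(pat$age[it]), sex = pat$sex[it], race = pat$race[it],
    ethnicity = pat$ethnicity[it], insurance = pat$insurance[it],
    riss = as.integer(pat$riss[it]), mechanism = pat$mechanism[it],
    body_region = pat$body_region[it], burn_flag = pat$burn_flag[it],
    injury_dx = pat$injury_dx[it], year = pat$recv_year[it],
    surgery_class = surgery[it]
  )

  # readmission records for surviving true re-triages
  surv <- truth_eligible & recv_dispo != "expired"
  readmit <- surv & (runif(n) < config$p_readmit)
  gap_r <- 1L + floor(runif(n) * 70)
  ir <- which(readmit & (pat$recv_discharge + gap_r) <= d1)
  if (length(ir)) {
    ra_admit <- pat$recv_discharge[ir] + gap_r[ir]
    ra_year <- as.integer(format(ra_admit, "%Y"))
    ra_fac <- character(length(ir))
    for (j in seq_along(ir)) {
      pool <- stac$facility_id[stac$year == ra_year[j]]
      ra_fac[j] <- if (length(pool) == 1L) pool else sample(pool, 1L)
    }
    ra <- tibble::tibble(
      rln = pat$rln[ir], facility_id = ra_fac, record_kind = "INPATIENT",
      admit_date = ra_admit, discharge_date = ra_admit + rpois(length(ir), 3),
      disposition = "routine home", admission_type = "EMERGENT",
      age = as.integer(pat$age[ir]), sex = pat$sex[ir], race = pat$race[ir],
      ethnicity = pat$ethnicity[ir], insurance = pat$insurance[ir],
      riss = as.integer(pat$riss[ir]), mechanism = pat$mechanism[ir],
      body_region = pat$body_region[ir], burn_flag = pat$burn_flag[ir],
      injury_dx = pat$injury_dx[ir], year = ra_year,
      surgery_class = sample(names(config$surgery_probs), length(ir),
                             replace = TRUE, prob = config$surgery_probs)
    )
    ip <- dplyr::bind_rows(ip, ra)
  }

  # missing RLNs (explicit NA, never an empty string)
  ed$rln[runif(nrow(ed)) < config$p_missing_rln] <- NA_character_
  ip$rln[runif(nrow(ip)) < config$p_missing_rln_inpatient] <- NA_character_

  # verbatim duplicate rows, inserted adjacent to the original
  dup_rows <- function(df, p) {
    k <- as.integer(runif(nrow(df)) < p)
    df[rep(seq_len(nrow(df)), times = 1L + k), , drop = FALSE]
  }
  ed <- dup_rows(ed, config$p_duplicate)
  ip <- dup_rows(ip, config$p_duplicate)

  truth <- tibble::tibble(
    patient_id = pat$patient_id, rln = pat$rln,
    sending_facility_id = pat$sending_facility_id,
    receiving_facility_id = pat$receiving_facility_id,
    year = pat$year, rtcc_id = pat$rtcc_id, lemsa_id = pat$lemsa_id,
    gap_days = pat$gap_days,
    transferred = pat$transferred,
    retriaged_within_1day = pat$retriaged_within_1day,
    true_retriage = truth_eligible,
    true_label = true_label,
    receiving_level = pat$receiving_level
  )
  list(ed = ed, inpatient = ip, truth = truth)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
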