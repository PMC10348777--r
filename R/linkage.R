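# Record cleaning, encounter linkage, and the inclusion/exclusion cascade.
#
# Linkage is deterministic: exact duplicates are collapsed, ED and inpatient
# records are paired on equal non-missing RLNs with a receiving admission 0-1
# days after the sending ED discharge, and the cohort is then carved out by a
# fixed, fully ledgered sequence of rules. Pair formation itself is purely
# identifier/date based; every facility-level criterion lives in the cascade
# so that each input ED encounter ends in exactly one of: cohort pair,
# under-triaged stratum, or excluded-with-reason.

#' Collapse exact duplicate records
#'
#' Rows identical on (`rln`, `facility_id`, `record_kind`, `admit_date`,
#' `discharge_date`) collapse to their first occurrence; all other order is
#' preserved. Missing RLNs compare equal to each other, mirroring how
#' administrative deduplication treats records without identifiers.
#'
#' @param records Encounter record tibble.
#' @return `list(records = <deduplicated tibble>, n_removed = <int>)`.
#' @export
deduplicate_records <- function(records) {
  key <- c("rln", "facility_id", "record_kind", "admit_date", "discharge_date")
  stopifnot(all(key %in% names(records)))
  dup <- duplicated(records[key])
  list(records = records[!dup, , drop = FALSE], n_removed = sum(dup))
}

#' Pair sending ED encounters with receiving encounters
#'
#' A candidate receiving record shares the ED record's non-missing RLN, sits
#' at a different facility, and has `gap_days = admit_date -
#' ed_discharge_date >= 0`. Candidates at gap 0-1 form re-triage pairs;
#' an ED record whose only candidates are at gap >= 2 becomes an
#' interfacility-transfer candidate instead. When several receiving records
#' qualify, the earliest admission wins, ties broken by lexicographic
#' facility id. Records lacking an RLN on either side can never pair.
#'
#' @param ed_records,inpatient_records Deduplicated record tibbles.
#' @return List of tibbles: `pairs` (sending fields plus `receiving_*` fields
#'   and `gap_days`), `interfacility` (same shape, gap >= 2), and
#'   `unpaired_ed` (ED rows with no candidate at all).
#' @export
link_encounter_pairs <- function(ed_records, inpatient_records) {
  ed <- tibble::as_tibble(ed_records)
  ip <- tibble::as_tibble(inpatient_records)
  ed$.ed_id <- seq_len(nrow(ed))

  recv <- ip[!is.na(ip$rln),
             c("rln", "facility_id", "admit_date", "discharge_date",
               "disposition", "admission_type", "surgery_class")]
  names(recv) <- c("rln", "receiving_facility_id", "receiving_admit_date",
                   "receiving_discharge_date", "receiving_disposition",
                   "receiving_admission_type", "receiving_surgery_class")

  cand <- dplyr::inner_join(ed[!is.na(ed$rln), ], recv, by = "rln",
                            relationship = "many-to-many")
  cand$gap_days <- as.integer(cand$receiving_admit_date - cand$discharge_date)
  cand <- cand[cand$gap_days >= 0L &
                 cand$receiving_facility_id != cand$facility_id, , drop = FALSE]
  cand <- cand[order(cand$.ed_id, cand$receiving_admit_date,
                     cand$receiving_facility_id), , drop = FALSE]

  pick_first <- function(df) df[!duplicated(df$.ed_id), , drop = FALSE]
  pairs <- pick_first(cand[cand$gap_days <= 1L, , drop = FALSE])
  inter <- pick_first(cand[cand$gap_days >= 2L, , drop = FALSE])
  inter <- inter[!(inter$.ed_id %in% pairs$.ed_id), , drop = FALSE]
  unpaired <- ed[!(ed$.ed_id %in% c(pairs$.ed_id, inter$.ed_id)), , drop = FALSE]

  list(pairs = tibble::as_tibble(pairs),
       interfacility = tibble::as_tibble(inter),
       unpaired_ed = tibble::as_tibble(unpaired))
}

# resolve facility attributes for a vector of (facility_id, year);
# unknown facility ids are a hard error naming the offender
resolve_facility <- function(directory, facility_id, year, prefix) {
  unknown <- setdiff(unique(facility_id[!is.na(facility_id)]),
                     unique(directory$facility_id))
  if (length(unknown)) {
    stop("unknown facility_id: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  d <- directory[, c("facility_id", "year", "level", "facility_type",
                     "lemsa_id", "rtcc_id")]
  names(d) <- c("facility_id", "year", paste0(prefix, "_level"),
                paste0(prefix, "_facility_type"), paste0(prefix, "_lemsa_id"),
                paste0(prefix, "_rtcc_id"))
  # clamp out-of-horizon years to the nearest designation year
  yr <- pmin(pmax(year, min(directory$year)), max(directory$year))
  q <- tibble::tibble(facility_id = facility_id, year = yr)
  res <- dplyr::left_join(q, d, by = c("facility_id", "year"))
  miss <- !is.na(facility_id) & is.na(res[[paste0(prefix, "_level")]])
  if (any(miss)) {
    stop("no annual designation for facility_id ",
         paste(unique(facility_id[miss]), collapse = ", "), call. = FALSE)
  }
  res[, -(1:2), drop = FALSE]
}

#' Apply the inclusion/exclusion cascade with an audit ledger
#'
#' Rules are applied sequentially, each removal attributed to the first rule
#' that fires, in this fixed order: age 18-89; injury diagnosis present;
#' injury severity score > 15 (strict); no burn injury; sending facility is a
#' short-term acute-care hospital; receiving admission not elective;
#' receiving facility is a short-term acute-care hospital; sending ED
#' disposition not in the excluded set (expired / left against medical advice
#' / rehabilitation with planned readmission); sending center not a level
#' I/II trauma center (direct field triage). Surviving pairs form the
#' re-triage cohort; surviving ED encounters without a 0-1 day pair form the
#' under-triaged-not-transferred stratum (interfacility candidates are kept
#' there, flagged).
#'
#' Trauma levels are resolved in the calendar year of each record's own date
#' (sending discharge year, receiving admission year).
#'
#' @param pairs,unpaired_ed,interfacility Output of [link_encounter_pairs()]
#'   (pass the list elements).
#' @param directory Hospital directory resolving every facility id; an
#'   unknown id is an error.
#' @param excluded_dispositions Sending-ED dispositions that exclude, default
#'   [default_excluded_ed_dispositions()].
#' @return List: `cohort` (pairs with sending/receiving levels attached),
#'   `undertriaged` (qualifying unpaired ED encounters, `is_interfacility`
#'   flagged), `ledger` (tibble `rule`, `n_removed`, `n_remaining`; first row
#'   is the input count).
#' @export
apply_inclusion_exclusion <- function(pairs, unpaired_ed, directory,
                                      interfacility = NULL,
                                      excluded_dispositions =
                                        default_excluded_ed_dispositions()) {
  pairs <- tibble::as_tibble(pairs)
  unpaired <- tibble::as_tibble(unpaired_ed)
  unpaired$is_interfacility <- FALSE
  if (!is.null(interfacility) && nrow(interfacility)) {
    inter <- tibble::as_tibble(interfacility)
    inter$is_interfacility <- TRUE
    keep <- intersect(names(unpaired), names(inter))
    unpaired <- dplyr::bind_rows(unpaired[keep], inter[keep])
  }
  pairs$.is_pair <- TRUE
  unpaired$.is_pair <- FALSE
  all_rows <- dplyr::bind_rows(pairs, unpaired)
  n0 <- nrow(all_rows)

  snd <- resolve_facility(directory, all_rows$facility_id,
                          as.integer(format(all_rows$discharge_date, "%Y")),
                          "sending")
  all_rows <- dplyr::bind_cols(all_rows, snd)
  if (any(all_rows$.is_pair)) {
    rcv_year <- ifelse(all_rows$.is_pair,
                       as.integer(format(all_rows$receiving_admit_date, "%Y")),
                       NA_integer_)
    rcv <- resolve_facility(directory, ifelse(all_rows$.is_pair,
                                              all_rows$receiving_facility_id,
                                              NA_character_),
                            rcv_year, "receiving")
    all_rows <- dplyr::bind_cols(all_rows, rcv)
  } else {
    all_rows$receiving_level <- NA_character_
    all_rows$receiving_facility_type <- NA_character_
    all_rows$receiving_lemsa_id <- NA_character_
    all_rows$receiving_rtcc_id <- NA_character_
  }

  rules <- list(
    age_18_89 = function(d) d$age < 18 | d$age > 89,
    injury_diagnosis = function(d) !d$injury_dx,
    riss_gt_15 = function(d) d$riss <= 15,
    burn_injury = function(d) d$burn_flag,
    sending_not_short_term_acute = function(d)
      d$sending_facility_type != "SHORT_TERM_ACUTE",
    elective_admission = function(d)
      (d$.is_pair & d$receiving_admission_type == "ELECTIVE") |
      (!d$.is_pair & d$admission_type == "ELECTIVE"),
    receiving_not_short_term_acute = function(d)
      d$.is_pair & d$receiving_facility_type != "SHORT_TERM_ACUTE",
    excluded_sending_disposition = function(d)
      d$disposition %in% excluded_dispositions,
    field_triage_direct_to_high_level = function(d)
      d$sending_level %in% high_trauma_levels()
  )

  ledger <- tibble::tibble(rule = "input", n_removed = 0L, n_remaining = n0)
  remaining <- all_rows
  for (rn in names(rules)) {
    drop <- rules[[rn]](remaining)
    drop[is.na(drop)] <- FALSE
    remaining <- remaining[!drop, , drop = FALSE]
    ledger <- dplyr::bind_rows(
      ledger,
      tibble::tibble(rule = rn, n_removed = sum(drop),
                     n_remaining = nrow(remaining)))
  }

  cohort <- remaining[remaining$.is_pair, , drop = FALSE]
  undertriaged <- remaining[!remaining$.is_pair, , drop = FALSE]
  cohort$.is_pair <- NULL
  undertriaged$.is_pair <- NULL
  drop_recv <- grep("^receiving_", names(undertriaged))
  if (length(drop_recv)) undertriaged <- undertriaged[, -drop_recv, drop = FALSE]

  list(cohort = tibble::as_tibble(cohort),
       undertriaged = tibble::as_tibble(undertriaged),
       ledger = ledger)
}

#' Run dedup + linkage + cascade in one step
#'
#' @param ed,inpatient Raw record tibbles (duplicates allowed).
#' @param directory Hospital directory.
#' @param ... Passed to [apply_inclusion_exclusion()].
#' @return The [apply_inclusion_exclusion()] list, plus `n_duplicates_removed`
#'   (named by record file) and the linkage intermediates.
#' @export
link_cohort <- function(ed, inpatient, directory, ...) {
  ded <- deduplicate_records(ed)
  dip <- deduplicate_records(inpatient)
  lk <- link_encounter_pairs(ded$records, dip$records)
  out <- apply_inclusion_exclusion(lk$pairs, lk$unpaired_ed, directory,
                                   interfacility = lk$interfacility, ...)
  out$n_duplicates_removed <- c(ed = ded$n_removed, inpatient = dip$n_removed)
  out$linkage <- lk
  out
}
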