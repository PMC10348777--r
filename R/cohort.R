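# Optimality labeling, covariate encoding, and hierarchical rate tables.

#' Label re-triage optimality
#'
#' A re-triage is OPTIMAL if and only if the receiving center is a level I/II
#' trauma center in the year of the receiving admission; distance is never
#' consulted. Everything else (a second nontrauma or level III/IV center) is
#' SUBOPTIMAL.
#'
#' @param pairs Cohort pairs from [apply_inclusion_exclusion()]; sending and
#'   receiving levels are resolved from `directory` if absent.
#' @param directory Hospital directory (facility-year rows).
#' @return The pairs tibble with `event_id`, `sending_level`,
#'   `receiving_level`, `lemsa_id`, `rtcc_id` (of the sending center) and
#'   `optimality` columns; an unresolvable level is an error.
#' @export
label_optimality <- function(pairs, directory) {
  ev <- tibble::as_tibble(pairs)
  if (nrow(ev) == 0L) {
    ev$optimality <- character(0)
    return(ev)
  }
  if (is.null(ev$receiving_level)) {
    rcv <- resolve_facility(directory, ev$receiving_facility_id,
                            as.integer(format(ev$receiving_admit_date, "%Y")),
                            "receiving")
    ev <- dplyr::bind_cols(ev, rcv)
  }
  if (is.null(ev$sending_level)) {
    snd <- resolve_facility(directory, ev$facility_id,
                            as.integer(format(ev$discharge_date, "%Y")),
                            "sending")
    ev <- dplyr::bind_cols(ev, snd)
  }
  if (anyNA(ev$receiving_level)) {
    stop("unresolvable receiving trauma level for ",
         sum(is.na(ev$receiving_level)), " pair(s)", call. = FALSE)
  }
  ev$event_id <- sprintf("E%06d", seq_len(nrow(ev)))
  ev$sending_facility_id <- ev$facility_id
  ev$lemsa_id <- ev$sending_lemsa_id
  ev$rtcc_id <- ev$sending_rtcc_id
  ev$optimality <- ifelse(ev$receiving_level %in% high_trauma_levels(),
                          "OPTIMAL", "SUBOPTIMAL")
  ev
}

band_age <- function(age) {
  cut(age, breaks = c(18, 25, 35, 45, 55, 65, 75, 85, 90),
      labels = retriage_vocabulary()$age_band, right = FALSE)
}

map_codes <- function(x, map, what) {
  out <- unname(map[tolower(x)])
  if (anyNA(out[!is.na(x)])) {
    bad <- unique(x[is.na(out) & !is.na(x)])
    stop("unmapped ", what, " code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Encode raw administrative covariates into the analysis vocabularies
#'
#' Deterministic mapping: age into the eight analysis bands (18-24 reference,
#' then 10-year intervals, capped at 85-89 by the inclusion rule), injury
#' severity into 16-25 vs >25 (a score of exactly 25 stays in the reference
#' band), raw race/insurance/mechanism codes through `maps` (unmapped codes
#' are an error listing the offenders), and multi-flag body regions through
#' the fixed precedence TBI > torso > other head/face/neck > extremities >
#' other.
#'
#' @param events Labeled events (or any record tibble with the raw fields).
#' @param maps Raw-code maps, default [default_code_maps()].
#' @return `events` with `age_band`, `riss_band` added and `race`,
#'   `insurance`, `mechanism`, `body_region`, `ethnicity`, `sex` replaced by
#'   coded values.
#' @export
encode_covariates <- function(events, maps = default_code_maps()) {
  ev <- tibble::as_tibble(events)
  ev$age_band <- as.character(band_age(ev$age))
  if (anyNA(ev$age_band)) {
    stop("age outside the 18-89 analysis range; apply the inclusion cascade first",
         call. = FALSE)
  }
  ev$riss_band <- ifelse(ev$riss > 25, ">25", "16-25")
  ev$race <- map_codes(ev$race, maps$race, "race")
  ev$insurance <- map_codes(ev$insurance, maps$insurance, "insurance")
  ev$mechanism <- map_codes(ev$mechanism, maps$mechanism, "mechanism")
  ev$sex <- toupper(ev$sex)
  ev$ethnicity <- toupper(ev$ethnicity)
  prec <- body_region_precedence()
  pick_region <- function(s) {
    parts <- strsplit(s, ";", fixed = TRUE)[[1]]
    bad <- setdiff(parts, prec)
    if (length(bad)) {
      stop("unmapped body_region code(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    prec[min(match(parts, prec))]
  }
  ev$body_region <- vapply(ev$body_region, pick_region, character(1),
                           USE.NAMES = FALSE)
  ev
}

#' Aggregate suboptimal re-triage counts and rates
#'
#' Counts and rates per aggregation unit, per year and pooled (`year =
#' "ALL"`). Units with zero re-triages keep `rate = NA` (an undefined rate is
#' never reported as zero). `share_of_state_suboptimal` divides each unit's
#' suboptimal count by the state total for the same year stratum.
#'
#' @param events Labeled events ([label_optimality()]).
#' @param level One of `"STATE"`, `"RTCC"`, `"LEMSA"`, `"CENTER"`.
#' @param directory Optional; when supplied, units of the requested level
#'   with zero re-triages are included (for `"CENTER"`, sending-eligible
#'   centers only: short-term acute, nontrauma/III/IV that year).
#' @return A tibble (`aggregation_level`, `unit_id`, `year`, `n_retriage`,
#'   `n_suboptimal`, `rate`, `share_of_state_suboptimal`); `year` is
#'   character ("2009", ..., "ALL").
#' @export
aggregate_rates <- function(events, level = c("STATE", "RTCC", "LEMSA", "CENTER"),
                            directory = NULL) {
  level <- match.arg(level)
  unit_col <- switch(level, STATE = NULL, RTCC = "rtcc_id", LEMSA = "lemsa_id",
                     CENTER = "sending_facility_id")
  ev <- tibble::as_tibble(events)
  ev$.unit <- if (is.null(unit_col)) "STATE" else ev[[unit_col]]
  ev$.year <- as.character(ev$year)
  ev$.sub <- ev$optimality == "SUBOPTIMAL"

  count_block <- function(d, yr_label) {
    d |>
      dplyr::group_by(unit_id = .data$.unit) |>
      dplyr::summarise(n_retriage = dplyr::n(),
                       n_suboptimal = sum(.data$.sub), .groups = "drop") |>
      dplyr::mutate(year = yr_label)
  }
  per_year <- ev |>
    dplyr::group_by(.data$.year) |>
    dplyr::group_map(~ count_block(.x, .y$.year)) |>
    dplyr::bind_rows()
  pooled <- count_block(ev, "ALL")
  tab <- dplyr::bind_rows(per_year, pooled)

  # enumerate zero-retriage units from the directory
  if (!is.null(directory) && level != "STATE") {
    d <- directory
    if (level == "CENTER") {
      d <- d[d$facility_type == "SHORT_TERM_ACUTE" &
               d$level %in% low_trauma_levels(), ]
      units_year <- tibble::tibble(unit_id = d$facility_id,
                                   year = as.character(d$year))
    } else {
      col <- if (level == "RTCC") "rtcc_id" else "lemsa_id"
      units_year <- tibble::tibble(unit_id = d[[col]],
                                   year = as.character(d$year))
    }
    units_year <- dplyr::distinct(units_year)
    units_all <- dplyr::distinct(tibble::tibble(unit_id = units_year$unit_id,
                                                year = "ALL"))
    grid <- dplyr::bind_rows(units_year, units_all)
    tab <- dplyr::left_join(grid, tab, by = c("unit_id", "year")) |>
      dplyr::mutate(n_retriage = dplyr::coalesce(.data$n_retriage, 0L),
                    n_suboptimal = dplyr::coalesce(.data$n_suboptimal, 0L))
  }

  state_sub <- ev |>
    dplyr::group_by(year = .data$.year) |>
    dplyr::summarise(.state_sub = sum(.data$.sub), .groups = "drop") |>
    dplyr::bind_rows(tibble::tibble(year = "ALL", .state_sub = sum(ev$.sub)))

  tab |>
    dplyr::left_join(state_sub, by = "year") |>
    dplyr::mutate(
      aggregation_level = level,
      rate = ifelse(.data$n_retriage > 0,
                    .data$n_suboptimal / .data$n_retriage, NA_real_),
      share_of_state_suboptimal =
        ifelse(!is.na(.data$.state_sub) & .data$.state_sub > 0,
               .data$n_suboptimal / .data$.state_sub, NA_real_),
      .state_sub = NULL
    ) |>
    dplyr::select("aggregation_level", "unit_id", "year", "n_retriage",
                  "n_suboptimal", "rate", "share_of_state_suboptimal") |>
    dplyr::arrange(.data$unit_id, .data$year)
}

#' Format a proportion as a percentage for report parity
#'
#' @param x Proportion in `[0, 1]` (NA allowed).
#' @param digits Decimal places, default 1 (report convention).
#' @return Numeric percentage rounded to `digits`.
#' @export
as_report_percent <- function(x, digits = 1) round(100 * x, digits)

#' Annual state rate and per-RTCC suboptimal shares
#'
#' @param events Labeled events.
#' @return List: `state` (per-year `n_retriage`, `n_suboptimal`, `rate`),
#'   `rtcc_share` (per year and RTCC, the share of that year's statewide
#'   suboptimal count; shares sum to 1 within a year with any suboptimal
#'   re-triage).
#' @export
annual_trend <- function(events) {
  ev <- tibble::as_tibble(events)
  state <- ev |>
    dplyr::group_by(year = .data$year) |>
    dplyr::summarise(n_retriage = dplyr::n(),
                     n_suboptimal = sum(.data$optimality == "SUBOPTIMAL"),
                     .groups = "drop") |>
    dplyr::mutate(rate = .data$n_suboptimal / .data$n_retriage)
  rtcc_share <- ev |>
    dplyr::filter(.data$optimality == "SUBOPTIMAL") |>
    dplyr::count(year = .data$year, rtcc_id = .data$rtcc_id,
                 name = "n_suboptimal") |>
    dplyr::group_by(.data$year) |>
    dplyr::mutate(share = .data$n_suboptimal / sum(.data$n_suboptimal)) |>
    dplyr::ungroup()
  list(state = state, rtcc_share = rtcc_share)
}

#' Sending-center level summary
#'
#' Denominators are the sending-eligible centers (short-term acute,
#' nontrauma/III/IV) operating in each year -- pooled rows use centers
#' eligible in at least one year. Reports the fraction of centers with at
#' least one suboptimal re-triage and the fraction whose center-level
#' suboptimal rate is >= 40% (inclusive; centers with no re-triage have an
#' undefined rate and never enter that numerator).
#'
#' @param events Labeled events.
#' @param directory Hospital directory.
#' @return List: `per_center` (per center-year and pooled counts/rates) and
#'   `by_year` (per-year and `"ALL"` fractions).
#' @export
center_level_summary <- function(events, directory) {
  ev <- tibble::as_tibble(events)
  elig <- directory[directory$facility_type == "SHORT_TERM_ACUTE" &
                      directory$level %in% low_trauma_levels(),
                    c("facility_id", "year")]
  per_center <- aggregate_rates(ev, level = "CENTER", directory = directory)
  frac_block <- function(yr_label, denom_ids) {
    pc <- per_center[per_center$year == yr_label &
                       per_center$unit_id %in% denom_ids, ]
    n_elig <- length(denom_ids)
    n_any <- sum(pc$n_suboptimal >= 1L)
    n_ge40 <- sum(pc$n_retriage > 0L & pc$rate >= 0.4, na.rm = TRUE)
    tibble::tibble(year = yr_label, n_eligible_centers = n_elig,
                   n_with_suboptimal = n_any,
                   frac_with_suboptimal = ifelse(n_elig > 0, n_any / n_elig, NA_real_),
                   n_ge_40pct = n_ge40,
                   frac_ge_40pct = ifelse(n_elig > 0, n_ge40 / n_elig, NA_real_))
  }
  yrs <- sort(unique(elig$year))
  by_year <- dplyr::bind_rows(
    lapply(yrs, function(y) frac_block(as.character(y),
                                       unique(elig$facility_id[elig$year == y]))),
    frac_block("ALL", unique(elig$facility_id))
  )
  list(per_center = per_center, by_year = by_year)
}

#' Cohort characteristics table
#'
#' One row per covariate level with re-triage, suboptimal and optimal counts
#' and within-stratum percentages (denominators are the stratum totals).
#'
#' @param events Labeled, encoded events.
#' @param digits Percent decimals, default 1.
#' @return Tidy tibble: `variable`, `level`, `n`, `pct`, `n_suboptimal`,
#'   `pct_suboptimal`, `n_optimal`, `pct_optimal`.
#' @export
build_table1 <- function(events, digits = 1) {
  ev <- tibble::as_tibble(events)
  vars <- c("age_band", "sex", "race", "ethnicity", "insurance", "mechanism",
            "body_region", "riss_band", "rtcc_id")
  vars <- intersect(vars, names(ev))
  n_all <- nrow(ev)
  n_sub <- sum(ev$optimality == "SUBOPTIMAL")
  n_opt <- n_all - n_sub
  blocks <- lapply(vars, function(v) {
    ev |>
      dplyr::count(level = .data[[v]], .data$optimality) |>
      tidyr::pivot_wider(names_from = "optimality", values_from = "n",
                         values_fill = 0L) |>
      dplyr::mutate(variable = v)
  })
  tab <- dplyr::bind_rows(blocks)
  if (!"SUBOPTIMAL" %in% names(tab)) tab$SUBOPTIMAL <- 0L
  if (!"OPTIMAL" %in% names(tab)) tab$OPTIMAL <- 0L
  tab |>
    dplyr::transmute(
      variable = .data$variable, level = .data$level,
      n = .data$SUBOPTIMAL + .data$OPTIMAL,
      pct = as_report_percent(.data$n / n_all, digits),
      n_suboptimal = .data$SUBOPTIMAL,
      pct_suboptimal = if (n_sub > 0) as_report_percent(.data$SUBOPTIMAL / n_sub, digits) else NA_real_,
      n_optimal = .data$OPTIMAL,
      pct_optimal = if (n_opt > 0) as_report_percent(.data$OPTIMAL / n_opt, digits) else NA_real_
    )
}
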