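# Hospital course at the receiving center and 2x2 comparisons.

#' Collapse a receiving discharge disposition into four groups
#'
#' @param raw_code Character vector of raw disposition codes (matched
#'   case-insensitively).
#' @param map Named raw -> group map, default [default_disposition_map()].
#' @return Character vector in {HOME, DIED, SHORT_TERM_ACUTE, POST_ACUTE};
#'   an unmapped code is an error naming it.
#' @export
collapse_disposition <- function(raw_code, map = default_disposition_map()) {
  map_codes(raw_code, map, "disposition")
}

#' Receiving length of stay in days
#'
#' @param admit_date,discharge_date Dates; discharge before admission is an
#'   error. Same-day discharge is 0 days.
#' @return Integer days.
#' @export
compute_los <- function(admit_date, discharge_date) {
  los <- as.integer(discharge_date - admit_date)
  if (any(los < 0, na.rm = TRUE)) {
    stop("discharge_date before admit_date", call. = FALSE)
  }
  los
}

#' Flag readmissions at 10/30/60 days
#'
#' A readmission is any later inpatient encounter with the same RLN at any
#' short-term acute-care facility whose admission falls 1 to W days after
#' the event's receiving discharge (inclusive of day W, exclusive of day 0:
#' a same-day transfer is not a readmission). Patients who died before
#' discharge get `NA` flags and are excluded from readmission denominators.
#'
#' @param events Labeled events carrying `event_id`, `rln`,
#'   `receiving_discharge_date` and `receiving_disposition`.
#' @param inpatient_records All (deduplicated) inpatient records.
#' @param directory Hospital directory (to restrict candidate facilities to
#'   short-term acute care).
#' @param windows Integer day windows, default `c(10, 30, 60)`.
#' @param disposition_map Map used to recognise in-hospital death.
#' @return `events` with logical `readmitted_<W>` columns.
#' @export
flag_readmissions <- function(events, inpatient_records, directory,
                              windows = c(10, 30, 60),
                              disposition_map = default_disposition_map()) {
  ev <- tibble::as_tibble(events)
  ip <- tibble::as_tibble(inpatient_records)
  stac_ids <- unique(directory$facility_id[
    directory$facility_type == "SHORT_TERM_ACUTE"])
  ip <- ip[!is.na(ip$rln) & ip$facility_id %in% stac_ids,
           c("rln", "admit_date")]
  died <- collapse_disposition(ev$receiving_disposition, disposition_map) == "DIED"

  cand <- dplyr::inner_join(
    tibble::tibble(event_id = ev$event_id, rln = ev$rln,
                   from = ev$receiving_discharge_date),
    ip, by = "rln", relationship = "many-to-many")
  cand$gap <- as.integer(cand$admit_date - cand$from)
  cand <- cand[cand$gap >= 1L, , drop = FALSE]
  for (w in windows) {
    hit <- unique(cand$event_id[cand$gap <= w])
    flag <- ev$event_id %in% hit
    flag[died] <- NA
    ev[[paste0("readmitted_", w)]] <- flag
  }
  ev
}

#' Odds ratio of a 2x2 table with a Woolf confidence interval
#'
#' `OR = (a d) / (b c)`. Any zero cell triggers the Haldane-Anscombe
#' correction (0.5 added to every cell), flagged in the result. A row or
#' column summing to zero is an error.
#'
#' @param a,b,c,d Nonnegative integer cells, laid out as
#'   `matrix(c(a, c, b, d), 2)`: rows = exposure, columns = outcome.
#' @param conf_level Confidence level, default 0.95.
#' @return List: `or`, `ci_lower`, `ci_upper`, `conf_level`, `corrected`.
#' @export
odds_ratio_2x2 <- function(a, b, c, d, conf_level = 0.95) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != floor(cells))) {
    stop("cells must be nonnegative integers", call. = FALSE)
  }
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) {
    stop("a row or column of the 2x2 table sums to zero", call. = FALSE)
  }
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  a <- cells[1]; b <- cells[2]; cc <- cells[3]; d <- cells[4]
  log_or <- log(a * d / (b * cc))
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(or = exp(log_or),
       ci_lower = exp(log_or - z * se),
       ci_upper = exp(log_or + z * se),
       conf_level = conf_level,
       corrected = corrected)
}

#' Pearson chi-square test of a contingency table
#'
#' Pearson statistic without continuity correction, df = (r-1)(c-1).
#' Degenerate tables (a zero row/column margin, hence a zero expected count)
#' are an error.
#'
#' @param contingency Matrix (or table) of nonnegative counts.
#' @return List: `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square_test <- function(contingency) {
  m <- as.matrix(contingency)
  if (any(m < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("degenerate contingency table: a margin sums to zero", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), expected = ht$expected)
}

#' Surgery rates by region, class, and optimality
#'
#' Counts and within-stratum percentages of receiving-center surgery classes
#' (diagnostic / minor therapeutic / major therapeutic) per RTCC, separately
#' for suboptimal and optimal re-triages. Percent denominators are the
#' stratum totals (all suboptimal re-triages, all optimal re-triages);
#' an empty stratum yields zero counts and `NA` percents.
#'
#' @param events Labeled events with a `surgery_class` column (the synthetic
#'   generator assigns classes directly; procedure-code classification is
#'   upstream of this package).
#' @param digits Percent decimals, default 1.
#' @return Tidy tibble: `rtcc_id`, `surgery_class`, `optimality`, `n`,
#'   `pct`, `stratum_total`.
#' @export
surgery_rate_table <- function(events, digits = 1) {
  ev <- tibble::as_tibble(events)
  cls_col <- if ("surgery_class" %in% names(ev)) "surgery_class"
             else "receiving_surgery_class"
  ev$.class <- ev[[cls_col]]
  totals <- ev |>
    dplyr::count(.data$optimality, name = "stratum_total")
  classes <- c("DIAGNOSTIC", "MINOR_THERAPEUTIC", "MAJOR_THERAPEUTIC")
  grid <- tidyr::expand_grid(
    rtcc_id = sort(unique(ev$rtcc_id)),
    surgery_class = classes,
    optimality = c("SUBOPTIMAL", "OPTIMAL"))
  ev |>
    dplyr::filter(.data$.class %in% classes) |>
    dplyr::count(.data$rtcc_id, surgery_class = .data$.class,
                 .data$optimality) |>
    dplyr::right_join(grid, by = c("rtcc_id", "surgery_class", "optimality")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::left_join(totals, by = "optimality") |>
    dplyr::mutate(
      stratum_total = dplyr::coalesce(.data$stratum_total, 0L),
      pct = ifelse(.data$stratum_total > 0,
                   as_report_percent(.data$n / .data$stratum_total, digits),
                   NA_real_)) |>
    dplyr::arrange(.data$surgery_class, .data$rtcc_id,
                   dplyr::desc(.data$optimality))
}

#' Hospital-course comparison between suboptimal and optimal re-triages
#'
#' Assembles the receiving hospital-course variables (disposition group,
#' length of stay, readmission flags), compares each categorical variable
#' with a chi-square test, and reports crude odds ratios for onward transfer
#' to a third short-term acute hospital and for readmission among survivors.
#'
#' @param events Labeled events with receiving dates/disposition and (after
#'   [flag_readmissions()]) readmission flags.
#' @param disposition_map See [collapse_disposition()].
#' @return List: `events` (with `los_days`, `disposition_group`),
#'   `disposition_table`, `los_summary`, `or_transfer_third`, and
#'   `or_readmitted_<W>` entries when the flags are present.
#' @export
compare_hospital_course <- function(events,
                                    disposition_map = default_disposition_map()) {
  ev <- tibble::as_tibble(events)
  ev$los_days <- compute_los(ev$receiving_admit_date, ev$receiving_discharge_date)
  ev$disposition_group <- collapse_disposition(ev$receiving_disposition,
                                               disposition_map)
  sub <- ev$optimality == "SUBOPTIMAL"
  disp_tab <- table(ev$disposition_group, ev$optimality)
  los_summary <- ev |>
    dplyr::group_by(.data$optimality) |>
    dplyr::summarise(median_los = median(.data$los_days),
                     mean_los = mean(.data$los_days), .groups = "drop")
  third <- ev$disposition_group == "SHORT_TERM_ACUTE"
  out <- list(events = ev, disposition_table = disp_tab,
              los_summary = los_summary)
  out$or_transfer_third <- odds_ratio_2x2(
    sum(third & sub), sum(!third & sub),
    sum(third & !sub), sum(!third & !sub))
  for (col in grep("^readmitted_", names(ev), value = TRUE)) {
    f <- ev[[col]]
    keep <- !is.na(f)  # survivors to discharge only
    if (sum(f[keep] & sub[keep]) + sum(f[keep] & !sub[keep]) == 0) next
    out[[paste0("or_", col)]] <- odds_ratio_2x2(
      sum(f[keep] & sub[keep]), sum(!f[keep] & sub[keep]),
      sum(f[keep] & !sub[keep]), sum(!f[keep] & !sub[keep]))
  }
  out
}
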