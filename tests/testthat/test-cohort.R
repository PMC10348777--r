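test_that("optimality depends only on the receiving level, never distance", {
  dir <- test_directory()
  pairs <- dplyr::bind_rows(
    make_record(rln = "R1"),                          # NONTRAUMA sender
    make_record(rln = "R2", facility_id = "A02"),     # LEVEL_III sender
    make_record(rln = "R3", facility_id = "A02"))
  ip <- dplyr::bind_rows(
    make_inpatient(rln = "R1", facility_id = "B02"),          # LEVEL_II
    make_inpatient(rln = "R2", facility_id = "A03",
                   admit_date = as.Date("2018-05-01")),       # LEVEL_IV, gap 0
    make_inpatient(rln = "R3", facility_id = "C02"))          # LEVEL_I, ~350 mi away
  res <- link_cohort(pairs, ip, dir)
  ev <- label_optimality(res$cohort, dir)
  lab <- setNames(ev$optimality, ev$rln)
  expect_equal(unname(lab[c("R1", "R2", "R3")]),
               c("OPTIMAL", "SUBOPTIMAL", "OPTIMAL"))
})

test_that("covariate encoding maps bands and raw codes deterministically", {
  ev <- make_record(age = 18L, riss = 25L, insurance = "hmo-unspecified",
                    race = "african american", mechanism = "motor vehicle traffic",
                    body_region = "TORSO;EXTREMITIES")
  enc <- encode_covariates(ev)
  expect_equal(enc$age_band, "18-24")
  expect_equal(enc$riss_band, "16-25")   # 25 stays in the reference band
  expect_equal(enc$insurance, "MANAGED_CARE_UNSPECIFIED")
  expect_equal(enc$race, "BLACK")
  expect_equal(enc$mechanism, "ALL_TRANSPORT")
  expect_equal(enc$body_region, "TORSO") # torso outranks extremities

  enc2 <- encode_covariates(make_record(age = 84L, riss = 26L,
                                        insurance = "blue cross blue shield",
                                        body_region = "TBI;TORSO"))
  expect_equal(enc2$age_band, "75-84")
  expect_equal(enc2$riss_band, ">25")
  expect_equal(enc2$insurance, "PRIVATE")
  expect_equal(enc2$body_region, "TBI")

  expect_equal(encode_covariates(make_record(age = 85L))$age_band, "85-89")
  expect_error(encode_covariates(make_record(insurance = "gold plan")),
               "gold plan")
})

make_events <- function(rtcc, lemsa, center, year, n_sub, n_opt) {
  tibble::tibble(
    optimality = rep(c("SUBOPTIMAL", "OPTIMAL"), c(n_sub, n_opt)),
    rtcc_id = rtcc, lemsa_id = lemsa, sending_facility_id = center,
    year = year,
    receiving_level = rep(c("NONTRAUMA", "LEVEL_I"), c(n_sub, n_opt)),
    receiving_facility_id = "X", gap_days = 0L)
}

test_that("rate tables report counts, rates, shares, and NA for empty units", {
  dir <- test_directory()
  ev <- dplyr::bind_rows(
    make_events("SOUTH_WEST", "SW_L01", "A01", 2018L, 7, 3),
    make_events("BAY_AREA", "BA_L01", "C01", 2018L, 1, 9))
  rt <- aggregate_rates(ev, "RTCC", directory = dir)
  pooled <- rt[rt$year == "ALL", ]
  sw <- pooled[pooled$unit_id == "SOUTH_WEST", ]
  expect_equal(sw$n_retriage, 10L)
  expect_equal(sw$rate, 0.7)
  expect_equal(sw$share_of_state_suboptimal, 7 / 8)
  expect_equal(sum(pooled$share_of_state_suboptimal, na.rm = TRUE), 1,
               tolerance = 1e-9)
  # a sending-eligible center with zero re-triages: rate NA, never 0
  ct <- aggregate_rates(ev, "CENTER", directory = dir)
  a02 <- ct[ct$unit_id == "A02" & ct$year == "ALL", ]
  expect_equal(a02$n_retriage, 0L)
  expect_true(is.na(a02$rate))
  # zero suboptimal of some re-triages is a true 0
  ev0 <- make_events("CENTRAL", "C_L01", "Z01", 2018L, 0, 10)
  st <- aggregate_rates(ev0, "STATE")
  expect_equal(st$rate[st$year == "ALL"], 0)
  expect_equal(as_report_percent(st$rate[st$year == "ALL"]), 0)
})

test_that("LEMSA tables roll up exactly to RTCC and state, order-invariantly", {
  sim <- get_shared_sim()
  ev <- sim$events
  lemsa <- aggregate_rates(ev, "LEMSA")
  rtcc <- aggregate_rates(ev, "RTCC")
  state <- aggregate_rates(ev, "STATE")
  lut <- unique(sim$dir[, c("lemsa_id", "rtcc_id")])
  rolled <- lemsa[lemsa$year == "ALL", ] |>
    dplyr::left_join(lut, by = c(unit_id = "lemsa_id")) |>
    dplyr::group_by(.data$rtcc_id) |>
    dplyr::summarise(n_retriage = sum(n_retriage),
                     n_suboptimal = sum(n_suboptimal))
  pooled_rtcc <- rtcc[rtcc$year == "ALL", ]
  cmp <- dplyr::left_join(rolled, pooled_rtcc, by = c(rtcc_id = "unit_id"))
  expect_equal(cmp$n_retriage.x, cmp$n_retriage.y)
  expect_equal(cmp$n_suboptimal.x, cmp$n_suboptimal.y)
  expect_equal(sum(pooled_rtcc$n_retriage),
               state$n_retriage[state$year == "ALL"])
  # permutation invariance
  set.seed(1)
  shuf <- ev[sample(nrow(ev)), ]
  expect_equal(aggregate_rates(shuf, "RTCC"), rtcc)
})

test_that("annual trend recovers a rising state rate and normalized shares", {
  set.seed(42)
  years <- 2009:2018
  ev <- dplyr::bind_rows(lapply(seq_along(years), function(i) {
    p <- 0.20 + 0.02 * (i - 1)
    n <- 400
    tibble::tibble(
      optimality = ifelse(runif(n) < p, "SUBOPTIMAL", "OPTIMAL"),
      year = years[i],
      rtcc_id = sample(c("SOUTH_WEST", "CENTRAL"), n, TRUE),
      lemsa_id = "L", sending_facility_id = "H")
  }))
  tr <- annual_trend(ev)
  fit <- stats::lm(rate ~ year, data = tr$state)
  expect_gt(stats::coef(fit)[["year"]], 0)
  shares <- tr$rtcc_share |>
    dplyr::group_by(year) |>
    dplyr::summarise(s = sum(share))
  expect_true(all(abs(shares$s - 1) < 1e-9))
})

test_that("center-level summary uses sending-eligible denominators", {
  dir <- test_directory()
  # eligible senders in 2018: A01, A02, A03, C01, C03 (low-level, acute)
  ev <- dplyr::bind_rows(
    make_events("SOUTH_WEST", "SW_L01", "A01", 2018L, 4, 6),   # 40% suboptimal
    make_events("SOUTH_WEST", "SW_L01", "A02", 2018L, 1, 9),   # 10%
    make_events("BAY_AREA", "BA_L01", "C01", 2018L, 0, 5))     # none
  cs <- center_level_summary(ev, dir)
  pooled <- cs$by_year[cs$by_year$year == "ALL", ]
  expect_equal(pooled$n_eligible_centers, 5L)
  expect_equal(pooled$frac_with_suboptimal, 2 / 5)
  # the >= 40% threshold is inclusive
  expect_equal(pooled$n_ge_40pct, 1L)
  expect_equal(pooled$frac_ge_40pct, 1 / 5)
  # all-optimal events give a zero fraction
  ev_opt <- make_events("SOUTH_WEST", "SW_L01", "A01", 2018L, 0, 10)
  expect_equal(center_level_summary(ev_opt, dir)$by_year$frac_with_suboptimal,
               c(0, 0))
})
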