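test_that("dispositions collapse into the four groups", {
  expect_equal(collapse_disposition("routine home"), "HOME")
  expect_equal(collapse_disposition("expired"), "DIED")
  expect_equal(collapse_disposition("transfer to short-term general hospital"),
               "SHORT_TERM_ACUTE")
  expect_equal(collapse_disposition("skilled nursing facility"), "POST_ACUTE")
  expect_error(collapse_disposition("beamed up"), "beamed up")
})

test_that("length of stay is a nonnegative day difference", {
  expect_equal(compute_los(as.Date("2018-01-01"), as.Date("2018-01-05")), 4L)
  expect_equal(compute_los(as.Date("2018-01-01"), as.Date("2018-01-01")), 0L)
  expect_error(compute_los(as.Date("2018-01-05"), as.Date("2018-01-01")),
               "before")
})

test_that("median synthetic length of stay matches the configured distribution", {
  sim <- get_shared_sim()
  ev <- sim$events
  los <- compute_los(ev$receiving_admit_date, ev$receiving_discharge_date)
  expect_equal(median(los), median(rpois(1e5, sim$cfg$los_lambda)) ,
               tolerance = 1)
})

test_that("readmission windows are inclusive of day W, exclusive of day 0", {
  dir <- test_directory()
  mk_event <- function(id, rln, dispo = "routine home") {
    tibble::tibble(event_id = id, rln = rln,
                   receiving_discharge_date = as.Date("2018-06-01"),
                   receiving_disposition = dispo)
  }
  ev <- dplyr::bind_rows(mk_event("E1", "R1"), mk_event("E2", "R2"),
                         mk_event("E3", "R3"), mk_event("E4", "R4", "expired"))
  ip <- dplyr::bind_rows(
    make_inpatient(rln = "R1", admit_date = as.Date("2018-06-01") + 60),
    make_inpatient(rln = "R2", admit_date = as.Date("2018-06-01") + 61),
    make_inpatient(rln = "R3", admit_date = as.Date("2018-06-01")),   # same day
    make_inpatient(rln = "R4", admit_date = as.Date("2018-06-15")))
  out <- flag_readmissions(ev, ip, dir)
  expect_true(out$readmitted_60[out$event_id == "E1"])
  expect_false(out$readmitted_60[out$event_id == "E2"])
  expect_false(out$readmitted_60[out$event_id == "E3"])
  # deaths before discharge carry NA flags
  expect_true(is.na(out$readmitted_60[out$event_id == "E4"]))
  # a readmission at a non-acute facility does not count
  ev5 <- mk_event("E5", "R5")
  ip5 <- make_inpatient(rln = "R5", facility_id = "R01",
                        admit_date = as.Date("2018-06-10"))
  expect_false(flag_readmissions(ev5, ip5, dir)$readmitted_60)
})

test_that("readmission flags are monotone across windows on synthetic data", {
  sim <- get_shared_sim()
  ip <- deduplicate_records(sim$data$inpatient)$records
  ev <- flag_readmissions(sim$events, ip, sim$dir)
  ok <- stats::complete.cases(ev$readmitted_10, ev$readmitted_30, ev$readmitted_60)
  expect_true(all(!ev$readmitted_10[ok] | ev$readmitted_30[ok]))
  expect_true(all(!ev$readmitted_30[ok] | ev$readmitted_60[ok]))
  expect_gt(sum(ev$readmitted_60[ok]), 0)
})

test_that("odds ratios follow the cross-product with Woolf intervals", {
  # female vs male odds of suboptimal re-triage from the published
  # characteristics table: (1211 * 3789) / (2413 * 1469)
  or <- odds_ratio_2x2(1211, 2413, 1469, 3789)
  expect_equal(or$or, 1.2944, tolerance = 1e-4)
  expect_false(or$corrected)
  expect_lt(or$ci_lower, or$or)
  expect_gt(or$ci_upper, or$or)

  expect_equal(odds_ratio_2x2(1, 1, 1, 1)$or, 1)
  # swapping the columns inverts the odds ratio
  expect_equal(odds_ratio_2x2(20, 5, 8, 14)$or *
                 odds_ratio_2x2(5, 20, 14, 8)$or, 1, tolerance = 1e-12)
  # zero cell: Haldane-Anscombe correction with a flag
  corr <- odds_ratio_2x2(0, 5, 5, 5)
  expect_true(corr$corrected)
  expect_equal(corr$or, (0.5 * 5.5) / (5.5 * 5.5))
  expect_error(odds_ratio_2x2(0, 0, 3, 4), "sums to zero")
})

test_that("the chi-square test matches its closed form and is permutation-invariant", {
  flat <- chi_square_test(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  m <- matrix(c(50, 10, 10, 50), 2)
  a <- 50; b <- 10; cc <- 10; d <- 50; n <- a + b + cc + d
  closed <- n * (a * d - b * cc)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
  got <- chi_square_test(m)
  expect_equal(got$statistic, closed, tolerance = 1e-12)
  expect_equal(got$df, 1)
  perm <- chi_square_test(m[2:1, c(2, 1)])
  expect_equal(perm$statistic, got$statistic)
  expect_error(chi_square_test(matrix(c(0, 0, 3, 4), 2)), "degenerate")
})

test_that("surgery rates use stratum totals as denominators", {
  ev <- tibble::tibble(
    optimality = rep(c("SUBOPTIMAL", "OPTIMAL"), c(20, 30)),
    rtcc_id = "BAY_AREA",
    surgery_class = c(rep("MINOR_THERAPEUTIC", 5), rep("NONE", 15),
                      rep("MAJOR_THERAPEUTIC", 3), rep("NONE", 27)))
  tab <- surgery_rate_table(ev)
  minor_sub <- tab[tab$surgery_class == "MINOR_THERAPEUTIC" &
                     tab$optimality == "SUBOPTIMAL", ]
  expect_equal(minor_sub$n, 5L)
  expect_equal(minor_sub$stratum_total, 20L)
  expect_equal(minor_sub$pct, 25.0)
  major_opt <- tab[tab$surgery_class == "MAJOR_THERAPEUTIC" &
                     tab$optimality == "OPTIMAL", ]
  expect_equal(major_opt$pct, 10.0)
  # empty cells are zero counts, not dropped
  diag_sub <- tab[tab$surgery_class == "DIAGNOSTIC" &
                    tab$optimality == "SUBOPTIMAL", ]
  expect_equal(diag_sub$n, 0L)
})

test_that("hospital course comparison produces crude ORs on synthetic data", {
  sim <- get_shared_sim()
  ip <- deduplicate_records(sim$data$inpatient)$records
  ev <- flag_readmissions(sim$events, ip, sim$dir)
  hc <- compare_hospital_course(ev)
  expect_true(all(c("HOME", "DIED") %in% rownames(hc$disposition_table)))
  expect_gt(hc$or_transfer_third$or, 0)
  expect_true(is.finite(hc$or_readmitted_60$or))
})
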