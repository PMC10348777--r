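test_that("exact duplicates collapse to the first occurrence, others survive", {
  r <- make_record()
  r_other <- make_record(discharge_date = as.Date("2018-05-02"))
  out <- deduplicate_records(dplyr::bind_rows(r, r, r_other))
  expect_equal(out$n_removed, 1)
  expect_equal(nrow(out$records), 2)
  # rows differing only in discharge_date are kept
  expect_equal(sort(as.character(out$records$discharge_date)),
               c("2018-05-01", "2018-05-02"))
})

test_that("pairs form on equal RLN within the 0-1 day window only", {
  ed <- make_record()
  gap1 <- link_encounter_pairs(ed, make_inpatient(admit_date = as.Date("2018-05-02")))
  expect_equal(nrow(gap1$pairs), 1)
  expect_equal(gap1$pairs$gap_days, 1L)

  gap0 <- link_encounter_pairs(ed, make_inpatient(admit_date = as.Date("2018-05-01")))
  expect_equal(gap0$pairs$gap_days, 0L)

  # gap 2 is an interfacility candidate, not a re-triage pair
  gap2 <- link_encounter_pairs(ed, make_inpatient(admit_date = as.Date("2018-05-03")))
  expect_equal(nrow(gap2$pairs), 0)
  expect_equal(nrow(gap2$interfacility), 1)

  # different or missing RLNs never pair
  expect_equal(nrow(link_encounter_pairs(
    ed, make_inpatient(rln = "RLN000002"))$pairs), 0)
  expect_equal(nrow(link_encounter_pairs(
    make_record(rln = NA_character_),
    make_inpatient(rln = NA_character_))$pairs), 0)

  # a same-facility "transfer" is not a pair
  same <- link_encounter_pairs(ed, make_inpatient(facility_id = "A01"))
  expect_equal(nrow(same$pairs), 0)
})

test_that("among several candidates the earliest admission wins, ties by facility id", {
  ed <- make_record()
  ip <- dplyr::bind_rows(
    make_inpatient(facility_id = "B02", admit_date = as.Date("2018-05-02")),
    make_inpatient(facility_id = "B01", admit_date = as.Date("2018-05-01")))
  lk <- link_encounter_pairs(ed, ip)
  expect_equal(lk$pairs$receiving_facility_id, "B01")  # earlier admission

  tie <- dplyr::bind_rows(
    make_inpatient(facility_id = "B02", admit_date = as.Date("2018-05-02")),
    make_inpatient(facility_id = "B01", admit_date = as.Date("2018-05-02")))
  lk2 <- link_encounter_pairs(ed, tie)
  expect_equal(lk2$pairs$receiving_facility_id, "B01")  # lexicographic tie-break
})

test_that("the exclusion cascade attributes removals to the first matching rule", {
  dir <- test_directory()
  ed <- dplyr::bind_rows(
    make_record(rln = "R1", age = 90L),                        # age rule
    make_record(rln = "R2", riss = 15L),                       # RISS strictly > 15
    make_record(rln = "R3"),                                   # receiving REHAB
    make_record(rln = "R4"),                                   # clean pair -> cohort
    make_record(rln = "R5", facility_id = "B01"),              # level I sender
    make_record(rln = "R6", disposition = "admitted as inpatient"))  # under-triaged
  ip <- dplyr::bind_rows(
    make_inpatient(rln = "R1"), make_inpatient(rln = "R2"),
    make_inpatient(rln = "R3", facility_id = "R01"),
    make_inpatient(rln = "R4"))
  res <- link_cohort(ed, ip, dir)
  led <- setNames(res$ledger$n_removed, res$ledger$rule)
  expect_equal(unname(led[c("age_18_89", "riss_gt_15",
                            "receiving_not_short_term_acute",
                            "field_triage_direct_to_high_level")]),
               c(1L, 1L, 1L, 1L))
  expect_equal(nrow(res$cohort), 1)
  expect_equal(res$cohort$rln, "R4")
  expect_equal(nrow(res$undertriaged), 1)
  expect_equal(res$undertriaged$rln, "R6")
  # ledger conservation and monotone n_remaining
  expect_equal(sum(res$ledger$n_removed) + nrow(res$cohort) +
                 nrow(res$undertriaged), res$ledger$n_remaining[1])
  expect_true(all(diff(res$ledger$n_remaining) <= 0))
})

test_that("an unknown facility id is a hard error naming the id", {
  dir <- test_directory()
  ed <- make_record(facility_id = "ZZZ")
  expect_error(link_cohort(ed, make_inpatient(), dir), "ZZZ")
})

test_that("with no missing identifiers, linkage recovers the ground truth exactly", {
  cfg <- sim_config(n_patients = 3000, p_missing_rln = 0,
                    p_missing_rln_inpatient = 0, seed = 7)
  dir <- generate_hospital_directory(cfg)
  s <- generate_encounters(cfg, dir)
  res <- link_cohort(s$ed, s$inpatient, dir)
  tr <- s$truth[s$truth$true_retriage, ]
  expect_equal(nrow(res$cohort), nrow(tr))
  expect_setequal(
    paste(res$cohort$rln, res$cohort$facility_id, res$cohort$receiving_facility_id),
    paste(tr$rln, tr$sending_facility_id, tr$receiving_facility_id))
})

test_that("recovered pair counts decrease monotonically in RLN missingness", {
  sizes <- vapply(c(0, 0.10, 0.25), function(p) {
    cfg <- sim_config(n_patients = 3000, p_missing_rln = p,
                      p_missing_rln_inpatient = 0, p_duplicate = 0, seed = 13)
    dir <- generate_hospital_directory(cfg)
    s <- generate_encounters(cfg, dir)
    nrow(link_cohort(s$ed, s$inpatient, dir)$cohort)
  }, numeric(1))
  expect_true(all(diff(sizes) < 0))
})

test_that("every ED encounter lands in exactly one partition cell", {
  sim <- get_shared_sim()
  lk <- sim$linked
  ded_ed <- deduplicate_records(sim$data$ed)$records
  ids_cohort <- lk$cohort$.ed_id
  ids_under <- lk$undertriaged$.ed_id
  n_excluded <- sum(lk$ledger$n_removed)
  expect_equal(length(intersect(ids_cohort, ids_under)), 0)
  expect_equal(length(ids_cohort) + length(ids_under) + n_excluded, nrow(ded_ed))
})
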