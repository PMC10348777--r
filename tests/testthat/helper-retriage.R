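# Shared fixtures, all built in code.

# A small hand-written directory: South-West has a full level mix plus a
# rehab facility; the Bay Area pair sits ~350 miles away so cross-region
# transfers exercise the "regardless of distance" rule.
test_directory <- function(years = 2018L) {
  base <- tibble::tribble(
    ~facility_id, ~latitude, ~longitude, ~facility_type,     ~lemsa_id, ~rtcc_id,     ~level,
    "A01",        34.00,     -118.20,    "SHORT_TERM_ACUTE", "SW_L01",  "SOUTH_WEST", "NONTRAUMA",
    "A02",        34.10,     -118.30,    "SHORT_TERM_ACUTE", "SW_L01",  "SOUTH_WEST", "LEVEL_III",
    "A03",        34.05,     -118.25,    "SHORT_TERM_ACUTE", "SW_L02",  "SOUTH_WEST", "LEVEL_IV",
    "B01",        34.06,     -118.26,    "SHORT_TERM_ACUTE", "SW_L02",  "SOUTH_WEST", "LEVEL_I",
    "B02",        33.90,     -118.10,    "SHORT_TERM_ACUTE", "SW_L01",  "SOUTH_WEST", "LEVEL_II",
    "R01",        34.02,     -118.22,    "REHAB",            "SW_L01",  "SOUTH_WEST", "NONTRAUMA",
    "C01",        37.77,     -122.42,    "SHORT_TERM_ACUTE", "BA_L01",  "BAY_AREA",   "NONTRAUMA",
    "C02",        37.60,     -122.10,    "SHORT_TERM_ACUTE", "BA_L01",  "BAY_AREA",   "LEVEL_I",
    "C03",        37.90,     -122.30,    "SHORT_TERM_ACUTE", "BA_L01",  "BAY_AREA",   "NONTRAUMA"
  )
  d <- base[rep(seq_len(nrow(base)), each = length(years)), ]
  d$year <- rep(as.integer(years), times = nrow(base))
  d$name <- paste("Hospital", d$facility_id)
  class(d) <- c("retriage_directory", class(d))
  d
}

# one encounter row with overridable fields
make_record <- function(...) {
  defaults <- list(
    rln = "RLN000001", facility_id = "A01", record_kind = "ED",
    admit_date = as.Date("2018-05-01"), discharge_date = as.Date("2018-05-01"),
    disposition = "transfer to short-term general hospital",
    admission_type = "EMERGENT", age = 40L, sex = "MALE", race = "white",
    ethnicity = "NON_HISPANIC", insurance = "self-pay", riss = 20L,
    mechanism = "fall", body_region = "TBI", burn_flag = FALSE,
    injury_dx = TRUE, year = 2018L, surgery_class = NA_character_)
  args <- utils::modifyList(defaults, list(...))
  args$year <- as.integer(format(args$admit_date, "%Y"))
  tibble::as_tibble(args)
}

make_inpatient <- function(..., facility_id = "B01",
                           admit_date = as.Date("2018-05-02"),
                           discharge_date = admit_date + 4L,
                           disposition = "routine home",
                           surgery_class = "NONE") {
  make_record(record_kind = "INPATIENT", facility_id = facility_id,
              admit_date = admit_date, discharge_date = discharge_date,
              disposition = disposition, surgery_class = surgery_class, ...)
}

# one moderately sized synthetic run shared across test files
.retriage_test_cache <- new.env(parent = emptyenv())
get_shared_sim <- function() {
  if (is.null(.retriage_test_cache$sim)) {
    cfg <- sim_config(n_patients = 4000, seed = 99)
    dir <- generate_hospital_directory(cfg)
    s <- generate_encounters(cfg, dir)
    lk <- link_cohort(s$ed, s$inpatient, dir)
    ev <- encode_covariates(label_optimality(lk$cohort, dir))
    .retriage_test_cache$sim <- list(cfg = cfg, dir = dir, data = s,
                                     linked = lk, events = ev)
  }
  .retriage_test_cache$sim
}
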