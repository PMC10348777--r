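# degrees of latitude spanning a given number of statute miles on the
# 3958.8-mile sphere (exact along a meridian)
lat_offset <- function(miles) (miles / 3958.8) * 180 / pi

test_that("haversine distances are symmetric, zero at identity, and match an independent oracle", {
  expect_equal(haversine_miles(34, -118, 34, -118), 0)
  expect_equal(haversine_miles(37.7749, -122.4194, 34.0522, -118.2437),
               347.4, tolerance = 0.05)
  set.seed(14)
  lat1 <- runif(50, -60, 60); lon1 <- runif(50, -179, 179)
  lat2 <- runif(50, -60, 60); lon2 <- runif(50, -179, 179)
  expect_equal(haversine_miles(lat1, lon1, lat2, lon2),
               haversine_miles(lat2, lon2, lat1, lon1))
  oracle <- geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                                     r = 3958.8)
  expect_equal(haversine_miles(lat1, lon1, lat2, lon2), oracle,
               tolerance = 1e-9)
  expect_error(haversine_miles(95, 0, 0, 0), "WGS84")
})

test_that("the ground/air mode boundary sits exactly at 50 miles", {
  near <- estimate_transport(34, -118, 34 + lat_offset(49.9), -118)
  expect_equal(near$mode, "GROUND")
  expect_equal(near$time_hours, 49.9 * 1.3 / 40, tolerance = 1e-9)
  at <- estimate_transport(34, -118, 34 + lat_offset(50), -118)
  expect_equal(at$mode, "AIR")
  far <- estimate_transport(34, -118, 34 + lat_offset(60), -118)
  expect_equal(far$mode, "AIR")
  expect_equal(far$time_hours, 0.5, tolerance = 1e-9)  # 60 mi at 120 mph
})

test_that("a failing drive-time provider falls back with a warning", {
  broken <- function(...) stop("routing service down")
  expect_warning(
    est <- estimate_transport(34, -118, 34 + lat_offset(10), -118,
                              provider = broken),
    "fallback")
  expect_equal(est$mode, "GROUND")
  expect_equal(est$time_hours, 10 * 1.3 / 40, tolerance = 1e-9)
})

opt_event <- function(year = 2018L) {
  tibble::tibble(event_id = "E1", year = year,
                 sending_facility_id = "S01",
                 receiving_facility_id = "X01")
}

opt_directory <- function(cands) {
  base <- tibble::tibble(
    facility_id = c("S01", "X01", cands$facility_id),
    name = "h", latitude = c(34, 34.01, cands$latitude),
    longitude = c(-118, -118.01, cands$longitude),
    facility_type = "SHORT_TERM_ACUTE", lemsa_id = "L", rtcc_id = "SOUTH_WEST",
    year = 2018L,
    level = c("NONTRAUMA", "LEVEL_III", cands$level))
  base
}

test_that("ground candidates within 50 miles are preferred over nearer-by-air", {
  dir <- opt_directory(tibble::tibble(
    facility_id = c("T2", "T1"),
    latitude = 34 + lat_offset(c(10, 30)), longitude = -118,
    level = c("LEVEL_II", "LEVEL_I")))
  alt <- find_alternative_destination(opt_event(), dir)
  expect_true(alt$resolvable)
  expect_equal(alt$proposed_facility_id, "T2")  # closest ground, regardless of level I/II
  expect_equal(alt$mode, "GROUND")
})

test_that("with no level I/II within 50 miles the closest is reached by air", {
  dir <- opt_directory(tibble::tibble(
    facility_id = c("T1", "T2"),
    latitude = 34 + lat_offset(c(80, 95)), longitude = -118,
    level = c("LEVEL_I", "LEVEL_II")))
  alt <- find_alternative_destination(opt_event(), dir)
  expect_equal(alt$proposed_facility_id, "T1")
  expect_equal(alt$mode, "AIR")
  expect_equal(alt$time_hours, 80 / 120, tolerance = 1e-6)
})

test_that("a directory without level I/II centers is unresolvable, not an error", {
  dir <- opt_directory(tibble::tibble(facility_id = character(0),
                                      latitude = numeric(0),
                                      longitude = numeric(0),
                                      level = character(0)))
  alt <- find_alternative_destination(opt_event(), dir)
  expect_false(alt$resolvable)
  expect_true(is.na(alt$proposed_facility_id))
})

test_that("candidates are restricted to centers operating at level I/II that year", {
  # T1 is level I only from 2017 onward
  dir <- dplyr::bind_rows(lapply(2015:2018, function(y) {
    d <- opt_directory(tibble::tibble(
      facility_id = "T1", latitude = 34 + lat_offset(20),
      longitude = -118, level = if (y >= 2017) "LEVEL_I" else "LEVEL_III"))
    d$year <- as.integer(y)
    d
  }))
  expect_false(find_alternative_destination(opt_event(2016L), dir)$resolvable)
  expect_true(find_alternative_destination(opt_event(2018L), dir)$resolvable)
})

test_that("adding a candidate never increases the chosen transport time", {
  set.seed(77)
  for (i in 1:25) {
    k <- sample(2:12, 1)
    cands <- tibble::tibble(
      facility_id = sprintf("T%02d", seq_len(k)),
      latitude = runif(k, 32.5, 39), longitude = runif(k, -123, -115),
      level = sample(c("LEVEL_I", "LEVEL_II"), k, TRUE))
    t_small <- find_alternative_destination(
      opt_event(), opt_directory(cands[-k, ]))$time_hours
    t_full <- find_alternative_destination(
      opt_event(), opt_directory(cands))$time_hours
    expect_lte(t_full, t_small + 1e-12)
  }
})

test_that("optimize_all summarises resolvable fractions and the accounting identity", {
  sim <- get_shared_sim()
  opt <- optimize_all(sim$events, sim$dir)
  s <- opt$summary
  expect_equal(s$n_suboptimal, sum(sim$events$optimality == "SUBOPTIMAL"))
  expect_equal(s$rate_after, (s$n_suboptimal - s$n_resolvable) / s$n_retriage)
  # proposed destinations are always level I/II in the event's year
  alts <- opt$alternatives[opt$alternatives$resolvable, ]
  ev_year <- sim$events$year[match(alts$event_id, sim$events$event_id)]
  lv <- mapply(function(f, y) {
    sim$dir$level[sim$dir$facility_id == f & sim$dir$year == y]
  }, alts$proposed_facility_id, ev_year)
  expect_true(all(lv %in% c("LEVEL_I", "LEVEL_II")))
  # default directory has level I/II in every region: everything resolvable
  expect_equal(s$resolvable_fraction, 1)
})
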