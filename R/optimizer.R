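# Alternative level I/II destinations under the ground/air transport rule.
#
# The rule: a candidate within 50 great-circle miles would be reached
# fastest by ground; at 50 miles or more, by air at a conservative 120 mph
# along the straight-line flight path. Among level I/II centers operating in
# the event's year, the destination is the candidate with the shortest
# ground time when at least one candidate lies within 50 miles, else the
# candidate with the shortest flight time; ties break on lexicographic
# facility id. No candidate anywhere is a data outcome (resolvable = FALSE),
# not an error.

EARTH_RADIUS_MILES <- 3958.8
AIR_SPEED_MPH <- 120
GROUND_THRESHOLD_MILES <- 50

#' Great-circle distance in statute miles
#'
#' Haversine formula on a sphere of radius 3958.8 miles.
#'
#' @param lat1,lon1,lat2,lon2 WGS84 decimal degrees (vectorized).
#' @return Distance in miles.
#' @export
haversine_miles <- function(lat1, lon1, lat2, lon2) {
  ok <- function(lat, lon) all(abs(lat) <= 90, na.rm = TRUE) &&
    all(abs(lon) <= 180, na.rm = TRUE)
  if (!ok(lat1, lon1) || !ok(lat2, lon2)) {
    stop("coordinates outside WGS84 bounds", call. = FALSE)
  }
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * EARTH_RADIUS_MILES * asin(pmin(1, sqrt(a)))
}

#' Built-in fallback drive-time model
#'
#' Ground travel time approximated as great-circle distance times a road
#' circuity factor, at a constant average speed. Used whenever no external
#' routing adapter is plugged in (or when one fails). The defaults (circuity
#' 1.3, 40 mph) are deliberately conservative urban-road values and are
#' config-exposed.
#'
#' @param circuity Road-distance inflation over the great circle.
#' @param speed_mph Average ground speed.
#' @return A drive-time provider: `function(lat1, lon1, lat2, lon2)`
#'   returning a data frame with `time_hours` and `distance_miles`
#'   (the modeled road distance).
#' @export
fallback_drive_time <- function(circuity = 1.3, speed_mph = 40) {
  force(circuity); force(speed_mph)
  function(lat1, lon1, lat2, lon2) {
    gc <- haversine_miles(lat1, lon1, lat2, lon2)
    data.frame(time_hours = gc * circuity / speed_mph,
               distance_miles = gc * circuity)
  }
}

#' Estimate transport mode and time between two centers
#'
#' Great-circle separation below 50 miles implies ground transport with the
#' drive-time provider's estimate; 50 miles or more (boundary inclusive)
#' implies air transport at 120 mph over the straight-line distance. A
#' failing provider falls back to the built-in drive model with a warning.
#'
#' @param lat1,lon1 Sending center coordinates.
#' @param lat2,lon2 Candidate coordinates (vectorized).
#' @param provider Drive-time provider, default [fallback_drive_time()].
#' @param screen `"great_circle"` (default) screens the 50-mile rule on the
#'   straight-line distance; `"provider"` screens on the provider's road
#'   distance.
#' @return Tibble: `mode` ("GROUND"/"AIR"), `distance_miles` (great-circle),
#'   `time_hours`.
#' @export
estimate_transport <- function(lat1, lon1, lat2, lon2,
                               provider = fallback_drive_time(),
                               screen = c("great_circle", "provider")) {
  screen <- match.arg(screen)
  gc <- haversine_miles(lat1, lon1, lat2, lon2)
  drv <- tryCatch(provider(lat1, lon1, lat2, lon2), error = function(e) {
    warning("drive-time provider failed (", conditionMessage(e),
            "); using built-in fallback", call. = FALSE)
    fallback_drive_time()(lat1, lon1, lat2, lon2)
  })
  screen_dist <- if (screen == "provider" &&
                       !is.null(drv$distance_miles)) drv$distance_miles else gc
  air <- screen_dist >= GROUND_THRESHOLD_MILES
  tibble::tibble(
    mode = ifelse(air, "AIR", "GROUND"),
    distance_miles = gc,
    time_hours = ifelse(air, gc / AIR_SPEED_MPH, drv$time_hours))
}

# candidate level I/II short-term acute centers operating in a year
high_level_candidates <- function(directory, year) {
  yr <- pmin(pmax(year, min(directory$year)), max(directory$year))
  d <- directory[directory$year == yr &
                   directory$facility_type == "SHORT_TERM_ACUTE" &
                   directory$level %in% high_trauma_levels(), , drop = FALSE]
  d[order(d$facility_id), c("facility_id", "latitude", "longitude", "level")]
}

#' Alternative optimal destination for one suboptimal re-triage
#'
#' @param event One-row tibble (or list) with `event_id`, `year`,
#'   `sending_facility_id`, `receiving_facility_id`.
#' @param directory Hospital directory with year-resolved levels.
#' @param provider Drive-time provider.
#' @param screen See [estimate_transport()].
#' @return One-row tibble: `event_id`, `original_receiving_facility_id`,
#'   `proposed_facility_id`, `mode`, `distance_miles`, `time_hours`,
#'   `resolvable`.
#' @export
find_alternative_destination <- function(event, directory,
                                         provider = fallback_drive_time(),
                                         screen = c("great_circle", "provider")) {
  screen <- match.arg(screen)
  snd <- directory[directory$facility_id == event$sending_facility_id &
                     directory$year == pmin(pmax(event$year, min(directory$year)),
                                            max(directory$year)), , drop = FALSE]
  if (nrow(snd) == 0L) {
    stop("unknown facility_id: ", event$sending_facility_id, call. = FALSE)
  }
  cand <- high_level_candidates(directory, event$year)
  unresolved <- tibble::tibble(
    event_id = event$event_id,
    original_receiving_facility_id = event$receiving_facility_id,
    proposed_facility_id = NA_character_, mode = NA_character_,
    distance_miles = NA_real_, time_hours = NA_real_, resolvable = FALSE)
  if (nrow(cand) == 0L) return(unresolved)

  est <- estimate_transport(snd$latitude[1], snd$longitude[1],
                            cand$latitude, cand$longitude,
                            provider = provider, screen = screen)
  within <- est$mode == "GROUND"
  pool <- if (any(within)) which(within) else seq_len(nrow(cand))
  # candidates are pre-sorted by facility id, so which.min resolves ties
  # lexicographically
  best <- pool[which.min(est$time_hours[pool])]
  tibble::tibble(
    event_id = event$event_id,
    original_receiving_facility_id = event$receiving_facility_id,
    proposed_facility_id = cand$facility_id[best],
    mode = est$mode[best],
    distance_miles = est$distance_miles[best],
    time_hours = est$time_hours[best],
    resolvable = TRUE)
}

#' Alternative destinations for every suboptimal re-triage
#'
#' @param events Labeled events (optimal events pass through untouched in
#'   the summary denominator).
#' @param directory Hospital directory.
#' @param provider Drive-time provider.
#' @param screen See [estimate_transport()].
#' @return List: `alternatives` (one row per suboptimal event) and `summary`
#'   (`n_retriage`, `n_suboptimal`, `n_resolvable`, `resolvable_fraction`,
#'   and the state suboptimal rate before and after hypothetically
#'   re-routing every resolvable event: `rate_after = unresolvable /
#'   n_retriage`).
#' @export
optimize_all <- function(events, directory, provider = fallback_drive_time(),
                         screen = c("great_circle", "provider")) {
  screen <- match.arg(screen)
  ev <- tibble::as_tibble(events)
  sub <- ev[ev$optimality == "SUBOPTIMAL", , drop = FALSE]
  alts <- if (nrow(sub)) {
    purrr::map_dfr(seq_len(nrow(sub)), function(i) {
      find_alternative_destination(sub[i, ], directory, provider = provider,
                                   screen = screen)
    })
  } else {
    tibble::tibble(event_id = character(0),
                   original_receiving_facility_id = character(0),
                   proposed_facility_id = character(0), mode = character(0),
                   distance_miles = numeric(0), time_hours = numeric(0),
                   resolvable = logical(0))
  }
  n_ret <- nrow(ev)
  n_sub <- nrow(sub)
  n_res <- sum(alts$resolvable)
  summary <- tibble::tibble(
    n_retriage = n_ret, n_suboptimal = n_sub, n_resolvable = n_res,
    resolvable_fraction = ifelse(n_sub > 0, n_res / n_sub, NA_real_),
    rate_before = ifelse(n_ret > 0, n_sub / n_ret, NA_real_),
    rate_after = ifelse(n_ret > 0, (n_sub - n_res) / n_ret, NA_real_))
  list(alternatives = alts, summary = summary)
}
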