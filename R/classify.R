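#' Interpolate positions along a track at arbitrary instants
#'
#' Linear interpolation of lon and lat between the bracketing GPS fixes,
#' weighted by time. Instants whose bracketing fixes are more than
#' `max_gap_intervals` nominal GPS intervals apart are flagged low
#' confidence; instants outside the track's time span are an error.
#'
#' @param track A `track` data.frame, sorted by time.
#' @param times POSIXct instants to locate.
#' @param max_gap_intervals Gap tolerance in nominal fix intervals (default 3).
#' @return data.frame with `lon`, `lat`, `low_confidence`.
#' @export
interpolate_dive_location <- function(track, times, max_gap_intervals = 3) {
  t <- as.numeric(track$timestamp)
  q <- as.numeric(times)
  if (any(q < t[1] | q > t[length(t)])) {
    stop_divetrip("time outside track span", "divetrip_range_error")
  }
  nominal <- stats::median(diff(t))
  i <- findInterval(q, t, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1), length(t) - 1)
  gap <- t[i + 1] - t[i]
  f <- ifelse(gap > 0, (q - t[i]) / gap, 0)
  data.frame(lon = track$lon[i] + f * (track$lon[i + 1] - track$lon[i]),
             lat = track$lat[i] + f * (track$lat[i + 1] - track$lat[i]),
             low_confidence = gap > max_gap_intervals * nominal)
}

#' Classify a single dive as benthic or pelagic
#'
#' Three criteria, combined with OR and evaluated in a fixed order for
#' provenance reporting:
#' \enumerate{
#'   \item `consecutive_10pct`: the dive's maximum depth is within 10% of
#'     either the previous or the subsequent dive's maximum depth (a flat
#'     sequence of maximum depths indicates a bottom phase on the seafloor).
#'     The 10% is taken of the larger of the two depths (symmetric).
#'   \item `shallow_bathy`: seafloor depth at the dive location < 10 m (in
#'     water that shallow every dive effectively reaches the bottom).
#'   \item `depth_vs_bathy`: |dive depth - seafloor depth| < 5 m.
#' }
#' A dive satisfying none is pelagic. Missing neighbours (first/last dive of
#' a trip) simply skip criterion 1.
#'
#' @param max_depth_m Dive maximum depth (m, > 0).
#' @param prev_max_depth_m,next_max_depth_m Neighbouring dives' maximum
#'   depths within the same trip, or `NA` when absent.
#' @param seafloor_depth_m Seafloor depth at the dive location (m,
#'   positive-down), or `NA` if unknown.
#' @param pct Neighbour similarity tolerance (default 0.10).
#' @param shallow_m Shallow-bathymetry cutoff (default 10 m).
#' @param bathy_diff_m Depth-vs-bathymetry cutoff (default 5 m).
#' @return List with `dive_class` ("benthic"/"pelagic") and
#'   `criterion_fired` ("consecutive_10pct", "shallow_bathy",
#'   "depth_vs_bathy" or "none").
#' @export
classify_dive <- function(max_depth_m, prev_max_depth_m = NA,
                          next_max_depth_m = NA, seafloor_depth_m = NA,
                          pct = 0.10, shallow_m = 10, bathy_diff_m = 5) {
  near <- function(nbr) {
    !is.na(nbr) && abs(max_depth_m - nbr) <= pct * max(max_depth_m, nbr)
  }
  crit <- if (near(prev_max_depth_m) || near(next_max_depth_m)) {
    "consecutive_10pct"
  } else if (!is.na(seafloor_depth_m) && seafloor_depth_m < shallow_m) {
    "shallow_bathy"
  } else if (!is.na(seafloor_depth_m) &&
             abs(max_depth_m - seafloor_depth_m) < bathy_diff_m) {
    "depth_vs_bathy"
  } else {
    "none"
  }
  list(dive_class = if (crit == "none") "pelagic" else "benthic",
       criterion_fired = crit)
}

#' Locate and classify every dive of a deployment
#'
#' Assigns each dive to a trip (by its interpolated start instant), locates it
#' on the track, looks up the seafloor depth by bilinear interpolation of the
#' bathymetry, and applies [classify_dive()] with neighbours restricted to the
#' same trip. Dives outside the bathymetry extent are flagged unclassifiable
#' and excluded from benthic proportions.
#'
#' @param dives Dive table from [extract_dives()].
#' @param track The deployment's `track`.
#' @param trips Trip table from [split_trips()] (for trip assignment and the
#'   neighbour window); may be empty, in which case all dives share one
#'   pseudo-trip.
#' @param bathy A [bathy_grid()].
#' @param ... Passed to [classify_dive()] (criterion thresholds).
#' @return List: `dives` (with `lon`, `lat`, `seafloor_m`, `dive_class`,
#'   `criterion_fired`, `trip_id`), `benthic_fraction` (over classifiable
#'   dives), `per_trip` (pelagic percentage per trip), `n_unclassifiable`.
#' @export
classify_deployment <- function(dives, track, trips, bathy, ...) {
  n <- nrow(dives)
  if (n == 0) {
    dives$lon <- numeric(0); dives$lat <- numeric(0)
    dives$seafloor_m <- numeric(0)
    dives$dive_class <- character(0); dives$criterion_fired <- character(0)
    dives$trip_id <- character(0)
    return(list(dives = dives, benthic_fraction = NA_real_,
                per_trip = data.frame(), n_unclassifiable = 0L))
  }
  loc <- interpolate_dive_location(track, dives$start)
  dives$lon <- loc$lon; dives$lat <- loc$lat
  dives$location_low_confidence <- loc$low_confidence
  dives$seafloor_m <- bathy_depth_at(bathy, dives$lon, dives$lat)

  s <- as.numeric(dives$start)
  trip_of <- rep(NA_character_, n)
  if (nrow(trips) > 0) {
    for (k in seq_len(nrow(trips))) {
      sel <- s >= as.numeric(trips$departure_time[k]) &
        s <= as.numeric(trips$return_time[k])
      trip_of[sel] <- trips$trip_id[k]
    }
  }
  trip_of[is.na(trip_of)] <- "untripped"
  dives$trip_id <- trip_of

  cls <- character(n); crit <- character(n)
  for (k in seq_len(n)) {
    same <- trip_of == trip_of[k]
    prev <- if (k > 1 && same[k - 1]) dives$max_depth_m[k - 1] else NA
    nxt <- if (k < n && same[k + 1]) dives$max_depth_m[k + 1] else NA
    r <- classify_dive(dives$max_depth_m[k], prev, nxt, dives$seafloor_m[k], ...)
    cls[k] <- r$dive_class; crit[k] <- r$criterion_fired
  }
  unclass <- is.na(dives$seafloor_m) & crit == "none"
  cls[unclass] <- NA_character_
  crit[unclass] <- NA_character_
  dives$dive_class <- cls
  dives$criterion_fired <- crit

  ok <- !is.na(cls)
  bf <- if (any(ok)) mean(cls[ok] == "benthic") else NA_real_
  per_trip <- do.call(rbind, lapply(unique(trip_of), function(tr) {
    sel <- trip_of == tr & ok
    data.frame(trip_id = tr, n_dives = sum(trip_of == tr),
               pelagic_pct = if (any(sel)) 100 * mean(cls[sel] == "pelagic")
                             else NA_real_)
  }))
  list(dives = dives, benthic_fraction = bf, per_trip = per_trip,
       n_unclassifiable = sum(unclass))
}
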