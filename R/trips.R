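#' Split a GPS track into foraging trips
#'
#' Central-place foraging trips are delimited by a circular buffer around the
#' colony (default 500 m). A fix at exactly the buffer distance counts as
#' inside (ties break toward the colony, so zero-length excursions cannot
#' occur). A trip runs from the last inside fix before an excursion to the
#' first inside fix after it; those two anchor fixes are included in the
#' trip's fix subset. Departure and return instants are refined by linearly
#' interpolating the distance-to-colony crossing of the buffer between the
#' bracketing fixes. Excursions still outside the buffer when the record ends
#' (or already outside when it starts) are flagged incomplete.
#'
#' @param track A `track` data.frame (`timestamp`, `lon`, `lat`), sorted.
#' @param colony_lonlat `c(lon, lat)` of the colony.
#' @param buffer_m Buffer radius in metres (> 0), default 500.
#' @return data.frame of trips: `trip_id`, `departure_time`, `return_time`,
#'   `duration_h`, `complete`, `i_first`, `i_last` (fix index range).
#' @export
split_trips <- function(track, colony_lonlat, buffer_m = 500) {
  if (buffer_m <= 0) stop_divetrip("buffer_m must be > 0", "divetrip_config_error")
  n <- nrow(track)
  dist <- great_circle_distance(track$lon, track$lat,
                                colony_lonlat[1], colony_lonlat[2])
  inside <- dist <= buffer_m
  t <- as.numeric(track$timestamp)
  out <- !inside
  if (!any(out)) {
    return(data.frame(trip_id = character(), departure_time = as.POSIXct(character(), tz = "UTC"),
                      return_time = as.POSIXct(character(), tz = "UTC"),
                      duration_h = numeric(), complete = logical(),
                      i_first = integer(), i_last = integer()))
  }
  r <- rle(out)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  exc1 <- starts[r$values]; exc2 <- ends[r$values]
  id <- if ("individual_id" %in% names(track)) track$individual_id[1] else "trk"
  rows <- lapply(seq_along(exc1), function(k) {
    a <- exc1[k]; b <- exc2[k]
    has_dep <- a > 1
    has_ret <- b < n
    i_first <- if (has_dep) a - 1L else a
    i_last <- if (has_ret) b + 1L else b
    dep <- if (has_dep) {
      f <- (buffer_m - dist[a - 1]) / (dist[a] - dist[a - 1])
      t[a - 1] + f * (t[a] - t[a - 1])
    } else t[a]
    ret <- if (has_ret) {
      f <- (dist[b] - buffer_m) / (dist[b] - dist[b + 1])
      t[b] + f * (t[b + 1] - t[b])
    } else t[b]
    data.frame(trip_id = sprintf("%s_trip%03d", id, k),
               departure_time = as.POSIXct(dep, origin = "1970-01-01", tz = "UTC"),
               return_time = as.POSIXct(ret, origin = "1970-01-01", tz = "UTC"),
               duration_h = (ret - dep) / 3600,
               complete = has_dep && has_ret,
               i_first = i_first, i_last = i_last)
  })
  do.call(rbind, rows)
}

#' Trip summary statistics
#'
#' Total distance is the sum of consecutive-fix great-circle distances over
#' the trip's fixes; maximum distance is the largest fix-to-colony distance.
#' Incomplete trips get statistics too, but carry their `complete` flag so
#' summaries can exclude them (the default reporting convention here).
#'
#' @param track The `track` the trips were split from.
#' @param trips Output of [split_trips()].
#' @param colony_lonlat `c(lon, lat)`.
#' @return `trips` with `total_distance_km` and `max_distance_km` added.
#' @export
trip_stats <- function(track, trips, colony_lonlat) {
  tot <- numeric(nrow(trips)); mx <- numeric(nrow(trips))
  for (k in seq_len(nrow(trips))) {
    i <- trips$i_first[k]:trips$i_last[k]
    lon <- track$lon[i]; lat <- track$lat[i]
    tot[k] <- sum(great_circle_distance(lon[-length(lon)], lat[-length(lat)],
                                        lon[-1], lat[-1])) / 1000
    mx[k] <- max(great_circle_distance(lon, lat, colony_lonlat[1],
                                       colony_lonlat[2])) / 1000
  }
  trips$total_distance_km <- tot
  trips$max_distance_km <- mx
  trips
}

#' Flag overnight roosting away from the colony
#'
#' A trip is an overnight-roost trip iff it spans at least one local midnight
#' while outside the colony buffer AND it contains a night-time window (sun
#' below the horizon throughout) of at least `min_window_h` hours whose net
#' displacement (great-circle distance between the window's first and last
#' fix) is under `max_displacement_m`. The stationarity thresholds are
#' package choices, configurable.
#'
#' @param track The `track`.
#' @param trips Output of [split_trips()].
#' @param tz_offset_h Local clock offset from UTC (hours).
#' @param min_window_h Minimum stationary night window (h), default 2.
#' @param max_displacement_m Maximum net displacement within the window (m),
#'   default 200.
#' @return `trips` with logical column `overnight_roost`.
#' @export
detect_overnight_roost <- function(track, trips, tz_offset_h,
                                   min_window_h = 2, max_displacement_m = 200) {
  t <- as.numeric(track$timestamp)
  flag <- logical(nrow(trips))
  for (k in seq_len(nrow(trips))) {
    i <- trips$i_first[k]:trips$i_last[k]
    # interior fixes only (anchors are at/inside the buffer)
    ii <- i[-c(1, length(i))]
    if (length(ii) < 2) next
    dep_day <- local_day(trips$departure_time[k], tz_offset_h)
    ret_day <- local_day(trips$return_time[k], tz_offset_h)
    if (ret_day <= dep_day) next
    night <- solar_elevation(track$timestamp[ii], track$lon[ii], track$lat[ii]) < 0
    if (!any(night)) next
    r <- rle(night)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (run in which(r$values)) {
      jj <- ii[starts[run]:ends[run]]
      if (length(jj) < 2) next
      for (a in seq_along(jj)) {
        span_ok <- t[jj] - t[jj[a]] >= min_window_h * 3600
        if (!any(span_ok)) break
        b <- which(span_ok)[1]
        disp <- great_circle_distance(track$lon[jj[a]], track$lat[jj[a]],
                                      track$lon[jj[b]], track$lat[jj[b]])
        if (disp < max_displacement_m) {
          flag[k] <- TRUE
          break
        }
      }
      if (flag[k]) break
    }
  }
  trips$overnight_roost <- flag
  trips
}

#' Hour-of-day histograms of trip departures and returns
#'
#' Counts complete trips by local clock hour (24 bins) of departure and
#' return, optionally split by sex.
#'
#' @param trips A trip table (may combine individuals); needs
#'   `departure_time`, `return_time`, `complete`, optionally `sex`.
#' @param tz_offset_h Local clock offset from UTC (hours).
#' @return data.frame with `sex`, `hour` (0-23), `departures`, `returns`.
#' @export
departure_return_histograms <- function(trips, tz_offset_h) {
  trips <- trips[trips$complete, , drop = FALSE]
  sex <- if ("sex" %in% names(trips)) trips$sex else rep("all", nrow(trips))
  out <- list()
  for (s in unique(sex)) {
    sub <- trips[sex == s, , drop = FALSE]
    dep_h <- local_hour(sub$departure_time, tz_offset_h)
    ret_h <- local_hour(sub$return_time, tz_offset_h)
    out[[s]] <- data.frame(
      sex = s, hour = 0:23,
      departures = as.integer(tabulate(dep_h + 1, nbins = 24)),
      returns = as.integer(tabulate(ret_h + 1, nbins = 24)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
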