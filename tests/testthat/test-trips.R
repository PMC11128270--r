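colony <- c(146.6758, -38.9403)

test_that("great-circle distance behaves like the haversine closed form", {
  expect_equal(great_circle_distance(146, -38, 146, -38), 0)
  # 0.0045 deg due north on a 6,371 km sphere: R * dlat(rad)
  d <- great_circle_distance(colony[1], colony[2], colony[1], colony[2] + 0.0045)
  expect_equal(d, 6371000 * 0.0045 * pi / 180, tolerance = 1e-6)
  # symmetry
  expect_equal(great_circle_distance(146, -38, 147, -39),
               great_circle_distance(147, -39, 146, -38))
})

test_that("split_trips recovers known excursions and handles boundaries", {
  cfg <- sim_config(n_days = 3, overnight_roost_prob = 0)
  co <- simulate_cohort(sim_config(n_males = 1, n_females = 0, n_days = 3,
                                   overnight_roost_prob = 0), seed = 19)
  dep <- co$deployments[[1]]
  trips <- split_trips(dep$track, cfg$colony_lonlat)
  truth <- dep$truth$trips
  expect_equal(nrow(trips), nrow(truth))
  expect_true(all(abs(as.numeric(trips$departure_time) -
                        as.numeric(truth$departure)) <= cfg$gps_interval_s))
  expect_true(all(abs(as.numeric(trips$return_time) -
                        as.numeric(truth$return)) <= cfg$gps_interval_s))
  expect_true(all(trips$complete))

  # track never leaving the buffer: zero trips, not an error
  still <- make_track(rep(colony[1], 10), rep(colony[2], 10))
  expect_equal(nrow(split_trips(still, colony)), 0)

  # a fix at exactly 500.0 m is inside (ties toward the colony)
  d500 <- 500 / (6371000 * pi / 180)          # degrees north for 500 m
  tr <- make_track(rep(colony[1], 3), colony[2] + c(0, d500, 0))
  expect_equal(nrow(split_trips(tr, colony, 500)), 0)
})

test_that("trip fixes tile the track: no fix lost or duplicated between trips", {
  co <- simulate_cohort(sim_config(n_males = 1, n_females = 0, n_days = 3,
                                   overnight_roost_prob = 0), seed = 23)
  dep <- co$deployments[[1]]
  trips <- split_trips(dep$track, sim_config()$colony_lonlat)
  # interior (strictly outside buffer) fix indices per trip are disjoint and
  # jointly cover every outside fix
  dist <- great_circle_distance(dep$track$lon, dep$track$lat,
                                146.6758, -38.9403)
  outside <- which(dist > 500)
  covered <- unlist(lapply(seq_len(nrow(trips)), function(k) {
    (trips$i_first[k] + 1):(trips$i_last[k] - 1)
  }))
  expect_equal(sort(intersect(covered, outside)), outside)
  expect_false(any(duplicated(covered)))
})

test_that("trip statistics: square and out-and-back geometries", {
  km <- 1000 / (6371000 * pi / 180)            # degrees per km (meridional)
  # out-and-back 10 km due north (fix every km)
  lat_out <- colony[2] + c(0, 1:10, 9:0) * km
  tr <- make_track(rep(colony[1], length(lat_out)), lat_out)
  trips <- split_trips(tr, colony)
  trips <- trip_stats(tr, trips, colony)
  expect_equal(trips$max_distance_km, 10, tolerance = 1e-3)
  expect_equal(trips$total_distance_km, 20, tolerance = 1e-3)

  # square: out 1 km north, 1 km east leg, back south, west home (4 legs)
  mlat <- km
  mlon <- 1000 / (6371000 * pi / 180 * cos(colony[2] * pi / 180))
  lon <- colony[1] + c(0, 0, mlon, mlon, 0)
  lat <- colony[2] + c(0, mlat, mlat, 0, 0)
  tr2 <- make_track(lon, lat)
  t2 <- trip_stats(make_track(lon, lat),
                   split_trips(tr2, colony), colony)
  expect_equal(t2$total_distance_km, 4, tolerance = 2e-3)
})

test_that("overnight roost detection follows the midnight + stationarity rule", {
  cfg <- sim_config(n_males = 1, n_females = 0, n_days = 2,
                    overnight_roost_prob = 1)
  co <- simulate_cohort(cfg, seed = 29)
  dep <- co$deployments[[1]]
  trips <- split_trips(dep$track, cfg$colony_lonlat)
  trips <- detect_overnight_roost(dep$track, trips, cfg$tz_offset_h)
  truth <- dep$truth$trips
  expect_equal(trips$overnight_roost, truth$roost)
  expect_true(any(trips$overnight_roost))

  # day trip (returns before sunset) is never a roost trip
  cfg0 <- sim_config(n_males = 1, n_females = 0, n_days = 1,
                     overnight_roost_prob = 0)
  co0 <- simulate_cohort(cfg0, seed = 29)
  t0 <- split_trips(co0$deployments[[1]]$track, cfg0$colony_lonlat)
  t0 <- detect_overnight_roost(co0$deployments[[1]]$track, t0, cfg0$tz_offset_h)
  expect_false(any(t0$overnight_roost))

  # crossing midnight while continuously moving > 200 m per window: no roost
  n <- 24 * 12                                  # 24 h of 5-min fixes
  step <- 400 / (6371000 * pi / 180)            # 400 m north per fix
  lat <- colony[2] + c(0, cumsum(rep(step, n - 2)), 0)
  lat[n] <- colony[2]
  tr <- make_track(rep(colony[1], n), lat, t0 = "2021-10-01T08:00:00Z")
  trips2 <- split_trips(tr, colony)
  trips2 <- detect_overnight_roost(tr, trips2, 11)
  expect_false(any(trips2$overnight_roost))
})

test_that("departure/return histograms bin by local hour and conserve counts", {
  mk <- function(dep_hours_local, tz = 11) {
    data.frame(
      departure_time = as.POSIXct("2021-10-01 00:00:00", tz = "UTC") +
        (dep_hours_local - tz) * 3600,
      return_time = as.POSIXct("2021-10-01 00:00:00", tz = "UTC") +
        (dep_hours_local - tz + 5) * 3600,
      complete = TRUE, sex = "M")
  }
  one <- mk(7 + 10 / 60)                        # departs 07:10 local
  h <- departure_return_histograms(one, 11)
  expect_equal(h$departures[h$hour == 7], 1)
  expect_equal(sum(h$departures), 1)

  # a 07:00-peaked schedule has modal departure bin 7, counts conserved
  set.seed(1)
  hrs <- pmin(pmax(stats::rnorm(200, 7.5, 0.45), 0), 23.9)
  many <- mk(hrs)
  hm <- departure_return_histograms(many, 11)
  expect_equal(sum(hm$departures), 200)
  expect_equal(sum(hm$returns), 200)
  expect_equal(hm$hour[which.max(hm$departures)], 7)
})
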