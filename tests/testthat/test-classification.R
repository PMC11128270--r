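test_that("dive-location interpolation is linear in time", {
  tr <- make_track(c(0, 0.02), c(0, 0), interval_s = 600)
  # exactly at a fix
  at <- interpolate_dive_location(tr, tr$timestamp[1])
  expect_equal(at$lon, 0)
  # temporal midpoint -> spatial midpoint
  mid <- interpolate_dive_location(tr, tr$timestamp[1] + 300)
  expect_equal(mid$lon, 0.01)
  expect_equal(mid$lat, 0)
  # outside the track span
  expect_error(interpolate_dive_location(tr, tr$timestamp[2] + 1),
               class = "divetrip_range_error")
  # wide gaps flagged low confidence (nominal interval 300 s, gap 3600 s)
  tr2 <- make_track(c(0, 0.001, 0.002, 0.003, 0.5), c(0, 0, 0, 0, 0))
  tr2$timestamp[5] <- tr2$timestamp[4] + 3600
  lc <- interpolate_dive_location(tr2, tr2$timestamp[4] + 1800)
  expect_true(lc$low_confidence)
  expect_false(any(interpolate_dive_location(tr2, tr2$timestamp[2] + 100)$low_confidence))
})

test_that("dive locations recovered within GPS noise", {
  cfg <- sim_config(n_days = 1, overnight_roost_prob = 0)
  co <- simulate_cohort(sim_config(n_males = 1, n_females = 1, n_days = 1,
                                   overnight_roost_prob = 0), seed = 37)
  for (id in names(co$deployments)) {
    dep <- co$deployments[[id]]
    loc <- interpolate_dive_location(dep$track, dep$truth$dives$start)
    err <- great_circle_distance(loc$lon, loc$lat,
                                 dep$truth$dives$lon, dep$truth$dives$lat)
    expect_lt(stats::median(err), 2 * cfg$gps_noise_sd_m)
  }
})

test_that("classify_dive applies the three criteria in order", {
  # neighbour within 10%: |20-19| = 1 <= 0.1 * 20
  r1 <- classify_dive(20, prev_max_depth_m = 19, next_max_depth_m = 30,
                      seafloor_depth_m = 35)
  expect_equal(r1$dive_class, "benthic")
  expect_equal(r1$criterion_fired, "consecutive_10pct")

  # shallow bathymetry: seafloor 8 < 10
  r2 <- classify_dive(6, seafloor_depth_m = 8)
  expect_equal(r2$dive_class, "benthic")
  expect_equal(r2$criterion_fired, "shallow_bathy")

  # all criteria fail -> pelagic
  r3 <- classify_dive(20, prev_max_depth_m = 10, next_max_depth_m = 35,
                      seafloor_depth_m = 40)
  expect_equal(r3$dive_class, "pelagic")
  expect_equal(r3$criterion_fired, "none")

  # depth-vs-bathymetry: |18-21| = 3 < 5
  r4 <- classify_dive(18, seafloor_depth_m = 21)
  expect_equal(r4$criterion_fired, "depth_vs_bathy")

  # a missing neighbour is skipped, not fatal
  r5 <- classify_dive(20, prev_max_depth_m = NA, next_max_depth_m = 19.5,
                      seafloor_depth_m = 40)
  expect_equal(r5$criterion_fired, "consecutive_10pct")
})

test_that("making the seafloor shallower never flips benthic to pelagic", {
  set.seed(11)
  for (k in 1:200) {
    d <- stats::runif(1, 2, 40)
    prev <- if (stats::runif(1) < 0.8) stats::runif(1, 2, 40) else NA
    nxt <- if (stats::runif(1) < 0.8) stats::runif(1, 2, 40) else NA
    sf_far <- d + stats::runif(1, 5, 30)
    cls_far <- classify_dive(d, prev, nxt, sf_far)$dive_class
    # move the seafloor toward the dive depth in steps
    for (sf in seq(sf_far, d, length.out = 5)) {
      cls <- classify_dive(d, prev, nxt, sf)$dive_class
      if (cls_far == "benthic") expect_equal(cls, "benthic")
      cls_far <- cls
    }
  }
})

test_that("deployment classification recovers the generator's labels", {
  cfg <- sim_config(n_males = 2, n_females = 0, n_days = 1,
                    overnight_roost_prob = 0)
  co <- simulate_cohort(cfg, seed = 41)
  acc <- c()
  for (id in names(co$deployments)) {
    dep <- co$deployments[[id]]
    ex <- extract_dives(dep$pressure)
    trips <- split_trips(dep$track, cfg$colony_lonlat)
    cl <- classify_deployment(ex$dives, dep$track, trips, co$bathy)
    truth <- dep$truth$dives
    expect_equal(nrow(cl$dives), nrow(truth))
    acc <- c(acc, cl$dives$dive_class == truth$class)
    # determinism
    cl2 <- classify_deployment(ex$dives, dep$track, trips, co$bathy)
    expect_identical(cl$dives$dive_class, cl2$dives$dive_class)
  }
  expect_gt(mean(acc, na.rm = TRUE), 0.95)
})

test_that("an all-benthic generator is recovered as 100% benthic", {
  cfg <- sim_config(n_males = 1, n_females = 1, n_days = 1,
                    benthic_fraction = 1, overnight_roost_prob = 0)
  co <- simulate_cohort(cfg, seed = 43)
  for (id in names(co$deployments)) {
    dep <- co$deployments[[id]]
    ex <- extract_dives(dep$pressure)
    trips <- split_trips(dep$track, cfg$colony_lonlat)
    cl <- classify_deployment(ex$dives, dep$track, trips, co$bathy)
    expect_equal(cl$benthic_fraction, 1)
  }
})

test_that("edge dives of a trip can still be classified via bathymetry", {
  # single dive in its trip: no neighbours at all, |12 - 13| < 5 -> benthic
  r <- classify_dive(12, NA, NA, 13)
  expect_equal(r$dive_class, "benthic")
  # dives over a missing bathymetry cell with no matching neighbour are
  # unclassifiable, not silently pelagic
  g <- bathy_grid(matrix(20, 2, 2), 0, 0, 0.01)   # tiny grid
  tr <- make_track(c(0.01, 5), c(0.01, 5), interval_s = 600)
  dv <- data.frame(i_first = 1, i_last = 1,
                   start = tr$timestamp[2] - 1, end = tr$timestamp[2],
                   max_depth_m = 30, duration_s = 1)
  cl <- classify_deployment(dv, tr, data.frame(), g)
  expect_equal(cl$n_unclassifiable, 1L)
  expect_true(is.na(cl$dives$dive_class))
})
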