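test_that("synthetic bathymetry has the required structure", {
  cfg <- sim_config()
  g <- generate_bathymetry(cfg)
  expect_lt(min(g$depth), 10)
  expect_gte(max(g$depth), 40)
  expect_true(all(g$depth >= 0))
  # colony inside the grid
  expect_false(is.na(bathy_depth_at(g, cfg$colony_lonlat[1], cfg$colony_lonlat[2])))
  # the shallow basin is contiguous around the NW corner: the corner cell and
  # a sizeable NW block are all < 10 m (the field is monotone along NW->SE)
  nw <- g$depth[(g$n_rows - 10):g$n_rows, 1:11]
  expect_true(all(nw < 10))
  expect_gt(mean(g$depth < 10), 0.05)
  # deterministic
  expect_identical(g$depth, generate_bathymetry(cfg)$depth)
})

test_that("flat-depth override gives a constant field", {
  g <- generate_bathymetry(sim_config(flat_depth_m = 25))
  expect_true(all(g$depth == 25))
})

test_that("non-positive resolution is a configuration error", {
  expect_error(sim_config(bathy_cellsize_deg = 0), class = "divetrip_config_error")
})

test_that("deployment simulation is deterministic and validates input", {
  cfg <- sim_config(n_days = 1)
  b <- generate_bathymetry(cfg)
  ind <- simulate_individuals(cfg, 1)
  d1 <- simulate_deployment(ind[1, ], cfg, b, seed = 9)
  d2 <- simulate_deployment(ind[1, ], cfg, b, seed = 9)
  expect_identical(d1$track, d2$track)
  expect_identical(d1$pressure, d2$pressure)
  expect_identical(d1$truth$dives, d2$truth$dives)

  bad <- ind[1, ]
  bad$mass_kg <- -1
  expect_error(simulate_deployment(bad, cfg, b, seed = 1),
               class = "divetrip_validation_error")
})

test_that("generated dives honour the stated world", {
  cfg <- sim_config(n_days = 2, overnight_roost_prob = 0.5)
  b <- generate_bathymetry(cfg)
  ind <- simulate_individuals(cfg, 2)
  dep <- simulate_deployment(ind[1, ], cfg, b, seed = 11)
  dv <- dep$truth$dives
  expect_gt(nrow(dv), 100)

  # every dive carries exactly one class label
  expect_true(all(dv$class %in% c("benthic", "pelagic")))

  # diving only in daylight at the dive location
  elev <- solar_elevation(dv$start, dv$lon, dv$lat)
  expect_true(all(elev > 0))

  # benthic dives track the seafloor at the true location
  ben <- dv[dv$class == "benthic", ]
  expect_true(all(abs(ben$max_depth_m - ben$seafloor_m) <=
                    3 * cfg$depth_noise_sd_m + 1e-9))
  # pelagic dives stay well clear of it
  pel <- dv[dv$class == "pelagic", ]
  if (nrow(pel) > 0) {
    expect_true(all(pel$seafloor_m - pel$max_depth_m > 5))
  }

  # depth record non-negative after removing sensor artefacts is not required
  # of the raw signal, but true depths are
  expect_true(all(dv$max_depth_m > 0))
})

test_that("benthic_fraction = 1 labels every dive benthic", {
  cfg <- sim_config(n_days = 1, benthic_fraction = 1)
  b <- generate_bathymetry(cfg)
  ind <- simulate_individuals(cfg, 3)
  dep <- simulate_deployment(ind[1, ], cfg, b, seed = 4)
  expect_true(all(dep$truth$dives$class == "benthic"))
})

test_that("realized benthic fraction is consistent with the configured rate", {
  # male deployments (deep habitat, so the 'forced benthic over very shallow
  # water' rule almost never bites); ~2000 dives
  cfg <- sim_config(n_males = 3, n_females = 0, n_days = 2,
                    overnight_roost_prob = 0)
  co <- simulate_cohort(cfg, seed = 21)
  dv <- truth_dive_table(co)
  n <- nrow(dv)
  k <- sum(dv$class == "benthic")
  ci <- stats::binom.test(k, n, p = 0.96, conf.level = 0.99)$conf.int
  expect_true(ci[1] <= 0.96 && 0.96 <= ci[2])
})

test_that("trip durations match the configured mean over many trips", {
  # >= 100 day-trips; roosting disabled so every trip is a plain day trip
  cfg <- sim_config(n_males = 6, n_females = 6, n_days = 9,
                    overnight_roost_prob = 0)
  co <- simulate_cohort(cfg, seed = 31)
  dur <- unlist(lapply(co$deployments, function(d) {
    tr <- d$truth$trips
    as.numeric(tr$return - tr$departure, units = "hours")[tr$complete]
  }))
  expect_gte(length(dur), 100)
  se <- stats::sd(dur) / sqrt(length(dur))
  expect_lt(abs(mean(dur) - cfg$trip_duration_mean_h), 3 * se)
})

test_that("diet simulation honours probabilities and identifiability", {
  cfg <- sim_config(diet_n_samples = 79, identifiable_fraction = 0.86)
  pool <- default_species_pool()
  pool$p_male[pool$species == "pipefish"] <- 0
  pool$p_female[pool$species == "pipefish"] <- 0
  d <- simulate_diet_samples(cfg, pool, seed = 5)

  # a zero-probability species never appears
  expect_false("pipefish" %in% d$species)

  # identifiable count within the exact binomial 99% CI of 0.86
  n_ident <- length(unique(d$sample_id[d$identifiable]))
  ci <- stats::binom.test(n_ident, 79, p = 0.86, conf.level = 0.99)$conf.int
  expect_true(ci[1] <= 0.86 && 0.86 <= ci[2])

  # determinism
  d2 <- simulate_diet_samples(cfg, pool, seed = 5)
  expect_identical(d, d2)

  # invalid probabilities rejected
  pool$p_male[1] <- 1.5
  expect_error(simulate_diet_samples(cfg, pool, seed = 5),
               class = "divetrip_validation_error")
})
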