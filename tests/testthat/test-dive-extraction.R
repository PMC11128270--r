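test_that("zero-offset correction removes constant and leaves clean data alone", {
  # constant +0.5 m offset on an all-surface record
  s <- make_series(rep(0.5, 3600))
  z <- zero_offset_correct(s)
  expect_true(all(z$depth_m == 0))

  # offset-free series unchanged within 1e-9
  depths <- rep(0, 2000)
  depths[500:520] <- c(seq(2, 20, length.out = 10), rep(20, 2),
                       seq(20, 2, length.out = 9))
  s2 <- make_series(depths)
  z2 <- zero_offset_correct(s2)
  expect_lt(max(abs(z2$depth_m - depths)), 1e-9)

  # idempotence
  z3 <- zero_offset_correct(z2)
  expect_lt(max(abs(z3$depth_m - z2$depth_m)), 1e-9)

  expect_error(zero_offset_correct(make_series(numeric(0))),
               class = "divetrip_validation_error")
})

test_that("drifting offset is removed well enough to recover max depths", {
  # linear drift 0 -> 1 m over 24 h, dives to a known 20 m every 20 min
  n <- 24 * 900                       # 24 h at 4 s
  t_rel <- (seq_len(n) - 1) * 4
  depths <- rep(0, n)
  starts <- seq(600, 24 * 3600 - 120, by = 1200)
  for (s0 in starts) {
    i <- which(t_rel >= s0 & t_rel <= s0 + 60)
    prof <- 20 * pmin(1, pmin((t_rel[i] - s0) / 20, (s0 + 60 - t_rel[i]) / 20))
    depths[i] <- pmax(depths[i], prof)
  }
  drift <- t_rel / (24 * 3600)
  s <- make_series(depths + drift)
  z <- zero_offset_correct(s)
  d <- detect_dives(z)
  expect_equal(nrow(d), length(starts))
  expect_lt(max(abs(d$max_depth_m - 20)), 0.1)
})

test_that("detect_dives segments threshold crossings exactly", {
  s <- make_series(c(0, 2, 4, 4, 2, 0))
  d <- detect_dives(s, min_depth_m = 1)
  expect_equal(nrow(d), 1)
  expect_equal(as.numeric(d$raw_first - s$timestamp[1]), 4)
  expect_equal(as.numeric(d$raw_last - s$timestamp[1]), 16)
  expect_equal(d$max_depth_m, 4)

  expect_equal(nrow(detect_dives(make_series(rep(0, 10)))), 0)

  # single-sample dives are retained
  d1 <- detect_dives(make_series(c(0, 3, 0)))
  expect_equal(nrow(d1), 1)
  expect_equal(d1$i_first, d1$i_last)
})

test_that("detect_dives matches the brute-force oracle on random series", {
  set.seed(42)
  for (rep in 1:1000) {
    depths <- round(stats::runif(30, 0, 3), 2)
    d <- detect_dives(make_series(depths), 1)
    o <- brute_force_dives(depths, 1)
    expect_equal(nrow(d), nrow(o))
    if (nrow(o) > 0) {
      expect_equal(d$i_first, unname(o[, 1]))
      expect_equal(d$i_last, unname(o[, 2]))
    }
  }
})

test_that("edge interpolation recovers the analytic zero crossing", {
  # descent line through (4,2),(8,4) crosses 0 at t=0; ascent through
  # (12,4),(16,2) crosses 0 at t=20; prior surface sample at t=0
  s <- make_series(c(0, 2, 4, 4, 2, 0))
  d <- interpolate_dive_edges(s, detect_dives(s, 1))
  expect_equal(as.numeric(d$start - s$timestamp[1]), 0)
  expect_equal(as.numeric(d$end - s$timestamp[1]), 20)
  expect_equal(d$duration_s, 20)
  expect_false(d$edge_fallback)

  # degenerate slope (first two samples equal) clamps to the previous
  # surface sample time
  s2 <- make_series(c(0, 3, 3, 0))
  d2 <- interpolate_dive_edges(s2, detect_dives(s2, 1))
  expect_equal(as.numeric(d2$start - s2$timestamp[1]), 0)
  expect_equal(as.numeric(d2$end - s2$timestamp[1]), 12)

  # duration always >= raw in-dive span; start within clamp bounds
  set.seed(7)
  for (k in 1:50) {
    depths <- c(0, round(stats::runif(8, 0, 10), 1), 0)
    dd <- detect_dives(make_series(depths), 1)
    if (nrow(dd) == 0) next
    dd <- interpolate_dive_edges(make_series(depths), dd)
    expect_true(all(dd$duration_s >=
                      as.numeric(dd$raw_last - dd$raw_first) - 1e-12))
    expect_true(all(dd$start <= dd$raw_first & dd$end >= dd$raw_last))
  }
})

test_that("dive summaries compute vertical distance and max depth", {
  s <- make_series(c(0, 2, 4, 4, 2, 0))
  d <- summarize_dives(s, interpolate_dive_edges(s, detect_dives(s, 1)))
  # edge legs 2 + 2 plus in-dive |4-2| + 0 + |2-4| = 8
  expect_equal(d$vertical_distance_m, 8)
  expect_equal(d$max_depth_m, 4)

  # monotone descent-ascent triangle: vertical distance = 2 * max depth
  tri <- c(0, 1.5, 3, 4.5, 6, 4.5, 3, 1.5, 0)
  s2 <- make_series(tri)
  d2 <- summarize_dives(s2, interpolate_dive_edges(s2, detect_dives(s2, 1)))
  expect_equal(d2$vertical_distance_m, 2 * 6)
})

test_that("post-dive intervals follow from consecutive dives", {
  s <- make_series(c(0, 5, 5, 0, 0, 0, 0, 5, 5, 0))
  d <- post_dive_intervals(interpolate_dive_edges(s, detect_dives(s, 1)))
  expect_equal(nrow(d), 2)
  expect_equal(d$post_dive_s[1],
               as.numeric(d$start[2]) - as.numeric(d$end[1]))
  expect_gt(d$post_dive_s[1], 0)
  expect_true(is.na(d$post_dive_s[2]))

  # single dive: interval undefined
  s1 <- make_series(c(0, 5, 0))
  d1 <- post_dive_intervals(interpolate_dive_edges(s1, detect_dives(s1, 1)))
  expect_true(is.na(d1$post_dive_s))

  # overlapping dives are an integrity error
  fake <- d
  fake$end[1] <- fake$start[2] + 10
  expect_error(post_dive_intervals(fake), class = "divetrip_integrity_error")
})

test_that("durations + surface intervals tile the record (telescoping)", {
  co <- cohort_with_truth(13, n_males = 1, n_females = 0, n_days = 1)
  dep <- co$deployments[[1]]
  ex <- extract_dives(dep$pressure)
  d <- ex$dives
  n <- nrow(d)
  expect_gt(n, 50)
  total <- sum(d$duration_s) + sum(d$post_dive_s[-n])
  expect_equal(total, as.numeric(d$end[n]) - as.numeric(d$start[1]))
})

test_that("extraction recovers the generator's dives", {
  co <- cohort_with_truth(17, n_males = 1, n_females = 1, n_days = 1)
  for (id in names(co$deployments)) {
    dep <- co$deployments[[id]]
    ex <- extract_dives(dep$pressure)
    truth <- dep$truth$dives
    expect_equal(nrow(ex$dives), nrow(truth))
    # max depths within ZOC residual + sensor noise
    expect_lt(stats::median(abs(ex$dives$max_depth_m - truth$max_depth_m)), 0.15)
    # post-dive intervals within one sampling interval of truth
    n <- nrow(truth)
    err <- abs(ex$dives$post_dive_s[-n] - truth$postdive_s[-n])
    expect_lt(stats::median(err), 4)
  }
})
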