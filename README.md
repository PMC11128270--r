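# divetrip

Dive-record and GPS-track analysis for central-place foraging seabirds.

Benthic-foraging cormorants breeding on island colonies leave two
complementary data streams: a time-depth recorder sampling pressure every
4 s and a GPS logger fixing position every 5–10 min. `divetrip` turns those
raw streams, plus a bathymetry grid and regurgitate diet samples, into the
standard foraging-ecology deliverables:

* **Dive extraction** — rolling-quantile zero-offset correction, threshold
  dive detection, linear interpolation of dive edges to the surface
  (durations at 4 s are otherwise underestimated), per-dive maximum depth,
  duration, vertical distance and post-dive surface interval.
* **Trip segmentation** — a 500 m buffer around the colony splits the track
  into foraging trips with duration, total and maximum distance, and an
  overnight-roost flag (trip spans local midnight away from the colony with
  a ≥2 h stationary night window).
* **Benthic/pelagic classification** — each dive located by linear track
  interpolation, seafloor depth read from bathymetry, and classed benthic
  iff its maximum depth is within 10% of a neighbouring dive's, the
  seafloor is <10 m, or |depth − seafloor| < 5 m; otherwise pelagic.
* **Aerobic dive limit (ADL)** — the lower 5% envelope of post-dive
  interval vs dive duration, with a continuous two-segment (broken-stick)
  fit; the breakpoint is the behavioural ADL when the second slope exceeds
  3× the first and an F-test supports the extra segment. Detected ADLs are
  regressed on body mass.
* **Spatial overlap** — Gaussian-kernel utilization distributions (UD) of
  dive locations per sex and year (h = 0.01 in degrees), 95% kernel home
  ranges, and Bhattacharyya's affinity BA = Σ√(p·q) ∈ [0, 1] between male
  and female UDs.
* **Diet** — frequency of occurrence (proportion of identifiable samples
  containing a species), numerical abundance, and whole-prey length
  summaries by sex and year.
* **Effort** — hourly dive rate (m·h⁻¹ vertical distance per hour of clock
  coverage) and solar day/night flags.

A synthetic-data generator (`sim_config()`, `simulate_cohort()`) produces
bathymetry, individuals, tracks, pressure series and diet tables with known
ground truth, so every stage has a parameter-recovery test.

## Worked example

```r
library(divetrip)

cfg    <- sim_config(n_males = 2, n_females = 2, n_days = 2, seed = 42)
bathy  <- generate_bathymetry(cfg)
cohort <- simulate_cohort(cfg, bathy, seed = 42)

dep <- cohort$deployments[["M01"]]
ex  <- extract_dives(dep$pressure)
head(ex$dives[, c("start", "duration_s", "max_depth_m", "post_dive_s")], 3)
#>                 start duration_s max_depth_m post_dive_s
#> 1 2021-09-30 20:04:37   47.54026    17.17943    20.69996
#> 2 2021-09-30 20:05:45   42.23208    16.92018    34.25735
#> 3 2021-09-30 20:07:02   65.78439    17.00850    38.02653
```

564 dives are detected for this male (median maximum depth 15.8 m). Trips,
classification and ADL:

```r
trips <- split_trips(dep$track, cfg$colony_lonlat)          # 500 m buffer
trips <- trip_stats(dep$track, trips, cfg$colony_lonlat)
trips[, c("trip_id", "duration_h", "total_distance_km", "max_distance_km")]
#>       trip_id duration_h total_distance_km max_distance_km
#> 1 M01_trip001    9.06384          46.38199        14.23091
#> 2 M01_trip002   10.87208          51.28060        14.09708

cl <- classify_deployment(ex$dives, dep$track, trips, bathy)
cl$benthic_fraction
#> [1] 0.95

estimate_adl(ex$dives)
#> ADL detected at 60.0 s (slopes 0.24 -> 1.54, F = 95.4, 563 pairs)
```

The benthic fraction recovers the generator's 96% rate (0.95 here over one
bird), and the estimated ADL of 60 s sits within one 8-s envelope bin of
this individual's true ADL (62.1 s). Sex overlap on the pooled cohort:

```r
dv <- do.call(rbind, lapply(names(cohort$deployments), function(id) {
  d <- cohort$deployments[[id]]$truth$dives
  d$sex <- substr(id, 1, 1); d$year <- cfg$year; d
}))
sex_overlap_by_year(dv)
#>   year           ba n_male n_female
#> 1 2021 3.933669e-26    834      936
```

BA ≈ 0 — males and females forage in disjoint habitat under the default
(segregated) configuration; setting `sex_mixing = 1` sends both sexes to
shared shallow hotspots and drives BA above 0.9.

## Full pipeline and CLI

```r
run_pipeline(list(seed = 1, simulate = TRUE, out_dir = "out",
                  sim = list(n_males = 2, n_females = 2, n_days = 2)))
```

writes `dives.csv`, `trips.csv`, `adl.csv`, `overlap_by_year.csv`,
`hourly_effort.csv`, diet summaries, the simulated truth tables, the
bathymetry grid, and a `report.json` with per-stage counts and timings.
Re-running with the same seed reproduces every CSV byte for byte. A thin
command-line wrapper lives at `inst/cli/divetrip.R`
(`run-all`, `simulate`, `extract-dives`, `split-trips` subcommands).

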