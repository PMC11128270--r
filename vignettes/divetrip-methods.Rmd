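---
title: "divetrip: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{divetrip: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`divetrip` analyses combined GPS / time-depth-recorder (TDR) deployments from
colonial diving seabirds — the archetype being a benthic-foraging cormorant
breeding on an island colony in a shelf sea — together with regurgitate diet
samples. This vignette records the models, the parameters that matter, the
numerical choices, and what the synthetic-data tests do and do not establish.

## The analysis chain

1. **Zero-offset correction (ZOC).** Pressure sensors drift, so the surface
   reads a non-zero depth. We estimate the surface baseline as a rolling low
   quantile (default 0.05) of depth in a sliding window (default 2 h, split
   into 12 blocks; per-block quantile, running minimum over the window,
   linear interpolation between block centres), subtract it and clip at 0.
   Any 2-h window of a cormorant record contains genuine surface time, so
   dive-dense blocks cannot inflate the baseline. The correction is
   idempotent: after one pass the surface sits at exactly 0 and the block
   quantiles vanish.

2. **Dive detection.** A dive is a maximal run of samples deeper than the
   threshold (default 1 m). The threshold matters for shallow-diving females
   (median depths near 8 m, with dives into the 1–3 m range); it is exposed
   everywhere and single-sample dives are retained, since discarding them
   would bias the shallow tail.

3. **Edge interpolation.** At a 4-s sampling interval the first in-dive
   sample is already ~1 bodylength down. The dive start is the zero-depth
   crossing of the line through the first two in-dive samples, clamped
   between the previous surface sample and the first in-dive sample; the end
   is symmetric. When the surface crossing falls between samples, the
   preceding sub-threshold sample has positive depth and the clamp truncates
   the extrapolation by up to (threshold / descent rate) seconds — an
   irreducible ambiguity of threshold sampling, which is why the
   exact-recovery test uses profiles whose crossings coincide with sample
   instants. Single-sample dives fall back to the raw span ± half an
   interval and are flagged.

4. **Summaries.** Vertical distance is Σ|Δdepth| over in-dive samples plus
   the two edge legs (first and last sample depth). Both depth and vertical
   distance are underestimates at 4 s; no correction is attempted, matching
   standard practice.

5. **Trip segmentation.** A 500-m buffer around the colony delimits trips; a
   fix at exactly the buffer distance is *inside* (ties break toward the
   colony, so zero-length trips cannot occur). Departure/return instants are
   interpolated linearly in distance-to-colony between the bracketing fixes.
   Incomplete trips (no observed departure or return) keep their statistics
   but are excluded from duration summaries.

6. **Overnight roosts.** The field observation is birds staying out
   overnight on islets. The paper-level behaviour ("roosted away from the
   colony overnight") has no printed criterion, so ours is explicit and
   configurable: the trip spans a local midnight outside the buffer AND
   contains a ≥2-h night window (solar elevation < 0 throughout) whose net
   displacement is < 200 m.

7. **Dive classification.** Each dive is located by linear interpolation of
   the track at its start instant (start vs midpoint is configurable;
   differences are far below the GPS noise), the seafloor depth is read from
   the bathymetry by bilinear interpolation, and the dive is benthic iff
   (a) its maximum depth is within 10% of the previous *or* subsequent
   dive's within the same trip — 10% of the larger of the two depths, the
   symmetric reading; (b) the seafloor is < 10 m; or (c) |dive depth −
   seafloor| < 5 m. Criteria are ORed but evaluated in that order so each
   dive records which criterion fired. Dives over missing bathymetry that no
   neighbour matches are *unclassifiable*, never silently pelagic.

8. **Aerobic dive limit (ADL).** The behavioural ADL is the dive duration
   beyond which post-dive surface recovery accelerates. The published
   constraint-lines procedure lives in an unprinted supplement, so this
   package defines a reproducible variant and documents it as a
   methodological stand-in: bin durations (default 8 s = two sampling
   intervals), take the 0.05 quantile of post-dive interval per bin (≥5
   points per bin, ≥50 pairs, intervals > 600 s discarded as rests), then
   fit a continuous two-segment line over candidate breakpoints at interior
   bin centres. Detection requires the second slope to exceed 3× the first
   *and* an F-ratio ≥ 10 for the two extra parameters. These thresholds were
   calibrated so that no-inflection controls yield a false-detection rate
   below 5% (measured at 0–2% in the test suite). Partial detectability is
   expected and mirrors field experience: individuals whose recorded dives
   never exceed their ADL are reported `detected = FALSE`, not forced.
   Detected ADLs are regressed on body mass by OLS.

9. **Space use.** Dive locations are pooled per sex and year, smoothed with
   an isotropic Gaussian kernel (h = 0.01, in decimal degrees, matching the
   common practice of smoothing unprojected coordinates; a projected
   equal-area workflow is preferable for new studies) on a shared 200×200
   grid with a 5h margin, and normalized to a utilization distribution (UD).
   The 95% home range is the smallest cell set by descending density
   reaching 0.95 mass. Overlap is Bhattacharyya's affinity
   BA = Σ√(p·q) over the full UDs (the standard definition); masking both
   UDs to their 95% contours first is available as an option because
   "overlap of home ranges" is sometimes computed that way. Pooling
   locations per sex (rather than averaging individual UDs) is the package's
   explicit choice; both conventions appear in the literature.

10. **Diet.** Frequency of occurrence is presence-based over identifiable
    samples; numerical abundance divides each species' total count by *all*
    identifiable samples in the group (the "per sample" reading of the
    ambiguous parenthetical definition; the per-occurrence denominator is a
    flag away). Prey-length summaries use whole items only, all species
    combined. The mixed-model analysis of prey length is deliberately out of
    scope; the package emits the tidy table such a model would consume.

11. **Effort.** The dive rate (m·h⁻¹ of vertical distance) is aggregated per
    individual × local clock hour, dividing by the record's coverage of that
    hour; covered hours without dives count 0, uncovered hours are absent.
    Dives are assigned to hours by midpoint. The circular-smoother GAMM of
    the original analysis is out of scope; a mean ± SE plot is provided.

## The synthetic world

The generator (`sim_config()`, `simulate_cohort()`) is a stated world, not a
tuning dial. Its defaults encode the field situation the pipeline targets:

* colony at 146.6758°E 38.9403°S; pressure every 4 s; GPS every 5 min;
* 96% of dives benthic; sex-typical foraging depths with medians 18 m (M)
  and 8 m (F), induced by habitat choice, not by drawing depths directly;
* mean day-trip duration 11.5 h; departures shortly after sunrise; optional
  overnight roosts (default probability 0.4 ≈ 184/455 trips);
* true ADL = 20 + 20·mass(kg) s, giving ≈54 s at typical masses;
* depth noise SD 0.2 m (truncated at ±3σ so benthic dives never stray from
  the seafloor by more than 0.6 m), GPS noise 30 m, sensor drift 0.5 m per
  deployment, sensor noise 0.03 m per sample.

Bathymetry is a deterministic smooth field: a shallow (1–15 m) basin to the
north-west of the colony grading to a 20–40 m shelf in the south-east, with
mild sinusoidal texture — the geometry of a shallow embayment beside a deeper
shelf. Tracks are out-and-back trips to a destination patch: females pick
cells near their median depth in the shallow band, males in the deep band,
each followed by an Ornstein–Uhlenbeck walk at the patch. The `sex_mixing`
parameter emulates a high-overlap year: mixed trips converge on a small,
deterministic set of shared shallow hotspots, cycled across trips, because
overlap in the field arises from both sexes tracking the same prey
aggregations — independent random shallow destinations would keep
Bhattacharyya affinity low even at full mixing.

Dives happen only while the sun is above the horizon (NOAA-style solar
position; "daylight" = elevation > 0°, refraction ignored). Benthic dives
touch the local seafloor; pelagic dives are drawn at 25–55% of the water
column and only where the seafloor is ≥ 12 m, because a "pelagic" dive over
very shallow water both contradicts the physics (< 5 m of clearance) and is
unidentifiable by the classification criteria. Post-dive intervals follow
`a + b·duration + c·(duration − ADL)₊` plus exponential noise — a linear
hinge rather than an exponential penalty, because the estimator fits a
two-segment line and an exponential's near-zero slope at the breakpoint
would bias recovery upward; the published generative relation is unknown, so
this is explicitly a stand-in.

**What a green test establishes.** Recovery tests show the pipeline inverts
*this* generator at realistic noise: dive boundaries exactly, trip
boundaries within one GPS interval, class labels at ≥95% accuracy, ADL
within ±10% over replicates, segregation/mixing scenarios on the right side
of 0.2/0.6. They do not validate the 10%-neighbour criterion against real
bottom phases, the quantile-envelope ADL against the original constraint-line
algorithm (an alternative estimator can be swapped in behind
`estimate_adl()`), or kernel smoothing in degrees near coastlines. Real
records also contain haul-out pressure artefacts, gappy GPS, and
device-failure truncation that the generator only partially emulates
(drift, noise, and incomplete final trips are included; gaps are not).

## Numerical choices and degenerate inputs

* Distances are haversine on a 6,371-km sphere; degree↔metre conversions
  for noise use the local metres-per-degree at the colony latitude.
* Timestamps must be timezone-aware ISO-8601; naive timestamps are rejected
  because an 11-hour silent error would corrupt every daylight flag. All
  internal arithmetic is UTC; local hours use a configurable fixed offset
  (default +11, AEDT).
* Bathymetry is ESRI ASCII grid (elevation, sea negative); GeoTIFF would
  require a raster stack not available here. Land cells clamp to depth 0
  with a counted warning; grids whose coordinates cannot be geographic are
  rejected rather than guessed at.
* Empty series, < 5 KDE points, < 50 ADL pairs, < 3 regression points,
  constant mass designs, and tracks that never leave the buffer all return
  typed error signals or empty results — never NA-laden silent output.
* The breakpoint grid excludes the outer two envelope bins so both segments
  always have ≥ 2 support points; ADL resolution is therefore one bin width
  (8 s by default).
* `fit_kde` normalizes over the evaluation grid, so mass that a wide kernel
  would place outside the grid is folded back by renormalization; grids are
  built with a 5h margin to keep that distortion ≪ the 1e-6 mass tolerance.

## Known limitations

* The 10% neighbour criterion inherits the paper's asymmetric information:
  single dives between two much deeper/shallower dives can only be rescued
  by bathymetry.
* Kernel UDs in lon/lat degrees distort at this latitude (1° lon ≈ 0.78° lat
  in metres); fine for within-study comparisons, not for area estimates.
* The roost criterion (2 h, 200 m) is a package convention; sensitivity to
  it should be checked before ecological interpretation.
* The ADL envelope uses a fixed 0.05 quantile; heavy-tailed surface
  intervals (rafting, preening) are handled by the 600-s cap rather than by
  modelling the interval mixture.
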