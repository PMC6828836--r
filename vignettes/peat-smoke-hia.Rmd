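---
title: "From fire hotspots to attributable mortality: the peathaze model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From fire hotspots to attributable mortality: the peathaze model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

peathaze estimates the long-term mortality burden that recurrent peatland-fire
smoke imposes on a rural tropical population, at the resolution of individual
villages. The chain has five stages: synthetic input generation, smoke
dispersion, station calibration, village exposure extraction, and the health
impact assessment proper. This vignette explains the model in each stage, the
parameters that matter, the numerical choices, and what the synthetic world
does and does not capture.

## The assessment chain

Satellite fire detections ("hotspots", one per ~1 km² pixel with a 0-100
detection confidence) are filtered to confidence ≥ 80, classified as shallow
(depth codes D1-D2, 50-200 cm) or deep peat (D3-D4, > 200 cm) by
point-in-polygon lookup in a peat map, and a random subset per class and year
is run through a dispersion model. The per-hotspot plumes are averaged into a
class-mean plume, multiplied by the class's annual hotspot count, placed
spatially according to where that class's hotspots occurred, and the resulting
annual surface is calibrated to the one ground monitoring station in the
region. Village annual means, their multi-year average X, and the regional
minimum X_o then drive concentration-response functions that convert exposure
into relative risk, attributable fraction and attributable deaths per disease
category and age group.

```{r}
library(peathaze)
cfg <- pipeline_config(seed = 1)   # the study-scale preset
res <- run_pipeline(cfg, out_dir = "peathaze_out")
res$exposure_summary
format_impact_table(res$impact)
```

## The dispersion surrogate

Full Lagrangian transport modelling driven by archived global meteorology is
deliberately out of scope: the contribution exercised here is the assessment
chain, and the station-calibration step (part of the method itself) absorbs
any absolute-scale error of the transport model. In its place peathaze uses a
transparent Gaussian-puff surrogate with the assessment's published runtime
and deposition assumptions:

| parameter | default | unit | role |
|---|---|---|---|
| `release_duration` | 24 | h | continuous release; peat fires burn for a day or more |
| `averaging_period` | 24 | h | output is a 24-h mean concentration |
| `plume_layer_top` (H) | 100 | m AGL | layer over which concentrations are averaged |
| `dry_deposition_velocity` (v_d) | 0.001 | m/s | first-order surface loss, applied as v_d/H |
| `wet_scavenging_rate` (Λ) | 8.0e-5 | 1/s | first-order wet loss, applied unconditionally |
| `horizontal_diffusivity` (K) | 8000 | m²/s | effective mesoscale spread, σ² = σ₀² + 2Kt |
| `initial_sigma_m` (σ₀) | 400 | m | source footprint of a ~1-km detection pixel |
| `emission_rate` | 1 | arbitrary/s | cancelled exactly by calibration |

A hotspot releases one puff per hour for `release_duration` hours. A puff of
age t has horizontal variance σ² = σ₀² + 2Kt, is displaced by t·(u, v) with
the (daily-constant) wind, is vertically uniform over H, and its mass decays
by exp[−(v_d/H + Λ)t]; with the defaults the 1-hour survival fraction is
exp(−9·10⁻⁵·3600) ≈ 0.7233. The 24-h mean field is the average of hourly
snapshots. Because the wind is constant within a run, a (release, evaluation)
pair contributes only through the puff age, so the implementation groups the
~600 pairs into 24 age classes — a 25-fold saving that the tests verify
against a brute-force pairwise summation at 1e-10 relative tolerance.

The wet-scavenging rate is applied with no precipitation switch because the
method specifies a single constant rate with no precipitation coupling. K and
σ₀ are surrogate-specific: K = 8000 m²/s is large for pure turbulent
diffusion but here also absorbs the sub-daily wind meander that a
daily-constant wind cannot express.

Two choices deserve emphasis:

* **Recentred class-mean plumes.** An "average plume of a peat-fire hotspot"
  is only meaningful in source-relative coordinates, so per-hotspot plumes
  are computed on a source-centred grid and averaged cell-wise within each
  peat class. `scale_up()` then re-places the mean plume by convolving it
  (FFT, zero-padded so the convolution is exactly linear) with the spatial
  density of all retained hotspots of the class, and multiplies by the
  class's annual count. Averaging in absolute coordinates instead is
  available by passing fields without the `recentered` attribute.
* **Single-factor calibration.** Each annual field is multiplied by
  k = (observed station annual mean) / (modelled value at the station cell),
  making the modelled station value exact by construction. One factor per
  year, from one station, because one station is all that exists in the
  emulated setting. This makes the final fields invariant to the arbitrary
  emission-rate units — a property the tests check directly.

## Exposure extraction

Fields live on a 1-km grid (cell-centre convention, values are cell means).
A village's annual mean is the area-weighted mean of cell values over its
polygon — exact for the axis-aligned rectangles used throughout, and reducing
to a plain mean of covered cells for the cell-aligned tile villages the
generator produces. The period mean X is the unweighted mean of annual means;
the reference concentration X_o is the minimum village period mean across the
whole region (a single region-wide reference, matching the definition of the
lowest observed concentration; a per-district variant can be had by
subsetting villages before calling `summarize_exposure()`). Threshold
summaries use strictly-below 10, at-or-above 20, and strictly-above 80
µg/m³, matching the guideline phrasing they mirror. Exposure here is the
*fire-attributable PM2.5 increment*: non-fire ambient background is out of
scope, and months without fires contribute zero.

Whether village means should be population- or area-weighted within a
village is not specified in the underlying method; area weighting is
implemented, and the subdivision invariance test (splitting a village into
four leaves the population-weighted regional mean unchanged) documents the
consequence.

## Health impact model

For a village with period-mean exposure X and reference X_o:

* log-linear form: RR = [(X + 1)/(X_o + 1)]^β
* linear-exponential form: RR = exp[β(X − X_o)]

Both give RR(X_o) = 1; for X < X_o the RR is clamped to exactly 1 so no
negative burden is attributed. AF = RR(X) − 1, not capped at 1 (a warning is
emitted when it exceeds 1, which the largest exposures do reach under the
lung-cancer coefficient). Attributable deaths are
AF × CDR × percent-of-deaths × (population × age-fraction), with the crude
death rate CDR = 0.0058 per person-year. The default category table:

| category | form | β per µg/m³ | % of deaths | age group (fraction) |
|---|---|---|---|---|
| all-cause | linear | 0.001829 (= 0.0008 × 48/21) | 100% | all (100%) |
| chronic respiratory | linear | 0.003794 (= 0.00166 × 48/21) | 4% | under 5 (10%) |
| cardiovascular | log-linear | 0.15515 | 33% | adults 30+ (44.5%) |
| lung cancer | log-linear | 0.23218 | 2% | adults 30+ (44.5%) |

The two linear coefficients are PM10 values renormalised by the exact
rational 48/21 (the Indonesian PM10/PM2.5 ratio); full precision is kept
internally and six decimals are used for display only. 0.1551 is an accepted
alternative cardiovascular coefficient via `health_cases(cardiovascular_beta =
0.1551)`.

Each category is reported twice, mirroring the dual accounting in the
underlying method: an all-ages row (attributable deaths on the full
population base) and an age-group row (the same burden scaled by the age
fraction, rated per 100,000 of the age-group population). The headline uses
the all-ages row. Aggregation is always on unrounded per-village values;
rounding (half-up) to whole deaths happens only in the printed table, and a
test demonstrates that round-then-sum and sum-then-round differ.

The sensitivity analysis re-runs the assessment with each category's form
swapped between log-linear and linear-exponential, with village exposures
shifted ±10 µg/m³ (floored at 0), and with X_o fixed at the 10 µg/m³
guideline value, reporting percent changes on unrounded totals (rounding
first makes small percentages unstable).

A convexity caveat: exp[β(X − X_o)] is convex in X for any β, so spreading
exposure across villages at a fixed mean never lowers those totals — this is
why a homogeneous-exposure run bounds the village-resolved all-cause total
from below. The log-linear form with β < 1, however, is *concave* in X; both
default log-linear coefficients are below 1, so for the cardiovascular and
lung-cancer categories heterogeneity can lower the total. The property tests
exercise convexity on the convex forms and assert the concave counter-case
explicitly.

## The synthetic world

The generator replaces satellite, meteorological and administrative inputs
with a rectangular 120 × 120 km region on a projected km grid:

* **Peat map** — four rectangles (D1-D4, ~22% of the region) placed in all
  four quadrants so that no part of the region is far from potential
  sources; the largest deep and shallow polygons adjoin near the
  south-east-centre, emulating one intensively drained and burned area.
* **Hotspots** — exact configured counts per year and class (deep exceeding
  shallow by 8% when split from per-year totals), with integer confidences
  uniform on 0-100 so both retained and discarded records exist, dates
  weighted 6:1 toward the July-November dry season, and locations drawn as a
  cluster-plus-background mixture: 50% around the class cluster centres
  (SD 6.5 km), the rest uniform over the class polygons.
* **Villages** — rectangles of whole grid cells tiling the region exactly
  (1569 in the study preset), with log-normal populations (σ_log = 1.1,
  emulating one dominant town) rescaled to sum exactly to 2.5 million;
  10% of each village is under 5 and 44.5% is 30 or older.
* **Meteorology** — one wind vector and mixing height per day; speeds around
  1.8 m/s and directions effectively uniform, reflecting weak, variable
  dry-season flow with no single transport direction at the daily scale.
* **Station** — a daily PM2.5 series whose annual means equal the configured
  observations exactly (seasonal profile plus noise, rescaled); the preset
  uses (28, 30, 22, 45, 65) µg/m³ for 2011-2015 — a 65 µg/m³ extreme year
  and a 38 µg/m³ five-year mean — at a site on the shoulder of the
  high-exposure zone, as a provincial-capital monitor would be.

With these defaults the preset reproduces the dynamic range the assessment
operates over: village period means span roughly 1-115 µg/m³ (covering the
5-100 µg/m³ band the design targets), a regional mean near 26 µg/m³, and a
handful of extreme villages above 80 µg/m³ next to the burned area.

What the synthetic world does *not* emulate: real geography and
administrative boundaries; multi-day haze accumulation and regional
recirculation, which in reality lift the exposure floor so that almost every
village exceeds 10 µg/m³ — the synthetic surface has a heavier low tail
(many villages below 10) and a lower X_o (~1-2 µg/m³), which in turn
inflates the log-linear categories relative to a world with X_o ≈ 4;
detection physics (confidences are uniform rather than skewed high); and
cross-border smoke import, which is excluded by design. Passing tests
therefore validate the arithmetic and the model properties, not the realism
of any particular exposure map.

## Numerical choices and problem sizes

* Grid convention: cell centres, values are cell means, 1-km spacing; field
  CSVs are written at 17 significant digits so grids round-trip bit-exactly.
* FFT convolution is zero-padded to full linear-convolution size; tiny
  negative round-off values (below 1e-9 of the field maximum) are clamped
  to zero to preserve non-negativity.
* The study preset samples 15 hotspots per class and year for plume
  averaging (the published workflow's 100 per class is configurable via
  `n_per_class`); because same-day plumes are identical in source-relative
  coordinates and are cached per day, the class-mean plume stabilises
  quickly, and a full preset run takes well under a minute on one core.
* Sampling seeds derive from the master seed (per-year offsets), so a
  configuration file plus seed fully determines every output file; the
  tests verify report-bundle hashes across reruns.
* Degenerate inputs: a year with no retained hotspots produces a zero
  increment field and skips calibration (which would otherwise divide by a
  zero station value and is an error when attempted directly); an empty
  peat class is an error naming the class; villages that miss the grid are
  errors naming the village.

## Known limitations

Morbidity, years of life lost, and age-specific death rates are out of scope
(one crude death rate, category shares of it). The RR coefficients are
cohort-derived constants; no uncertainty intervals are propagated. The
surrogate has no chemistry, terrain, or precipitation coupling. Annual
averaging hides the strong seasonality of smoke, a recognised source of
unsigned bias in the underlying method.
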