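---
title: "Source-water risk screening: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Source-water risk screening: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swrisk)
```

`swrisk` couples two screening models used in drinking-water source
protection: a quantitative hazard-quotient screen of monitoring data against
water-quality standards, and a qualitative source–proximity–extent (S × P ×
E) matrix that ranks land-use activities by their potential to impair raw
water, sub-watershed by sub-watershed. This vignette explains both models,
the conventions and parameters the implementation fixes, what the synthetic
generator does and does not emulate, and the known limitations.

## The quantitative model

For a parameter with an upper concentration limit, the hazard quotient is

$$\mathrm{HQ} = \frac{\text{exposure concentration}}{\text{safe threshold}},$$

with HQ > 1 meaning exposure exceeds the allowable limit. Two exposures are
screened per station × parameter: the pooled sample mean (`hq_avg`, the
chronic screen) and the observed maximum (`hq_max`, the acute screen). HQ is
a ratio of like units, so each parameter's monitoring values and threshold
must share units; the registry records them.

Three conventions matter and are fixed here:

* **Rounding.** HQs are carried unrounded through the pipeline and rounded
  half away from zero to two decimals only at the reporting boundary
  (`format_hq_table()`, `render_reports()`). Rounding inside the pipeline
  would compound; half-up matches how regulatory tables are printed (base
  R's half-to-even would turn 87.45 into 87.4).
* **Exceedance.** Flags use the strict comparison HQ > 1.0 on the unrounded
  value.
* **Two-sided and lower-bounded parameters.** pH (range 6.5–8.5) and
  dissolved oxygen (≥ 6.5 mg/L) admit no meaningful ratio-to-limit; a
  reciprocal "DO hazard quotient" would invert the direction of harm. They
  are reported with an absent HQ (rendered "-") plus `range_within` (did the
  summary min/max stay in bounds) and, when raw records are available,
  `range_compliance()` — the fraction of samples inside the allowed
  interval.

### Censored summaries

Monitoring series contain non-detects. `summarize_monitoring()` makes the
treatment explicit via a `policy` flag: `detected_only` (default), or
substitution of 0, DL/2, or DL per non-detect. The default is
`detected_only` because published summary tables that report n and
n-detected separately, with ranges starting at the smallest *detected*
value, are only consistent with detected-only statistics. The policy is a
flag everywhere precisely because this choice is not universal: DL/2
substitution is the common alternative, and for heavily censored series the
policies diverge (the suite checks the ordering
substitute_zero ≤ substitute_half_dl ≤ substitute_dl on the mean).
Statistics pool all samples per station × parameter; no monthly weighting
or trend adjustment is applied, matching routine screening practice.

### Standards registry

The built-in registry (`default_standards()`) ships two sets: `class_a`
surface-water criteria (the conservative choice for source water, since raw
water is treated before consumption but screening should flag watershed
pollution potential) and `drinking` water standards. Cells the regulations
leave unspecified are absent, and lookup distinguishes "no standard exists"
(`swrisk_not_found`) from a malformed registry (`swrisk_config_error`).
Parameter labels are normalized through an alias table; two deliberate
mappings:

* Total coliform counts are screened against the 50 CFU/100 mL Class A
  *E. coli* value — the convention the published screening tables
  themselves use. The regulatory intent is ambiguous (the standards table
  labels the row *E. coli*, the screening table reports total coliforms);
  we follow the arithmetic actually used.
* "Solids" is two parameters: suspended solids (Class A, ≤ 25 mg/L) and
  total dissolved solids (drinking, ≤ 500 mg/L). They are never
  cross-compared.

## The qualitative model

Each source in a sub-watershed is scored 1–4 on three factors and the
product R = S × P × E (range 1–64) is banded low (≤ 6), medium (≤ 9),
high (≤ 16), very high (> 16). The scale is comparative — it sorts issues
by risk potential; R = 64 is not "four times" R = 16.

* **S** from two booleans: pathogen potential and major/minor, giving 4
  (major pathogen source) down to 1 (minor non-pathogen source).
* **P** from the riparian buffer zone: 0–50 m → 4, 50–250 m → 3,
  250–1,000 m → 2, > 1,000 m → 1.
* **E** from the activity's percent of the sub-watershed's own total area:
  ≥ 1% → 4, 0.1–1% → 3, 0.01–0.1% → 2, < 0.01% → 1.

Conventions fixed here, because the printed bin labels overlap at shared
endpoints:

* Buffer-zone bins are closed on the upper edge ([0, 50], (50, 250],
  (250, 1000], (1000, ∞)). Any consistent convention reproduces the
  worked-example areas, since no area sits exactly on a boundary; one had
  to be chosen and documented.
* Extent bins are lower-inclusive with a top clamp (everything ≥ 1%,
  including extents above the nominal 10% cap, maps to 4).
* Band boundaries are upper-inclusive (R = 16 is high, 16.01 very high), as
  the "≤ 16 / > 16" definitions state.

Aggregation over zones is the unweighted arithmetic mean of the per-zone
products, **excluding zones where the activity is absent**: a vacuous zone
contributes no exposure pathway and averaging in its R would dilute the
score of a source concentrated in the riparian band. The published worked
example averages four zones, but all four have non-zero area there, so it
cannot discriminate between the conventions; `include_empty_zones = TRUE`
restores strict four-zone averaging. An activity absent from every zone is
a no-exposure case: flagged, banded low, aggregate NA.

Two further interpretive choices:

* Sources whose footprint is not meaningfully areal (scattered recreation
  spots along a creek) take declared levels instead of computed ones:
  `source_characterization()` accepts `p_override`/`e_override`, mirroring
  the practice of assigning recreation E = 1 and P = 4 by judgement.
* Multiple sources in one sub-watershed are assessed independently and
  reported side by side; `rollup_sources()` offers an optional unweighted
  mean across sources, flagged interpretive because published score maps do
  not state their combination rule.

## The spatial engine

Buffer zones come from a per-cell Euclidean distance to the nearest stream
cell (cell centre to cell centre, scaled by cell size), computed by the
exact Euclidean distance transform in `EBImage::distmap()`. The test suite
holds this equal to an exhaustive minimum-over-all-stream-cells oracle on
randomized grids, and checks monotonicity (adding stream cells never
increases a distance). Distance is straight-line, not flow-path: the model
input is "distance from the closest source water", and flow routing is out
of scope. Whether the stream mask includes reservoir cells is the user's
choice — proximity "to water" can reasonably include both.

Zone areas are cell counts × cell area; conservation (the four zone areas
of a class sum to the class's total area per sub-watershed) is exact in
integer cell counts. Areas are carried in m² internally; land-use basin
tables use km² and say so in their column names. Rasters are exchanged as
ESRI ASCII grids (a plain-text format; reader/writer included since no
raster package is assumed), and a pre-tabulated zone-area CSV bypasses the
raster path entirely so that qualitative assessments can be run on
published or GIS-derived areas directly.

## The synthetic generator

`gen_monitoring()` emulates a routine monthly sampling programme:
concentrations are lognormal — strictly positive, right-skewed, consistent
with monitoring summaries whose means sit far below their maxima — with an
optional multiplicative seasonal modulation
`1 + a·sin(2π(month − phase)/12)` (the observed summer rise of suspended
solids motivates the form; no functional form is published, so a sinusoid
is an assumption). Values below the detection limit become non-detects.
`gen_watershed()` rasterizes a stream polyline, rectangular activity
patches over a background class, and vertical-band sub-watersheds —
enough structure to exercise every spatial code path with known analytic
answers.

What the generator does **not** emulate: spatial correlation of land use,
autocorrelated or rainfall-driven concentration series, laboratory
measurement error distinct from environmental variance, multiple detection
limits per series, and flow-dependent dilution. Tests passing on synthetic
data therefore demonstrate correctness of the computations, not validity of
the screening models for any particular real watershed.

Problem sizes used in the checks: distribution-recovery checks run at
10,000 monthly samples against closed-form lognormal moments (3-standard-
error bands); the distance-transform equivalence runs on 100 random grids
up to 50 × 50. Both finish in seconds.

## Numerical notes and limitations

* `round_half_up()` adds a 1e-9 relative nudge before truncation so that
  values stored just below a representable .5 round as printed tables do.
* The published screening table is internally consistent except one cell:
  the A008 total phosphorus average HQ prints 1.42, while the printed mean
  (0.028) over the 0.02 mg/L threshold gives 1.40. The published figure was
  evidently computed from the unrounded mean (≈ 0.0284). Since raw samples
  are unpublished, only the summary → HQ step is verifiable; the suite
  checks that cell within the rounding half-width the 3-decimal printed
  mean implies (± 0.025) and every other cell exactly.
* Basin land-use totals printed to one decimal can shift a recomputed
  percentage by up to one least-significant digit (e.g. a "Total" column
  water-area share recomputing as 2.4% against a printed 2.3%); percentage
  reproduction is therefore checked to ± 0.1.
* Sub-watershed delineation is out of scope: grids arrive with their
  sub-watershed labels. So are carcinogenic slope-factor risk, multi-pathway
  exposure, Monte Carlo risk ranges, and weighting schemes beyond the
  unweighted mean.
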