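---
title: "Partitioning dendrometer series into growth and tree water deficit: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning dendrometer series into growth and tree water deficit: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendropart)
```

## The problem

Automatic band dendrometers record stem circumference continuously at
micrometre resolution. The measured signal confounds two processes:
irreversible radial growth (cell division and enlargement) and the
reversible shrinking and swelling of elastic tissues as the stem's water
pools are depleted by transpiration and refilled from the soil. In
water-limited (Mediterranean) climates the reversible component can dwarf
the growth signal for months, so separating the two is the precondition for
any statement about when, how much, and under which hydrometeorological
conditions trees grow.

`dendropart` implements the zero-growth partition of a stem-diameter series
and every metric layer built on it: annual phenology and duration metrics,
seasonal bimodality, normalized response surfaces over the drought plane,
and hour-of-day growth decomposition. A coupled synthetic climate-and-stem
generator with an exact truth ledger makes the whole pipeline testable
without access to field data.

## The zero-growth partition

Let $D(t)$ be stem diameter (µm; circumference readings are divided by
$\pi$ at ingest) and $M(t) = \max_{s \le t} D(s)$ its running maximum. The
zero-growth concept assumes no irreversible growth occurs while the stem is
shrunken below its historical maximum. Then

$$\mathrm{GRO}(t) = \max\{0,\; D(t) - M(t-1)\}, \qquad
  \mathrm{TWD}(t) = M(t) - D(t).$$

GRO is the non-negative increment beyond the previous maximum; TWD (tree
water deficit) is the depth of the current depression, a proxy of
stem water-pool depletion. Three structural identities follow and are
asserted by `validate_outputs()` on every run: $D + \mathrm{TWD} -
\sum \mathrm{GRO}$ is constant; $\mathrm{GRO} > 0 \Rightarrow \mathrm{TWD}
= 0$; and $M$ is non-decreasing. The first observation initialises
$M = D$, GRO $= 0$, TWD $= 0$ — a convention, which is why test fixtures
that require exact hour-level symmetry prepend a warm-up reading. Missing
hours are simply absent rows: the running maximum carries across a gap and
any growth during it is credited to the first observation after it.

A note on a boundary case: when a stem recovers from deficit and then
exceeds its old maximum in one step (e.g. 10, 12, 11, 13), the step first
cancels the standing deficit and only the excess over the old maximum (1
µm, not 2) counts as growth. Any other attribution breaks the conservation
identity.

## Climate drivers

Sub-hourly station records are aggregated to hourly values (means of air
temperature, relative humidity and soil water content; rainfall summed).
Two drought axes are derived:

* **VPD** (kPa), atmospheric drought, from the FAO-56 Tetens saturation
  curve: $e_s(T) = 0.6108\,\exp(17.27\,T/(T+237.3))$, $\mathrm{VPD} =
  e_s(T_\mathrm{air})(1 - \mathrm{RH}/100)$. Humidity overshoots up to
  100.5 % are clamped (sensor drift); anything further is an error.
* **REW** (unitless), soil drought: soil water content linearly rescaled
  between the site-specific minimum and field capacity,
  $\mathrm{REW} = (\mathrm{SWC}-\mathrm{SWC_{min}})/(\mathrm{SWC_{max}} -
  \mathrm{SWC_{min}})$. If no calibration is supplied the extremes of the
  monitored record are used. Values outside $[0,1]$ are clamped and
  counted (`attr(, "n_clamped")`).

Daily drivers are the medians of the hourly values per day. All timestamps
are local standard time with no daylight-saving shifts, so clock hours stay
solar-anchored — this matters for the diel windows below.

## Quality control

A tree-year is excluded when a temporal gap or a run of exactly constant
readings *exceeding* 7 days overlaps the growing-season gate window. The
gate window is a fixed calendar interval (default DOY 60–330) rather than
the estimated season, to avoid the circularity of needing growth metrics
before QC. Runs are measured in hours on the year's full hourly grid, so
partial coverage counts as a gap; a run of exactly 7 days is kept.
Constancy means exact equality of consecutive readings (`flat_tol = 0`),
which is detectable at 1 µm sensor resolution.

## Annual metrics

Per kept tree-year: annual GRO (sum of hourly increments over the calendar
year); GRO~START~/GRO~END~, the first days of year at which the end-of-day
cumulative growth reaches 5 % and 95 % of the annual total (ties to the
earliest day); GRO~LENGTH~ their difference; GRO~DAYS~ and GRO~HOURS~, the
counts of days/hours with positive growth over the whole year (not only
inside the 5–95 % window); TWD~MAX~ and TWD~CUM~ (hourly maximum and hourly
integral, µm·h — hourly being the native resolution); and TWD:GRO~LENGTH~,
the percentage of days within the season with no growing hour. For the
latter the denominator is the inclusive day count of the season
(GRO~END~ − GRO~START~ + 1): with growth on every season day the metric is
exactly 0 %, which the open-interval denominator cannot produce. An
alternative definition (days with TWD > 0) is available via
`shrink_day = "twd_positive"`.

Cumulative climate (REW~CUM~, VPD~CUM~) is summed from daily medians over
the calendar year and over the measurement-set median season window, where
a measurement set is a species-by-site combination and its window is the
median GRO~START~–GRO~END~ over kept tree-years.

## Seasonal layer and the bimodal split

Daily GRO and TWD are the within-day 99th percentiles of the hourly values
(a robust daily maximum; percentile convention: linear interpolation
between order statistics, pinned by tests against a hand-rolled oracle —
note that under this convention a single 2 µm hour among 24 zeros gives
1.54, not 2). Both series are smoothed with a centred 14-day running mean
(partial windows at the edges). The spring-to-autumn transition of bimodal
Mediterranean growth is the day the smoothed TWD reaches its maximum
(earliest on ties); the spring and autumn percentages split annual growth
at that day. Because percentages must partition the annual total, the split
is computed on summed daily growth, while the 99th-percentile series
remains the display/surface variable — the two choices coexist because the
percentile aggregate is not additive.

## Response surfaces over the drought plane

Daily GRO and TWD are normalized per tree by the 99th percentile across the
tree's whole multi-year record (values may exceed 1), pooled per
measurement set, and regressed on the daily (VPD, REW) pair with a local
polynomial estimator built from first principles: at each query point the
$\lceil \alpha n \rceil$ nearest observations (Euclidean distance after
standardizing each predictor to unit variance) receive tricube weights
$(1-(d/d_{max})^3)^3$ and a bivariate quadratic is fitted by weighted least
squares; the prediction is the fitted value at the query point
($\alpha = 0.75$, degree 2). A rank-deficient local quadratic falls back to
degree 1 at that node and is recorded in the output. Implementing the
estimator explicitly (rather than delegating) makes the neighbourhood,
weighting and fallback rules fully specified and testable: constants and
exact quadratics are reproduced to $10^{-8}$, and predictions match an
independent normal-equations solve at random nodes.

The admissible region (the hydrometeorological space) is the convex hull of
the daily (VPD, REW) cloud after discarding the $\lceil 1\% \rceil$ of
points farthest from the cloud centre — extreme conditions such as
heavy-rain saturation. Distances are measured on axes standardized to unit
variance, since kPa and unitless REW are not commensurable; this is one of
the genuinely open choices (raw-axis distances would over-weight whichever
axis has larger spread) and is stated rather than hidden. Grid predictions
are only reported inside the hull.

## Sub-daily layer

Per tree-year and clock hour $h$: growth probability (share of observed
hours at $h$ with GRO > 0), growth rate (mean GRO over growing hours at
$h$; conditional on growth), and contribution (share of annual GRO accrued
at $h$; sums to 100 across the 24 hours). Measurement-set trends are
per-hour medians across tree-years. Night/day averages use the inclusive
windows 21:00–7:00 (11 hour labels) and 8:00–20:00 (13 labels); the
night:day ratio is reported as `Inf` when the day mean is zero but the
night mean positive (strictly nocturnal growth) and `NA` only when both
vanish — a limit convention that keeps "nocturnal-only" distinguishable
from "no data".

The midnight-zeroed diel curve averages, over selected days (all days or
growing days), the hourly diameter deviation from the day's hour-0 reading;
days missing hour 0 are skipped. Shrinkage hours are counted on this mean
curve (not per day), as the number of hour steps where it declines. When
the curve is simple (a rising phase, one shrinking phase, optional
recovery) the first-maximum and subsequent minimum hours are reported;
curves with several shrink phases are flagged intermittent and the labels
withheld.

Hour-resolved growth surfaces reuse the same local regression on hourly GRO
normalized to the tree-specific 99th percentile of *positive* hourly GRO,
with zero-growth hours included as zeros, against (hour, VPD), (hour, REW)
and (VPD, REW); hour is a linear coordinate 0–23. Because the estimator's
cost grows with the number of observations, surfaces subsample inputs
beyond `max_points` (default 20 000) reproducibly under the run seed; with
hundreds of thousands of hourly observations the subsample changes
predictions negligibly relative to the estimator's own smoothing.

## The synthetic generator

The generator exists to give every pipeline stage a known truth, emulating
the data properties the pipeline is sensitive to, not full ecophysiology.

**Climate.** Hourly temperature = annual sinusoid (peak mid-July) + diel
sinusoid (peak 15:00) + AR(1) noise; relative humidity anti-correlated with
temperature, clamped to [5, 100]; rainfall as winter-skewed marked Poisson
events; soil water from a bucket that gains rain and loses
`et_coef · VPD · REW` per hour. Defaults (mean temperature 13 °C, 420 mm
rain per year, 100 mm bucket) produce the target regime: wet winters and a
summer in which REW spends most hours below 0.1, while spring almost never
does.

**Stem.** A hydraulic-capacitor model: elastic depletion $W$ gains
`k_t · VPD` during transpiration hours (default 8:00–20:00), loses
`k_r · REW` (refill) every hour, floored at 0 and capped at `w_max`
(400 µm: depletion saturates once elastic tissue approaches residual water
content — without the cap a deep drought leaves a pool too deep to refill
before the autumn window, which no real stem shows). Growth is gated by
phenology windows (spring DOY 70–184, autumn 245–320), a soil threshold
(REW > 0.15), optional diel gates (`night_only`, `uniform_hours`), and — in
strict mode — the condition $W = 0$. Annual growth is drawn from seasonal
budgets, `(1 − autumn_fraction)` and `autumn_fraction` of `annual_target`
(default 2000 µm/yr at up to 2 µm/h, a realistic Mediterranean diameter
increment), so the realized bimodal split is known and, when both budgets
exhaust, exact. Observed diameter is
$D_0 + \sum g - W$ plus optional Gaussian noise and 1 µm quantization.

Strict mode is the oracle: growth only occurs at $W = 0$, i.e. at a fresh
maximum, so the zero-growth partition recovers the true hourly growth and
depletion identically (up to float rounding at the 150 mm diameter scale,
observed below $10^{-10}$ µm relative). Relaxed mode
(`strict_zero_growth = FALSE`) allows turgor-limited growth
($g \propto e^{-W/\text{relax\_scale}}$) at small depletion; there the
partition is *biased by construction* — growth during shrinkage is
invisible to it — which is a feature for studying the method, not a bug.

**What the generator does not emulate.** Jumps from dendrometer
re-installation, thermal expansion of the band, multi-day rain-on-stem
artefacts, phloem osmotic dynamics, species-specific parameter fits. A
green test suite therefore certifies the *method implementation* on data
with known truth, not the pipeline's robustness to every field artefact;
the QC gate covers only the one-week gap/flat rule that the study design
specifies.

**A consequence worth knowing:** noise-free strict series contain genuinely
constant stretches (winter dormancy, exhausted budgets) that the QC flat
rule — correctly — rejects as week-long constancy. Oracle tests therefore
call the partition and metric functions directly on noise-free series,
while pipeline-level runs (`run_study()`) use observation noise (2 µm) and
quantization, which is also the realistic regime.

## The study driver

`run_study()` orchestrates simulate → QC → partition → annual → seasonal →
surfaces → diel, writes tidy CSVs and a JSON manifest (seed, parameter
echo, per-stage record counts), and is byte-reproducible under a fixed
config. `validate_outputs()` re-reads the emitted files and asserts the
cross-module invariants by name. The packaged analysis under `analysis/`
runs the same stages as numbered scripts with narrative output; sizes used
there and in the tests (4 trees × 3 years for exact recovery, 13 trees ×
12 years for the full-pipeline run) are the package's chosen demonstration
scales — the 13 × 12 hourly run (~1.4 M readings) completes in a few
minutes on one CPU.

## Numerical conventions and degenerate inputs

* Percentiles/medians: linear interpolation between order statistics.
* Phenology ties: earliest day; smoothed-TWD argmax ties: earliest day.
* Zero annual growth: phenology, bimodal split and contributions are
  undefined — reported as `NA` with a warning, never as 0.
* Zero-length season: TWD:GRO~LENGTH~ undefined (`NA`).
* A tree whose normalization quantile is 0 is excluded from surfaces with
  an error naming the reason; a tree with no positive hourly growth
  contributes zeros to hourly surfaces.
* Collinear point clouds raise a degenerate-hull error rather than
  returning a sliver polygon.
* REW clamping outside [0, 1] is counted, not silent.

## Known limitations

* The QC flat rule at `flat_tol = 0` relies on genuine sensor quantization;
  analog-smoothed loggers would need a tolerance.
* TWD~CUM~ integrates hourly TWD; with sub-hourly native data the value
  scales with the chosen step.
* The hull-trimming fraction excludes by central distance, which assumes a
  roughly convex cloud; strongly bimodal climates could see interior
  conditions excluded.
* Local regression at grid nodes near the hull boundary extrapolates from
  one-sided neighbourhoods; point density there is low and predictions
  correspondingly uncertain (the emitted grids carry `inside_hull` so
  consumers can mask further).
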