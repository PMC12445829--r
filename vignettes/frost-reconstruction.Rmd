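---
title: "Reconstructing late spring frost damage from tree rings, climate and phenology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing late spring frost damage from tree rings, climate and phenology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frostring)
```

## The problem

A late spring frost (LSF, or "false spring") is a sub-freezing night that
strikes after deciduous trees have flushed their leaves. Emerged leaves are
killed near −3 °C and below, the canopy must be rebuilt from reserves, and
the year's ring ends up narrow. Reconstructing which historical years had
damaging LSFs is hard: narrow rings are also caused by drought and other
shared stresses, phenological observations rarely reach back a century, and
frost damage depends on the match between the frost date and a leaf-out date
that itself must be modelled.

`frostring` combines three lines of evidence:

1. a process model of leaf-out driven by daily temperature and photoperiod,
2. a climate-side damage rule (frost at or below a threshold inside a window
   around predicted leaf-out), and
3. a tree-ring indicator that contrasts a frost-sensitive deciduous species
   with an evergreen reference species at the same site.

The indicator is the core idea. Both species integrate the same site
climate, so subtracting the reference-species chronology from each
sensitive-species tree's ring-width index (RWI) cancels the shared signal.
What survives is species-specific: frost defoliation hits the deciduous
species only (the evergreen keeps older, frost-hardy foliage), whereas
drought depresses both and cancels. The same host-versus-nonhost logic is
standard in dendroentomology for insect-outbreak detection.

## The leaf-out model

The M1 model accumulates photoperiod-weighted thermal forcing from day
`t0`:

$$R_i = \left(\tfrac{L_i}{10}\right)^{k} \cdot \max(T_i - T_b,\, 0), \qquad
S(d) = \sum_{i=t_0}^{d} R_i,$$

and predicts leaf-out on the first day with \(S(d) \ge F_{crit}\). `Ti` is
the daily **mean** temperature (°C) and `Li` the daylength in hours. The
photoperiod factor `(L/10)^k` suits species with strong photoperiod control
of spring phenology, such as European beech: with `k` large, forcing
accumulated under short early-spring days counts for little, which captures
why such species leaf out late — and, at high elevation, why long days can
push them out before temperatures are reliably frost-free.

Parameters, defaults, and constraints:

| parameter | units | constraint | meaning |
|---|---|---|---|
| `t0` | day of year | ≥ 1 (on/after 1 Jan) | start of forcing accumulation |
| `Tb` | °C | > 0 | base temperature |
| `k` | – | ≥ 0 | photoperiod exponent (0 = plain degree-day model) |
| `Fcrit` | forcing units | > 0 | accumulation threshold |

Calibration bounds default to `t0 ∈ [1, 90]`, `Tb ∈ (0, 10]`, `k ∈ [0, 10]`,
`Fcrit ∈ [1, 5000]`, a box that encloses published estimates for temperate
broadleaves (`default_m1_bounds()`). The two hard constraints — forcing only
after 1 January, positive base temperature — are enforced as configuration
errors.

### Numerical decisions

* **Daylength.** The model literature leaves the daylength formula
  unspecified. We use the CBM model of Forsythe et al. (1995) with the
  standard sunrise/sunset definition (solar depression 0.8333°); the
  depression angle is an argument, so civil-twilight daylength is one
  keyword away. Polar latitudes (>66.5°) are rejected rather than clamped.
* **Non-emergence during calibration.** A candidate parameter set may never
  reach `Fcrit`. Dropping such site-years would let the optimiser shrink its
  own training set; instead they are penalised with pseudo-day 250, keeping
  the objective bounded and steering the search back toward emitting
  predictions. Day 250 (early September) is late enough never to collide
  with a real leaf-out date.
* **Optimiser.** The calibration contract is "seeded derivative-free global
  minimiser of the prediction RMSE inside the bounds". The default is
  simulated annealing (starting temperature 10⁴, budget 40 000 objective
  calls, geometric cooling, reflecting proposals) over `(t0, Tb, k)` with
  `Fcrit` *profiled* analytically — set to the median accumulated forcing at
  the observed dates — followed by a coordinate-descent polish and a short
  final polish with `Fcrit` free. Profiling removes the strongest parameter
  ridge (any `(Tb, k)` change can be largely compensated by rescaling
  `Fcrit`), which is why recovery experiments judge *predictions*, not raw
  parameters: the objective is nearly flat along those ridges and several
  parameter sets predict identical dates.
* **Integer dates.** Predictions are integer DOY (first day the threshold is
  met); observations are rounded to whole days. The RMSE surface is
  therefore piecewise constant, which is why the polish is a shrinking-step
  coordinate search rather than a gradient method.
* **Leap years.** DOY is computed per calendar; predictions are compared on
  DOY without leap adjustment (≤ 1 d effect, below observation noise).
* **Cross-validation.** Folds partition site-years, are drawn once from the
  seed, and are invariant to input row order (observations are canonically
  sorted before assignment).

## The frost-risk rules

* **Threshold −1.0 °C, inclusive.** Screen-height gridded minima understate
  bud tissue temperature on clear radiative-cooling nights, so a mild
  screen-level threshold is deliberately inclusive; comparisons use `<=`
  everywhere for consistency.
* **Damage window −5…+14 d around predicted leaf-out, inclusive bounds.**
  Buds are still frost-hardy more than ~5 d before emergence; after
  emergence, vulnerability fades only gradually while frost probability
  drops sharply.
* **Last spring frost** is searched in DOY 1–181 (through June); the cutoff
  is configurable. The **safety margin** is leaf-out DOY minus last-frost
  DOY; negative margins mean frost struck after leaf-out.
* **Trends** are Theil–Sen slopes (median of pairwise slopes, reported per
  decade) with Sen's rank-based 95% interval and a two-sided Mann–Kendall
  test with tie correction. No autocorrelation correction is applied,
  matching standard usage for yearly phenological series; with ~90 yearly
  values and weak persistence the size distortion is small.
* The 10-yr moving average of the margin is centered (offsets −4…+5 for the
  even window) and requires ≥ 6 non-missing years.

## Tree-ring processing

* **Detrending** divides each core's widths by a smoothing-spline growth
  curve whose frequency response is 50% at a 30-yr wavelength. We implement
  the Cook–Peters formulation as the discrete penalised least-squares
  smoother with a second-difference penalty; its transfer function
  `H(ω) = 1/(1 + λ(2 − 2cos ω)²)` gives
  `λ = (1/f − 1)/(2 − 2cos(2π/nyrs))²` analytically, and the 50%-retention
  property is verified spectrally in the tests. Ratio (division) indices are
  used, making RWI dimensionless around 1; if a growth curve dips to zero
  the series falls back to a linear, then mean, fit with a warning.
* **Chronologies** average the two cores per tree arithmetically, then the
  trees with **Tukey's biweight** robust mean (tuning constant 9, median/MAD
  start, iterated to 1e-8 or 50 iterations — the conventions of the standard
  dendro toolchain). Sample depth is recorded and years below 6 trees are
  flagged. Quality statistics: rbar (mean pairwise correlation over ≥ 20
  overlapping years) and `EPS = n·rbar/(n·rbar + 1 − rbar)`.
* **Crossdating is assumed done upstream**; the package validates span
  contiguity only, and discarded cores are handled by an exclusion list.
* The Tucson/RWL reader treats only the *final* value of a series as the
  stop marker (999 → 0.01 mm, −9999 → 0.001 mm); a mid-series `999` in a
  0.001-mm file is a data value (0.999 mm).

## The indicator

Per sensitive tree: residual = tree RWI − reference chronology, standardised
to z-scores over the tree's full overlap with the chronology (the
standardisation window is a choice; whole-series is the least arbitrary and
matches how z-scoring is usually applied to complete series). A year is
called a frost year when at least 60% of the contributing trees have
`z < −1`, severe when the same fraction is below −1.5. Decisions:

* The supermajority rule is implemented as `>= 0.60`. With 12 trees the
  alternative strict reading (`> 60%`) differs only at exactly 7.2 trees,
  which is unattainable; the threshold is configurable.
* Years with fewer than 3 contributing trees are not evaluated, avoiding
  spurious fractions at low sample depth.
* The site-level *residual chronology* is a plain mean of the z series
  (unlike the biweight used for species chronologies): the z-scores are
  already standardised and outliers there are signal, not noise.
* The reference is the site-level reference-species chronology, not
  individual reference trees: the chronology integrates out tree-level
  noise, while individual sensitive trees are kept to capture the real
  within-population spread of frost damage.

Concordance with the climate/phenology rule is summarised per site as the
fraction of tree-ring-flagged years that also carry a damage-window frost;
for discordant years the spring frosts *outside* the window are listed as
candidate explanations (radiative-cooling nights can damage tissue at
screen-level temperatures above the threshold, and phenology-model error
shifts the window).

## Growth-climate response and legacy effects

* **Daywise correlation grids**: the chronology is correlated with a climate
  variable aggregated per year over every window (start DOY × window
  length); temperatures are averaged, precipitation is summed — the
  conventions of daily-resolution dendroclimatology. Default axes are starts
  1–270 and lengths 15–90 by 5. Cells are masked at raw p < 0.05 when
  requested; **no multiple-testing correction is applied across the grid**,
  so isolated significant cells must be read as exploratory (the type-I
  envelope is tested explicitly on white noise).
* **Superposed epoch analysis**: anomalies are departures from the
  chronology mean scaled by its SD; the null is built from `n_boot`
  resamples of equally many pseudo-event years drawn with replacement from
  all years with full lag coverage, and a lag is significant (two-tailed,
  5%) when the observed anomaly falls outside the null's 2.5–97.5%
  quantiles. Lags default to 0…+4: the event year plus the four following.

## What the synthetic generator does and does not emulate

`synthetic_config()` defaults describe one mid-elevation limestone-ridge
site: 91 years of daily climate from 1931; seasonal mean-temperature
sinusoid with the coldest day mid-January (mean 4.7 °C for the high site,
6.3 °C for a low site; half-amplitude 8.5 °C, so January ≈ −4 °C and July ≈
13 °C); AR(1) daily noise (lag-1 coefficient 0.7, marginal SD 3 °C); a
constant 8 °C diurnal range. Injected frost events lower `tmin` only, on one
night, emulating radiative-cooling nights with large daily amplitude.
Leaf-out observations derive from the known M1 parameters
(`t0 = 3, Tb = 0.29, k = 4.76, Fcrit = 1248`) plus Gaussian noise (7.5 d by
default, on the scale of volunteer-network site means). Ring series combine
a negative-exponential age trend (3 mm initial width, 2%/yr decay), one
shared standardised summer climate index (mean tmax of DOY 160–220, slope
0.3 on log width — this single index is what *guarantees* the
common-climatic-signal assumption the indicator needs), lognormal tree and
core noise (SD 0.2 and 0.1 on the log scale, keeping widths positive), and a
×0.4 frost-year multiplier on the sensitive species only. The 0.4 magnitude
is a modelling choice consistent with extreme defoliation years in which RWI
collapses below ~0.4; no published value fixes it. A drought switch reduces
both species equally for specificity tests.

The generator deliberately omits: spatial interpolation and lapse-rate
physics (sites differ by a constant offset), precipitation-driven growth,
chilling/dormancy effects on phenology, masting, age-dependent noise, and
missing rings. Passing tests therefore demonstrate that the *algorithms*
recover what this generative model encodes — not that real beech/spruce
pairs satisfy the common-signal assumption, which on real data is threatened
chiefly by masting years (sensitive-species growth collapses without frost)
and must be checked against climate evidence, as the concordance table does.

## Problem sizes used in validation

The recovery and power experiments are sized to run on one CPU in a few
minutes: M1 recovery uses 40 synthetic sites × 30 yr (1200 site-years) with
a 2500-call annealing budget, cross-validation 10 folds × 1000 calls;
indicator power uses 50 replicates of the full two-species, 12-tree, 91-yr
design; SEA uses 999 bootstrap resamples. The annealing default remains the
full 40 000-call budget for real calibrations.

## Known limitations

* The indicator cannot separate LSF from any *other* strictly
  species-specific growth collapse (masting being the obvious one); the
  climate/phenology concordance is the guard.
* z-scores are standardised over the full overlap, so a trend in the
  residuals (e.g. slowly diverging species performance under warming) would
  inflate the SD and mute detection late in the record.
* Mann–Kendall p-values ignore serial correlation; for strongly
  autocorrelated margins a block-resampling variant would be needed.
* The grid of daywise correlations is exploratory (no multiplicity
  control), and the SEA null assumes exchangeable years.
* Calibrated M1 parameters are reported as found, but only predictions are
  identifiable; do not interpret `Tb` or `k` in isolation.
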