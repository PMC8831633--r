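---
title: "Climate Stability Index: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Climate Stability Index: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(climstab)
```

## The model

The Climate Stability Index summarizes, per pixel, how much the local
climate moved over a set of time periods. For one bioclimatic variable the
raw signal is the per-pixel **sample standard deviation** (denominator
n − 1) of its values across periods; the **range** (max − min) is available
as an alternative statistic for sensitivity analysis. Dispersion layers are
min-max normalized per variable, a collinearity screen reduces the candidate
set to one representative per correlated group, and the index is the
per-pixel sum of the kept normalized layers, re-normalized to [0, 1]
(0 = most stable).

Assumptions worth making explicit:

* **One shared grid.** All layers must sit on a bit-identical grid (shape
  exact; affine transform equal to 1e-9 degrees). There is deliberately no
  resampling or reprojection: mixed grids are an error, because silently
  interpolating inputs would corrupt per-pixel temporal statistics.
* **Periods are exchangeable observations.** The SD treats the time periods
  as unordered draws; it measures spread, not trend. A monotone warming and
  an oscillation with equal spread get the same score. Trend-aware
  statistics are out of scope.
* **Normalization before summation.** Raw dispersions mix units (°C for
  temperature variables, mm for precipitation); precipitation magnitudes
  would otherwise dominate the sum. Per-variable normalization also makes
  the index invariant to any affine rescaling of a single variable's raw
  values, which the tests assert.
* **Strict NoData in the sum.** A pixel missing any kept layer is NoData in
  the index: a partial sum over fewer variables is not comparable across
  pixels.

### The two workflows

**Past.** One stack per variable across the paleoclimate periods (T1…T12 by
default; variables absent from the oldest periods are excluded by the
catalog, leaving 14 of 19). Sea level moved over these periods, so two
masking rules apply. (1) A *current-land mask* (most recent period as
template) removes pixels that are sea today but were emerged at glacial low
stands — most were emerged for a single period only, and any dispersion
value there would be an artifact of too few observations (spuriously
"stable"). (2) Current-land pixels that were *submerged during warm periods*
(T2, T4, T10 by default) are kept — they still have 9+ valid periods — but
flagged in a separate raster so users can judge whether the reduced coverage
matters. The flag annotates; only the land mask removes.

**Future.** Per SSP scenario, each future window holds an ensemble of GCM
projections. The per-pixel **median** over available members (mean as the
sensitivity alternative) collapses each variable × window to one layer;
members flagged unavailable in the roster are skipped, never imputed, and an
even member count uses the midpoint of the two central values. Dispersion is
then taken across the present baseline plus the four reduced windows
(5 periods), and composition proceeds as in the past workflow. The order —
reduce first, then dispersion — matters: dispersion across raw members would
mix inter-model disagreement into the temporal signal.

## Tunable parameters

| Parameter | Default | Units | Why this default |
|---|---|---|---|
| `statistic` | `"sd"` | — | Sample SD (n − 1), the conventional estimator invoked by the field's tooling; range kept for validation. Population vs sample SD is not distinguishable from the original description; sample SD is pinned here and surfaced in `dispersion_config()`. |
| `min_valid` | 2 | periods | A pixel needs at least two valid periods for any dispersion; one observation carries no spread information. Together with the land mask this reproduces both masking behaviours (remove glacial-only shelf; keep warm-period-submerged land). |
| `reducer` | `"median"` | — | Robust to a single outlier GCM; mean kept for validation. |
| `n_points` | 10,000 | points | Suited to a global 2.5 arc-min grid. On the 80×120 synthetic world only ~5,300 land pixels exist, so examples and tests use 2,000; `sample_points()` errors rather than silently reducing when the request exceeds the valid-pixel count. |
| `r_th` | 0.8 | — | Standard collinearity cut-off; 0.7/0.9 form the sensitivity sweep. Raising the threshold can only refine the grouping (tested property). |
| `warm_period_ids` | T2, T4, T10 | — | The interglacial periods of the default past map set; a config list so other datasets can redefine them. |
| `n_categories` | 32 | — | The published cartography's category count; equal-interval breaks are generated, custom break lists (e.g. top bin 0.71–1 past, 0.356–1 future) are user-supplied since only those two boundaries are published. |
| seeds | explicit | — | Sampling and per-group selection use independent, always-logged seeds; nothing is clock-derived. |

## Design choices where the design was open

* **Grouping = connected components** of the graph with edges where
  |r| > r_th. The original description says only "groups of correlated
  ones"; components are the minimal order-independent closure of pairwise
  exceedance, so a chain A–B–C groups together even if r(A,C) is small.
* **Absolute |r|** at the cut-off: strongly anti-correlated variables are
  equally redundant. Signed grouping is available
  (`correlated_groups(..., absolute = FALSE)`).
* **The screen runs on the normalized dispersion layers** — the quantities
  actually summed — not on raw climatologies. Any aligned layer list can be
  substituted via `remove_collinearity()` directly.
* **Deletion-mask polarity**: `lgm_del_mask.tif` stores 1 = pixel removed by
  the current-land mask (valid in some period, sea today), 0 elsewhere.
  Internally all keep-masks use 1 = keep.
* **Composition sums in sorted variable order**, making the result
  bit-identical under permutations of the kept list (floating-point addition
  is not associative).
* **Constant layers normalize to all zeros** with a warning: a variable with
  no spatial spread carries no ranking information, and zeros leave the sum
  unaffected.
* **Degenerate validation sweeps** (a single cell) report an explicit
  self-comparison row with r = 1 rather than an empty table.

## The synthetic world

`make_world()` emulates the *shape* of a real collection, with known
structure:

* **Spatial autocorrelation**: every field is white noise convolved with a
  periodic Gaussian kernel (sd 3 pixels by default), standardized. Smooth
  fields are what make SD- and range-based indices agree strongly, as they
  do on real climatologies.
* **Planted correlation blocks.** For variable *v* in block *b* with target
  correlation ρ (default 0.95), a standardized latent field is mixed as
  F_v = √ρ·L_b + √(1−ρ)·E_v, so cor(F_i, F_j) = ρ within the block. The
  dispersion amplitude is the linear map A_v = amp·(1 + 0.25·F_v) (clamped
  at 0.05), and the time series is x_t = μ_v + A_v·d_t with temporal
  deviations d_t = e_t + 0.25·w_{b,t} shared within a block. Since μ_v is
  constant in time, the sample SD is exactly A_v·sd(d), so the *dispersion
  layers* — the quantities the collinearity screen actually sees — carry the
  planted correlation. The shared temporal factor inflates the empirical
  within-block r slightly above ρ and spatial autocorrelation widens its
  sampling spread; the tests assert the calibrated band [0.90, 0.99].
  Between-block fields share nothing, so |r| stays far below any grouping
  threshold. Note the calibration is planted in the dispersion layers, not
  in single-period raw layers (whose mean fields μ_v are independent).
* **Temporal drift and noise**: a single standardized global trajectory e_t
  (glacial-cycle-like for the past, trending for the future) plus smooth
  per-block, per-period noise fields (τ = 0.25).
* **Sea-level scenario** driven by an elevation field: the lowest 35% of
  pixels are permanent sea, the next 10% are glacial shelf (70% of them
  emerged only at the glacial maximum, the rest at all seven low-stand
  periods), the next 5% are lowland submerged during the three warm periods,
  the rest stable land. These fractions keep ~5,300 land pixels on the
  default grid — enough for a 2,000-point screen with realistic sea/land
  geometry.
* **GCM ensemble**: each member is the scenario truth plus smooth noise
  (relative level 0.15 by default, symmetric about the truth, so mean- and
  median-reduced indices converge as the noise shrinks — a tested property).
  The availability roster mimics a real ensemble table: one model missing
  from two scenarios throughout, two more missing from the first window of
  single scenarios, giving member counts of 7–9.

What the generator does **not** emulate: physically realistic climate
dynamics, inter-variable constraints (e.g. bio7 = bio5 − bio6), latitudinal
gradients, heavy-tailed precipitation, or correlated GCM biases. A green
test therefore establishes that the *pipeline computes its definitions
correctly and recovers planted structure* — not that any particular
published map is reproduced, which would require the external global
rasters.

## Numerical conventions

* Value layers are stored as float32 in GeoTIFF; masks and categories as
  uint8. In memory NoData is always `NA`; on disk it is the file's sentinel
  (−3.4e38 by default for float layers, 255 for uint8).
* Grid equality: shape exact, transform to 1e-9 degrees. Misalignment is an
  error naming the offending layer and field.
* Categorization uses lower-exclusive/upper-inclusive bins with the first
  bin closed at 0, so a top bin "0.71–1" contains 0.80 but not 0.71.
* Histograms use equal-width bins on [0, 1], report empty bins, and count
  a value of exactly 0 into bin 1 and exactly 1 into the last bin.
* Even-count medians are the midpoint of the two central values.

## Limitations

* No reprojection/resampling, tiled or compressed GeoTIFF, or multi-band
  files; inputs must share one grid.
* The SD is trend-blind (see assumptions); century-scale interpolation and
  detrended stability statistics are out of scope.
* The exact 32 break values of the published colour schemes (beyond the two
  printed top-bin boundaries) are not public; users supply their own break
  lists.
* Published global index values cannot be verified offline; validation here
  is structural (oracles, planted-truth recovery, determinism) plus a soft
  regression bound on the SD-vs-range agreement (> 0.9 on the default
  world).
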