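---
title: "Mapping canopy functional diversity and drought response: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping canopy functional diversity and drought response: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specdiv)
```

## Overview

`specdiv` implements a satellite-based biodiversity–ecosystem-functioning
(BEF) analysis for forest canopies. From multi-band surface-reflectance
rasters it derives three ecophysiological trait proxies per 20 m pixel,
summarizes the local trait cloud into functional richness and evenness with
a circular moving window, quantifies the forest's response to a drought year
as fractional changes of a canopy water index across four years, and relates
diversity to drought response with binned, pixel-count-weighted regression
and sequential variance partitioning across geographic subregions. A
synthetic-landscape generator with full ground truth makes every stage
testable end to end without any satellite data.

## Trait proxies

Three spectral indices serve as trait proxies, chosen to be spectrally
disjoint and weakly correlated:

* **CHL** — red-edge chlorophyll index, $CI_{re} = \rho_{783}/\rho_{704} - 1$
  (bands B7, B5): photosynthetic capacity.
* **CCR** — carotenoid/chlorophyll index,
  $CCI = (\rho_{560}-\rho_{664})/(\rho_{560}+\rho_{664})$ (B3, B4):
  photoprotection strategy.
* **EWT** — normalized difference infrared index,
  $NDII = (\rho_{865}-\rho_{1614})/(\rho_{865}+\rho_{1614})$ (B8A, B11):
  canopy water content.

Each index map is rescaled to $[0,1]$ with the lowest and highest 0.1% of
values clipped to 0 and 1 (`rescale01()`, linear-interpolation percentiles).
A constant raster rescales to 0.5 everywhere rather than erroring: a
degenerate range carries no ordering information, and downstream a
zero-dispersion window simply yields zero richness. Whether tail clipping
applies at the trait-map stage as well as before binning is configurable
through a single `clip_pct` used by both stages.

The drought response uses the normalized difference water index
$NDWI = (\rho_{833}-\rho_{1614})/(\rho_{833}+\rho_{1614})$ (B8, B11), which
shares no acquisition dates with the diversity composite, keeping the
spatial (diversity) and temporal (response) dimensions observationally
independent up to the shared B11 band.

## Masking

A pixel is cloud- and shadow-free when B2 < 5% and B8A > 15% reflectance
(strict inequalities). The forest mask further requires, per scene: location
inside the forest polygons; NDVI at or above a robust lower threshold; and
B6 and B12 at or above their lower thresholds (shadow removal). Thresholds
are `median − c·MAD` with the raw median absolute deviation and `c = 3` by
default. A pixel is *excluded* when it falls strictly below a threshold, so
a zero-MAD (constant) distribution excludes nothing; `c` is configurable
because the outlier constant that reproduces any particular empirical NDVI
threshold on real data is data-dependent. The final mask keeps pixels valid
in at least 2 of the 3 early-summer scenes. Small 8-connected patches
(default < 28 px, about one window area) are removed, with optional binary
erosion, because windows dominated by edges bias the diversity metrics.

## Functional diversity

Within a circular kernel of radius 3 px (60 m at 20 m pixels; weight of each
cell = fraction of its unit square inside the circle, estimated on a 100×100
subgrid), the valid pixels' (CHL, CCR, EWT) triples form a 3-D point cloud.

* **Functional richness** is the volume occupied by the cloud. The default
  estimator is the *alpha-complex* volume — the union of Delaunay tetrahedra
  with circumradius ≤ α — with α chosen per window as twice the mean branch
  length of the cloud's minimum spanning tree. The adaptive choice keeps
  hulls connected across windows of very different dispersion; a fixed α and
  a convex-hull mode are selectable. The convex mode is deterministic in the
  sense of having no tuning parameter, and the package's simulation studies
  use it for exactly that reason. Hull geometry ignores abundances.
* **Functional evenness** is the Villéger-style FEve: for MST branch $l$
  joining points $i, j$, $EW_l = d(i,j)/(w_i + w_j)$,
  $PEW_l = EW_l/\sum EW$, and
  $FEve = \frac{\sum_l \min(PEW_l, \tfrac{1}{S-1}) - \tfrac{1}{S-1}}
  {1 - \tfrac{1}{S-1}}$. By default the kernel area fractions serve as the
  abundances $w_i$ (equal abundances are selectable, in which case the
  $w$ terms cancel). FEve is invariant to translation, uniform scaling and
  relabeling.

Numerical choices: the convex hull is built incrementally with horizon
repair and tolerances scaled to the cloud's bounding box; Delaunay
tetrahedra are found by exhaustive empty-circumsphere testing, which is
exact for the ≤ 40-point windows that occur in practice; MST ties break by
lexicographic edge order so outputs are platform-stable. A window is
reported only when at least 50% of the kernel weight lies on valid pixels
(suppressing edge artifacts), with ≥ 4 points for richness (a 3-D simplex)
and ≥ 3 for evenness.

## Drought response

Yearly late-summer NDWI composites are per-pixel medians over each year's
cloud-free acquisitions. With years 1–4 (pre-drought, drought, and two
post-drought years):

* resistance $= (NDWI_2 - NDWI_1)/NDWI_1$,
* recovery $= (NDWI_3 - NDWI_2)/NDWI_2$,
* resilience $= (NDWI_4 - NDWI_1)/NDWI_1$.

Resilience uses the *second* post-drought year so that it is not a linear
combination of resistance and recovery. Ratios are invalid where
$|NDWI_1| < \varepsilon$ (default $10^{-3}$): percent changes of a
near-zero index are unstable. Responses are stored as fractions and turned
into percentages only at reporting time. The exact identity
$(1+\text{resistance})(1+\text{recovery}) = NDWI_3/NDWI_1$ is enforced by a
property test.

## Statistical analysis

**Separate analysis.** Each rescaled diversity metric is discretized into
1000 equal-range bins (`[i/n, (i+1)/n)`, last bin closed); the mean response
per bin is fitted on the bin center by weighted least squares with the
per-bin pixel count N as weight. Bins holding fewer than 1% of the maximum
bin count are dropped (a bin exactly at the threshold is kept). Linear,
quadratic and logarithmic forms are fitted and the form with the lowest AIC
wins; AIC uses the frequency-weight log-likelihood, consistent with N being
a pixel count. The RSS inside the AIC is floored just above numerical zero
so an essentially perfect fit selects the simpler form through the parameter
penalty rather than by rounding noise.

**Combined analysis.** Richness bins × evenness bins × subregions
(20 × 20 × K, K = 21 by default) form the strata; empty strata are kept as
N = 0 rows for accounting and excluded from fitting. Weighted least squares
with sequential (Type-I) sums of squares in a fixed entry order:
`logric + eve + eve² + REG + logric:REG + eve:REG + eve²:REG` for resistance
and recovery, `ric + eve + REG + ric:REG + eve:REG` for resilience, with
`logric = log(ric + δ)` and δ defaulting to half a bin width because the
first bin's center can be arbitrarily close to zero. Each term's SS divided
by the total SS is its increment of multiple r²; the decomposition is
exactly additive. The conservative F-ratio F2 tests each diversity term
against its interaction with subregion (`F2 = MS(term)/MS(term:REG)`),
which corresponds to treating between-region slope variation as the error —
the appropriate yardstick for a *generalizable* diversity effect. p-values
are upper-tail F probabilities without multiple-testing adjustment. For
display, subregion-corrected values are the residuals of a weighted
regression on the subregion factor plus the weighted grand mean. Rank
deficiency (possible with many empty strata) is flagged and SS are computed
on the estimable subspace, as `lm()` does.

## The synthetic landscape

The generator emulates the structure of the real observation problem, not
its radiometric physics:

* **Species patches** by multi-source flood fill from seeded points
  (default 8 species × 6 seeds), giving a patchy mixed-stand mosaic whose
  local species density varies spatially.
* **Traits**: each species carries a trait triple drawn from [0.20, 0.72];
  pixels add within-species Gaussian jitter (SD 0.03, clipped to
  [0.15, 0.78]). Within-species trait variance at 20 m is poorly
  characterized in the field, so it is an explicit parameter rather than an
  assertion; the clip range keeps every trait inside the invertible range of
  its band inversion.
* **Bands** are constructed by inverting the index definitions. The
  inversions are under-determined (two free bands per index), so one band
  per index is fixed at a realistic anchor (B5 = 0.08, B4 = 0.06,
  B11 = 0.12) and the other solved for; targets outside the invertible
  range raise an error naming the pixel. Band noise is Gaussian with
  SD 0.002 — instrument-level noise, since atmospheric effects are outside
  the generator's scope.
* **Contamination**: per date, binomially drawn pixel counts are covered by
  random bright (cloud) and dark (shadow) disks that violate the cloud-free
  rule, so realized contamination matches the configured rates up to
  binomial sampling error.
* **Drought linkage**: the drought-year NDWI drop of each pixel is
  `drop_mean + β·ric01 + γ₁·eve01 + γ₂·eve01² + region effect + noise`,
  where `ric01`/`eve01` are the true local diversity layers computed from
  the noise-free traits with the same kernel the pipeline uses (convex mode,
  so the truth contains no α tuning), rescaled to 0–1. Defaults:
  `drop_mean = −0.25`, `β = +0.10`, `γ = (+0.10, −0.10)` (hump with an
  interior optimum), per-region offsets with SD 0.02, response noise
  SD 0.02. Year trajectories encode a dip (year 2, factor `1 + drop`), a
  strong rebound (year 3, `1 + 0.3·drop`) and a partial relapse (year 4,
  `1 + 0.5·drop`).
* All randomness flows from one root seed through named substreams
  (species, patches, jitter, clouds, noise, …), so any stage is
  reproducible in isolation and identical (config, seed) pairs give
  bit-identical outputs.

What the generator does **not** emulate: radiative transfer, BRDF and
sun-angle effects, topography, phenology, spatially correlated atmospheric
residuals, and species whose trait triples drift over time. Passing tests
therefore demonstrate the correctness of the algorithms and the
recoverability of a known linkage under realistic sensor noise — not that
the method is unbiased on real imagery.

## Parameter recovery and its limits

The package's simulation study (100 seeded 128×128 landscapes, convex-hull
richness) checks that the combined model recovers the generative linkage:
the pooled (across-region) richness term is positive and the pooled eve²
term negative in ≥ 95 of 100 seeds, and the fitted richness slope — from
the model matching the generative form (linear richness), with sum-to-zero
region contrasts so the coefficient is the across-region average slope —
agrees with the generative β within twice its standard error on average.
Pooled coefficients are used for the sign check because the default
treatment-contrast coefficient is the slope of one reference region only,
which carries far more sampling noise than the average effect.

A real limitation surfaced by the same study: measured richness is a noisy
version of true richness (band noise propagates through the index
inversions into the trait cloud and inflates hull volumes), so the fitted
slope is attenuated toward zero — classical regression dilution. The
attenuation is strongest on landscapes whose species triples happen to lie
near a plane in trait space, where true hull volumes are tiny and noise
dominates. Seed-averaged recovery stays within the stated tolerance, but
users comparing fitted slopes against external expectations should keep
errors-in-variables bias in mind; the package makes no attempt to
deconvolve it.

## Problem sizes used by the test suite

Unit tests run on 48×48 to 64×64 landscapes with 6–8 subregions; the
recovery study uses 100 seeds at 128×128 with 21 subregions, and oracle
equivalence checks use 200 random point sets against brute-force hull and
Kruskal-MST re-implementations. These sizes give stable statistics while
keeping the whole suite in the single-digit minutes on one CPU; they are the
package's own trade-off between statistical resolution and convenience.

## Known limitations

* Alpha-shape richness depends on an α parameter with no field-standard
  value; the adaptive default is a pragmatic choice, and results should be
  reported together with the mode used.
* FEve computed from ~28-point windows is a high-variance statistic; its
  measured maps correlate only moderately with the underlying truth at
  realistic noise levels.
* The sequential-SS shares depend on the term entry order by construction;
  the order is part of the model specification, not a tunable.
* Drought attribution is correlational: nothing separates drought effects
  from co-occurring disturbances (e.g. bark beetle outbreaks).
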