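# specdiv

Satellite-based mapping of canopy **functional diversity** and its
relationship with forest **drought response**, for ecologists and
remote-sensing scientists studying biodiversity–ecosystem-functioning (BEF)
at landscape scale.

From multi-band surface-reflectance rasters at 20 m (the band set of a
decametric multispectral sensor: B2–B8, B8A, B11, B12), `specdiv`:

1. derives three weakly correlated trait proxies per pixel —
   chlorophyll content (CHL) from the red-edge chlorophyll index
   `CIre = ρ783/ρ704 − 1`, the carotenoid/chlorophyll ratio (CCR) from
   `CCI = (ρ560 − ρ664)/(ρ560 + ρ664)`, and equivalent water thickness
   (EWT) from `NDII = (ρ865 − ρ1614)/(ρ865 + ρ1614)` — each rescaled to
   0–1 with 0.1% tail clipping;
2. builds a forest mask from a cloud-free rule (B2 < 5%, B8A > 15%),
   polygon clipping, robust median − 3·MAD thresholds on NDVI and the
   shadow-sensitive bands B6/B12, and 2-of-3 multi-date voting;
3. computes, in a circular 60 m moving window (weight sum 28.3 pixels =
   1.131 ha), **functional richness** — the α-shape (concave hull) volume
   of the local (CHL, CCR, EWT) point cloud — and **functional evenness** —
   the Villéger-style regularity of its minimum spanning tree;
4. maps **drought resistance, recovery and resilience** as fractional
   changes of yearly late-summer NDWI composites:
   `(NDWI₂−NDWI₁)/NDWI₁`, `(NDWI₃−NDWI₂)/NDWI₂`, `(NDWI₄−NDWI₁)/NDWI₁`;
5. relates diversity to response with 1000-bin weighted univariate fits
   (AIC selection among linear/quadratic/logarithmic forms) and a
   20 × 20 × 21 stratification (richness bins × evenness bins ×
   subregions) analyzed by weighted sequential-SS (Type-I) linear models,
   e.g. `rst ~ logric + eve + eve² + REG + logric:REG + eve:REG + eve²:REG`
   with pixel counts N as weights, reporting each term's share of total SS
   (r² increments × 100), conservative F-ratios against the
   diversity×region interactions, and subregion-corrected values.

A fully seeded **synthetic-landscape generator** (species patches, invertible
band construction, cloud/shadow contamination, a four-year NDWI trajectory
with a drought dip, and a configurable diversity→response linkage) provides
ground truth for every stage, so the whole pipeline is testable offline.

## Worked example

```r
library(specdiv)

cfg <- run_config(generator = landscape_config(rows = 96, cols = 96),
                  alpha = "convex")
res <- run_synthetic_analysis(cfg, seed = 1)

res$fd
#> <fd_map> 96 x 96 px, radius 3 px, alpha: convex
#>   fric: 8093 valid (range 0.00171 .. 0.131)
#>   feve: 8093 valid (range 0.0323 .. 0.889)

res$responses
#> <drought_response> 96 x 96 px
#>   resistance: 9216 valid, mean -21.8%
#>   recovery:   9216 valid, mean +19.7%
#>   resilience: 9213 valid, mean -10.9%

res$analysis$anova$rst
#> <bef_anova> response: rst, r2 = 0.7506
#>         term   df       ss        ms         f         p r2_increment     f2  df2        p2
#> 1     logric    1 2.379104 2.3791038 3069.4898 0.000e+00     0.348935 597.80   20 2.261e-16
#> 2        eve    1 0.007942 0.0079415   10.2460 1.389e-03     0.001165  12.14   20 2.338e-03
#> 3       eve2    1 0.045475 0.0454746   58.6707 2.776e-14     0.006670 106.19   20 1.905e-09
#> 4        REG   20 2.583903 0.1291952  166.6860 0.000e+00     0.378972     NA   NA        NA
#> 5 logric:REG   20 0.079596 0.0039798    5.1347 9.160e-13     0.011674     NA   NA        NA
#> 6    eve:REG   20 0.013082 0.0006541    0.8439 6.606e-01     0.001919     NA   NA        NA
#> 7   eve2:REG   20 0.008565 0.0004282    0.5525 9.445e-01     0.001256     NA   NA        NA
#> 8  Residuals 2194 1.700528 0.0007751        NA        NA     0.249410     NA   NA        NA
```

Reading the output: the synthetic forest lost on average 21.8% of its canopy
water index in the drought year and ended 10.9% below baseline three years
later. In the combined model, log-richness explains 34.9% of the total sum
of squares (`r2_increment` × 100) with a positive coefficient — richer
canopies resisted better — and the negative `eve2` term (0.7% of SS,
conservative F2 = 106 against its region interaction) recovers the
generator's hump-shaped evenness linkage. Subregions absorb 37.9% of SS,
which is why the model partials them out before interpreting diversity.

`tidy()`/`glance()` turn fitted objects into tibbles, and `autoplot()`
draws diversity/response maps, binned univariate fits and SS-share bars.
The on-disk equivalent with per-stage artifacts, content hashes and resume
is:

```sh
Rscript scripts/pipeline.R run    --seed 1 --out runs/demo --alpha convex
Rscript scripts/pipeline.R report --out runs/demo
```

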