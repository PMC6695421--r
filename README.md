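# nightlux

Tools for identifying behaviorally relevant levels of artificial nighttime
light and mapping their extent across an urban landscape.

Urban wildlife experiences nighttime illuminance spanning four orders of
magnitude, from moonlight (< 0.01 lux) to brightly lit commercial streets
(> 100 lux). `nightlux` implements a complete laboratory-to-landscape
workflow for asking *at what light level does behavior change, and how much
of a city's habitat is exposed to that level?*:

- **Illumination clustering** — a univariate Gaussian finite mixture over
  ground-level lux readings, fitted by EM with BIC model selection
  (`fitIlluminationMixture`, `summarizeClusters`), identifying the typical
  light environments of a city.
- **Imagery-to-lux modeling** — random forest regression of
  ln(lux + 1) at ground control points on exact area-weighted nighttime
  image pixel features (`extractImageFeatures`, `fitIlluminationModel`),
  rasterized to a 30 m illumination grid by dense point prediction and
  cell averaging (`predictIlluminationRaster`), with buffer summaries
  around cameras that reject points inside building footprints
  (`sampleBufferIllumination`).
- **Circadian actogram analysis** — the Sokolove–Bushell chi-square
  periodogram (`chiSquarePeriodogram`); activity onset/offset detection
  with a run-length/quiet-span rule (`detectOnsetOffset`); total activity,
  active-phase length alpha, and onset error (residual SD about the linear
  onset trend) per light condition (`circadianMetrics`); and mixed-model
  condition comparisons with Tukey–Kramer letters (`compareConditions`).
- **Field activity analysis** — von Mises circular kernel densities of
  detection times (`fitCircularDensity`), activity levels
  act = 1/(2π·max f̂) with bootstrap SEs (`estimateActivityLevel`), Wald
  and Kolmogorov–Smirnov light/dark contrasts (`compareActivityLevels`,
  `compareActivityDistributions`).
- **Occurrence model grid** — camera-hour logistic regressions of species
  presence on a light indicator × circadian harmonics plus human-activity,
  land-use and astronomical controls, over a 270-model grid of lux
  cutoffs {1, 3, 6} × buffer radii {300, 500, 1000 m} × dusk anchors
  {−2..+2 h} × harmonic orders {1..3} × 2 species groups, selected by
  minimum BIC (`selectModelGrid`), with normalized light/dark
  predicted-probability contrasts (`probabilityContrast`).
- **Greenspace fragmentation** — majority-rule resampling of land cover to
  a 30 m greenspace mask, thresholding at > 6 lux, connected-component
  patch labeling, and FRAGSTATS-style metrics (number of patches, mean/SD
  patch area, total edge, mean nearest-neighbor distance, percent of
  landscape) plus per-neighborhood photopollution shares
  (`resampleGreenspace`, `illuminatedMask`, `labelPatches`,
  `landscapeMetrics`, `neighborhoodPhotopollution`).

A first-class synthetic-data module (`simConfig`, `simLightscape`,
`simActograms`, `simDetections`, `simLandscape`) generates every input the
pipeline consumes — actograms with configurable period/alpha/jitter and
lux-dependent suppression, a ground-truth lux surface with blurred noisy
image bands and noisy control points, detection streams driven by circular
activity densities that shift at illuminated sites, and
land-cover/building/neighborhood layers — so the whole pipeline is
testable against known truth. See the methods vignette
(`vignettes/nightlux-methods.Rmd`) for the models, assumptions and design
decisions.

## Worked example

```r
library(nightlux)

cfg <- simConfig(seed = 5)            # the default synthetic study
ls  <- simLightscape(cfg)             # truth, image bands, control points

# cluster ground illumination
mix <- fitIlluminationMixture(ls$controlPoints$lux)
summarizeClusters(mix)

# learn imagery -> lux, rasterize at 30 m
feats <- extractImageFeatures(ls$bands, ls$controlPoints$x, ls$controlPoints$y)
mod   <- fitIlluminationModel(feats, ls$controlPoints$lux, holdout = 200,
                              controlPoints = ls$controlPoints, seed = 2)
mod$cvReport$varianceExplained
#> [1] 0.968
rast <- predictIlluminationRaster(mod, ls$bands, nRandom = 40000, seed = 3)
rast
#> GridLayer: 100 x 100 cells of 30 m
#>   extent: x [0, 3000]  y [0, 3000]
#>   values: min 0.5717  median 2.885  max 125.5  (95 NA)
```

The held-out variance explained (0.97 here) says how much of the
log-illuminance variation the image bands predict; the raster is the
city-scale lux map that downstream buffer classification and greenspace
thresholding consume. On the laboratory side:

```r
cfg <- simConfig(seed = 3, studyDays = 10, conditionLux = c(dark = 0.005))
a   <- simActogram(cfg, noise = "none", jitterSD = 0, suppression = 0,
                   alpha = 12)
tauHat(chiSquarePeriodogram(a))
#> [1] 24
detectOnsetOffset(a, 5)
#>   day onset offset valid
#> 1   5    18      6  TRUE
```

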