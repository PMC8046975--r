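# microbuff

Quantify how a forest canopy buffers near-ground microclimate against
open-field (macroclimate) conditions from paired station records — the
standard design in forest-microclimate and treeline ecology where one
logger sits below the canopy and a reference logger in a nearby open
field, both recording air temperature/humidity at 10 cm above ground and
soil temperature/moisture at 10 cm depth every half hour.

The package covers the full analysis chain:

* **QC and aggregation** — ±3 SD outlier screening on the full record,
  regularization, daily/ISO-week summaries with completeness guards,
  season masks (growing season May–Sep, JJA, DJF).
* **Seasonal temperature offsets** — ΔT = T_below − T_open (negative =
  cooler under canopy), estimated with intercept-only linear mixed models
  with nested month/day/hour random intercepts (REML via `lme4`); daily
  maximum/minimum offsets as differences of per-day extremes.
* **Offset response** — harmonic mixed line ΔT ~ T_open + sin/cos(hour)
  with nested month/day random effects, χ² likelihood-ratio comparison
  against the intercept-only baseline, Nakagawa marginal/conditional R²,
  and a penalized-spline (GCV) nonlinearity check.
* **Buffering capacity** — the core statistic. For the daily-mean
  coupling line *y* = α + β·x (β < 1) with crossing point
  x\* = α/(1 − β) against the 1:1 line, the thermal sums

      B_warm = ∫ max(α + (β − 1)x, 0) dx      (canopy warmer, left of x*)
      B_cool = ∫ max((1 − β)x − α, 0) dx      (canopy cooler, right of x*)

  over the observed open-field range, in closed form (units °C), plus
  hourly decoupling profiles and ANCOVA site contrasts.
* **Soil, snow, phenology** — zero-curtain snow-period detection from
  daily soil temperatures, thermal amplitude, and SOS/EOS/LOS phenology
  metrics from 16-day NDVI composites.
* **Synthetic campaigns** — a seeded generator with analytically known
  ground truth (seasonal/diurnal harmonics, synoptic and AR(1) noise,
  hour-of-day coupling profiles, nested random effects, snow clamps,
  moisture dynamics, gap/outlier injection) so every estimator is
  validated by parameter recovery.

## Worked example

```r
library(microbuff)

# two-site synthetic campaign, one year at half-hourly resolution
cfg <- synth_config(end = "2017-04-30", seed = 3)
report <- run_pipeline(cfg, output_dir = "microbuff_out")

dplyr::filter(report$offsets, statistic == "mean")
#>   site  season statistic     mu    se     n
#> 1 NW    JJA    mean      -1.17  0.264  4243
#> 2 NW    DJF    mean       1.91  0.166  4123
#> 3 NW    GS     mean      -0.835 0.251  7033
#> 4 S     JJA    mean      -2.56  0.152  4223
#> 5 S     DJF    mean       3.04  0.366  4148
#> 6 S     GS     mean      -1.93  0.399  7032
```

The south-aspect canopy is ~2.6 °C cooler than the open field in summer
and ~1.9 °C cooler across the growing season (standard errors from the
nested mixed model); the denser northwest canopy buffers less (−1.2 °C
JJA). Winter offsets are positive: snow and the canopy keep the
understory milder.

The buffering statistic itself works directly from a fitted (or supplied)
coupling line:

```r
buffering_capacity(c(3.65, 0.60), x_min = 0.85, x_max = 9.31)
#> Buffering capacity for y = 3.650 + 0.600 x over [0.85, 9.31] degC
#>   crossing with 1:1: x* = 9.12 degC
#>   B_warm (canopy warmer) = 13.70 degC
#>   B_cool (canopy cooler) = 0.01 degC
```

A thin CLI lives at `inst/cli/microbuff.R`
(`simulate | run | qc | offsets | coupling | buffering | soil | phenology |
report`, with `--config <yaml> --seed --out`).

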