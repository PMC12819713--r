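# shrubelf

Landscape analysis of deciduous tall-shrub (*Alnus*/*Salix*) fractional
cover: terrain drivers, patch structure, multi-scale driver importance,
niche differentiation, leaf-level water-use traits, and
environmental-limiting-factor (ELF) modeling of potential cover.

## Who this is for

Spatial ecologists and remote-sensing scientists working with gridded
fractional-cover maps (percent cover per pixel, 0–100) and environmental
driver stacks who want to answer: *where can shrub cover still increase,
and which environmental factor caps it at each location?*

## The core model

For each genus and each of 13 drivers (eight climate, three topography, two
permafrost-soil layers), the upper envelope of cover against the driver —
its **maximum response** — is estimated by 99th-quantile regression on a
cubic B-spline basis, minimizing the pinball loss
&rho;<sub>&tau;</sub>(r) = r(&tau; − 1[r &lt; 0]) with an interior-point
solver on the quantile-regression linear program. Per pixel, **Liebig's law
of the minimum** combines the 13 envelope values: the smallest is the
potential cover, and the driver attaining it is the environmental limiting
factor (ELF). Growth potential is potential minus observed cover.

Around this core the package provides:

* `terrain_layers()` — depression filling (priority flood), Horn slope,
  D8/MFD flow accumulation, and TWI = ln(SCA / tan φ);
* `empirical_variogram()`, `fit_spherical()`, `variogram_ensemble()` —
  patch-size analysis via Matheron semivariograms on repeated 5% pixel
  subsamples; `community_frequency()` for density classes;
* `scale_scan()`, `fit_rf_ensemble()`, `variable_importance()`,
  `partial_profile()`, `compute_vif()` — bootstrap random-forest driver
  importance (%IncMSE) with partial response profiles;
* `pca_by_threshold()`, `centroid_distance_curve()`,
  `group_difference_tests()` — niche differentiation in standardized
  13-driver space across cover thresholds;
* `fit_g1()`, `g1_by_environment()`, `summarize_and_test_traits()` — the
  stomatal slope g1 (kPa^0.5) of the unified stomatal optimization model
  gs = g0 + 1.6(1 + g1/√VPD)·An/Ca, plus genus-level trait contrasts;
* `synthetic_landscape()` — a fully seeded generator (fractal DEM,
  elevation-coupled climate/soil fields, cover realized under known
  limiting curves with Beta-suppression) that emits complete ground truth
  for recovery testing;
* `run_all()` / `make_report()` — the end-to-end pipeline with a hashed,
  reproducible run manifest (a thin CLI wrapper lives in
  `inst/scripts/tundra-elf.R`).

## Worked example

```r
library(shrubelf)

land <- synthetic_landscape(generator_config(nrow = 150, ncol = 150,
                                             cell_size = 25, seed = 2))
tab  <- stack_to_table(land$stack, land$alnus$fcover, land$salix$fcover)

curves <- fit_all_limit_curves(tab, "Alnus", tau = 0.99)
val    <- binned_max_validation(curves, tab)
val$pooled
#>   genus    slope        r2     rmse n_bins
#> 1 Alnus 1.021343 0.9009755 8.525001    260

pots <- predict_potential(curves, land$stack, "combined")
elf  <- determine_elf(pots$per_driver)
fr   <- elf_frequency(elf)$overall
head(fr[order(-fr$frequency), ], 3)
#>       driver count  frequency
#> 11       TWI 10856 0.48248889
#> 9  elevation  6679 0.29684444
#> 8       Tmin  1298 0.05768889

sel <- land$alnus$margin$values > 5   # pixels whose true limiting margin > 5 points
mean(elf$elf_label$values[sel] == land$alnus$elf_label$values[sel])
#> [1] 0.9184153
```

The validation table says the fitted envelopes reproduce bin-wise maximum
cover nearly 1:1 (slope ≈ 1.02, R² ≈ 0.90); the frequency table says wetness
(TWI), elevation and winter temperature cap Alnus cover most often on this
landscape; and the last line says the per-pixel limiting-factor label
matches the generator's ground truth on 92% of the pixels where the true
margin between the two lowest limits exceeds 5 cover points.

Stomatal slope from gas-exchange data:

```r
gas <- generate_gas_exchange(g1_true = 1.59, n = 60, noise_sd = 0, seed = 1)
fit_g1(gas)$g1
#> [1] 1.59
```

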