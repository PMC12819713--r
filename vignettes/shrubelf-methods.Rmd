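---
title: "Methods: landscape drivers and limiting factors of tall-shrub cover"
author: "shrubelf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landscape drivers and limiting factors of tall-shrub cover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and scientific question

Deciduous tall shrubs — alder (*Alnus*) and willow (*Salix*) — are expanding
across low-Arctic landscapes, but not uniformly: their fractional cover
(fCover, percent of pixel area) is patchy, genus-specific, and ultimately
bounded by whichever environmental resource is most limiting at a site.
`shrubelf` implements a complete landscape workflow for analysing this
structure on gridded cover maps and a 13-layer environmental driver stack
(eight climate layers, three topographic layers, two permafrost soil layers):

1. **Terrain derivatives** — slope, flow accumulation and the topographic
   wetness index TWI = ln(SCA / tan φ), where SCA is the specific catchment
   area (upstream contributing area per unit contour width) and φ the slope
   in radians. High TWI marks flat, convergent, wet positions.
2. **Patch structure** — omnidirectional Matheron semivariograms on repeated
   random pixel subsamples, fitted with a spherical model; the fitted range
   is read as the characteristic patch size. Density-class frequencies
   (sparse (5,25], medium (25,75], high (75,100] percent) summarize the
   cover distribution.
3. **Driver importance** — bootstrap ensembles of random-forest regressions
   of cover on the 13 drivers; importance is the percent increase in
   held-out mean squared error when a driver is permuted (%IncMSE), with
   partial response profiles and a variance-inflation-factor screen for
   multicollinearity. A multi-resolution scan locates the aggregation scale
   at which drivers explain the most cover variance.
4. **Niche differentiation** — threshold-scanned PCA and centroid distances
   in the standardized 13-driver space, comparing where each genus sits as
   community density grows, plus per-driver Welch contrasts between
   genus-dominated pixels.
5. **Environmental limiting factors (ELF)** — for each genus and driver, a
   99th-quantile cubic B-spline regression estimates the upper envelope of
   cover against that driver (the "maximum response"); per pixel, Liebig's
   law of the minimum picks the driver whose envelope value is lowest as the
   ELF, and that minimum as the potential cover. Growth potential is
   potential minus observed cover.
6. **Stomatal slope** — the water-use-efficiency parameter g1 (kPa^0.5) of
   the unified stomatal optimization model
   gs = g0 + 1.6 (1 + g1/√VPD) An/Ca, estimated from gas-exchange records
   with g0 fixed at 0.

Because the workflow's real inputs (airborne-spectroscopy cover maps,
downscaled climate) are large external products, the package ships a
synthetic-landscape generator with full ground truth, and every claim the
test suite makes is a recovery claim against that truth.

## The quantile-envelope solver

The envelope fit minimizes the pinball loss
ρ_τ(r) = r(τ − 1[r < 0]) at τ = 0.99 over cubic B-spline coefficients, with
interior knots at empirical quantiles of the driver. This is a linear
program; `shrubelf` solves it with a primal-dual interior-point method on
the bounded dual (`rq_fit`), which costs O(n p²) per iteration and reaches
the LP optimum to ~1e-9 on 300-point instances (the test suite pins the
objective against an independently computed LP optimum and against an exact
simplex solve at run time). Numerical choices:

* convergence: complementarity gap below 1e-10 (relative), feasibility
  below 1e-9; a tiny ridge is added to the normal equations only if the
  Cholesky solve fails;
* predictions are clipped to [0, 100] and clamped to the training range of
  the driver (no extrapolation: envelope behaviour beyond observed
  conditions is unidentified);
* no monotonicity or non-crossing constraints are imposed — the observed
  envelopes are unimodal, not monotone;
* default 5 interior knots, degree 3. The suite checks that predictions move
  by less than 2 cover points as knots vary from 4 to 8.

Validation bins each driver into 20 equal-count bins (robust to skewed
driver distributions; equal-width is available) and regresses the bin-wise
observed maximum on the bin-wise mean predicted envelope. With data lying
exactly on a non-constant curve the bin maximum exceeds the bin mean by
O(bin width × curve slope), so even a perfect curve scores slightly off
slope 1 / RMSE 0; the tests therefore assert near-perfect rather than exact
recovery on that case.

## The synthetic landscape: what it emulates, and what it does not

The generator is the package's study system, not a test fixture; its
defaults are fixed and documented here.

* **DEM**: spectral-synthesis fractal surface with power-spectrum exponent
  2.6 (the 2.3–3 band typical of real terrain spectra), rescaled to 0–650 m
  — the relief of a coastal low-Arctic hill landscape.
* **Drivers**: Tmax/Tmin fall with elevation (lapse rates −6.5 and −4
  K km⁻¹), rain and snow rise with it, ET0/AET/radiation are smooth fields
  partially coupled to Tmax, water deficit is ET0 − AET *by definition* (so
  three climate layers are exactly collinear, as in the real variable set),
  and ALD/AGT follow Tmin at a coarse block scale, emulating a 500 m soil
  product. Smooth-noise amplitudes are set so driver–driver correlations sit
  near r ≈ 0.7 (VIF ≈ 2–7): the moderate multicollinearity band a real
  downscaled climate/soil stack shows. Much stronger coupling would make
  limiting-factor attribution between a driver and its proxy unidentifiable
  for any method of this family.
* **Cover**: per genus, a set of limiting curves (unimodal Gaussian bumps or
  logistic ramps in [0, 100]) is combined by a minimum rule into an envelope
  E; realized cover is clip(E·U + ε, 0, 100) with suppression U ~ Beta(a, 1)
  (a = 5, so the 99th percentile of U is 0.99^{1/5} ≈ 0.998 and the
  99%-quantile envelope stays recoverable) and measurement noise
  ε ~ N(0, 3) cover points, approximating spectroscopic retrieval error.
  Alnus peaks near 94% cover at mid elevations (≈300 m), steep slopes and
  moderately dry positions (suppressed where TWI is high); Salix peaks near
  77% at lower elevations, gentle slopes and wet positions (suppressed where
  TWI is low). Winter temperature and snow bind weakly. Ground truth (true
  envelope, argmin driver label, margin between the two lowest limits) is
  emitted with every realization.
* **Optional coupling scale**: cover can respond to block-mean drivers at a
  coarser scale (e.g. 250 m) with sub-scale noise, which gives the
  scale-scan a known optimum to find.
* **Leaf data**: gas exchange is drawn from the stomatal model at known g1
  (defaults 1.02 for Alnus, 1.59 kPa^0.5 for Salix); leaf traits are
  truncated-Gaussian draws at field-campaign means, spreads and sample
  sizes (e.g. LNC 24.6 ± 3.5 vs 20.8 ± 3.7 mg g⁻¹ at n = 130/202).

What the generator does **not** emulate: anisotropy and non-stationarity of
real cover fields, disturbance and biotic interactions, retrieval-error
spatial structure, cross-scale interactions beyond the single coupling
scale, and categorical land-cover confusion. Passing recovery tests
therefore demonstrate the estimators' correctness and calibration under the
stated statistical structure — not that field data meet that structure.

## Design decisions on genuinely open points

* **Flow routing** defaults to multiple flow direction (Freeman exponent
  1.1), with D8 retained for exact hand-traceable oracles. Flats are drained
  by an infinitesimal gradient toward spill cells (BFS distance), and
  boundary cells export off-grid; total exported area equals grid area to
  1e-6 relative. The slope in the TWI denominator is floored at 0.001 rad.
* **Aggregation** masks an output cell when fewer than half its inputs are
  valid (`min_valid_frac = 0.5`), an explicit knob because partially valid
  blocks have no canonical treatment.
* **Resampling between grids is never implicit**; a bilinear/nearest helper
  exists and must be called deliberately, because silent regridding hides
  alignment errors between products of different native resolutions.
* **"Hypervolume geometric center"** is implemented as the centroid of
  z-scored drivers over the union of occupied pixels: it is the quantity the
  distance curves actually plot, and it is deterministic and unit-free
  (affine-invariance is tested). Kernel hypervolumes are out of scope.
* **%IncMSE** is computed by permuting each driver on each ensemble member's
  held-out 25% rather than per-tree out-of-bag rows: numerically different
  from the classic forest importance but rank-consistent, and honest about
  what is resampled. Negative importances are reported, not clipped.
* **Partial profiles** default to the at-means variant (sweep one driver,
  others fixed at training means); the classical partial-dependence average
  is available as `mode = "pdp"`.
* **Welch's t** is used for all two-group contrasts (the unequal-variance
  default is the safe reading of "unpaired t-tests"); no multiple-testing
  correction is applied by default, with Benjamini-Hochberg exposed as an
  option.
* **g1 estimation**: with g0 fixed the stomatal model is linear in g1, so
  the least-squares estimate is closed-form; the classical linearized
  transform estimate is reported alongside as a diagnostic. Rows with
  An ≤ 0 carry no slope information and are excluded with a count.
* **Ties in the ELF argmin** break toward the canonical driver order
  (climate, then topography, then soil) and raise a tie flag band.
* **Raster storage** uses TIFF with a scaled data channel plus an exact mask
  channel and a JSON sidecar (cell size, units, value range, category
  labels); categorical maps store small integer codes with a label table.

## Problem sizes and determinism

All stochastic stages take explicit seeds and derive per-repetition seeds
deterministically, so identical configuration and seed reproduce
byte-identical outputs (the end-to-end test hashes two full runs). The
shipped analyses use: variogram recovery on 256×256 cells with the cell
size chosen so the domain spans ≈26 variogram ranges (on much smaller
domains the single realized field's variogram legitimately deviates from
its model by more than the ±15% the recovery check allows); envelope
recovery at 20,000 pixels; ELF recovery on a 150×150
landscape; driver-importance checks on 80×80 landscapes over ten seeds; and
a 200×200 end-to-end run. These sizes are the package's chosen compromise
between estimator stability and a desk-scale footprint.

## Known limitations

* ELF label attribution between strongly correlated drivers is partially
  unidentifiable in principle: a passive driver tightly coupled to an
  active one develops a genuinely dipped conditional envelope and can
  absorb its label, and the mislabeled pixels are near-ties between fitted
  curves. The recovery tests stratify by the true margin and use moderately
  correlated drivers; per-genus label recovery then sits near (sometimes
  just under) 90% depending on the landscape realization, while the
  binned-maximum validation of the envelopes themselves is consistently
  strong. Real-data attributions should be read as driver *groups* where
  collinearity is high.
* The interior-point solver assumes a full-rank basis; degenerate drivers
  (single value) are rejected rather than regularized.
* Variogram fitting is WLS on binned estimates, not REML; nugget and range
  trade off on short-range fields when few pairs fall inside the range.
* The forest mask is a simple summed-tree-cover threshold; no spectral or
  structural forest classification is attempted.
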