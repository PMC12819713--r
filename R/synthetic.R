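# Synthetic landscape and leaf-level data generators with known ground truth.
#
# The generator emulates the statistical structure the downstream analyses
# assume: a fractal DEM, climate/soil fields coupled to elevation plus
# spatially autocorrelated noise, fractional-cover fields whose upper
# envelope with respect to each driver follows known limiting curves
# combined by a Liebig minimum rule with sub-envelope Beta suppression, and
# gas-exchange records drawn from the unified stomatal optimization model
# with known g1.

#' Generator configuration
#'
#' @param nrow,ncol grid shape.
#' @param cell_size cell size in meters.
#' @param relief elevation range in meters (default 0 to 650, the relief of
#'   a low-Arctic hill landscape rising from sea level).
#' @param spectral_exponent power-spectrum exponent of the fractal DEM
#'   surface (spectral density ~ f^-exponent).
#' @param lapse_tmax,lapse_tmin temperature lapse coefficients (K per m;
#'   negative = cooling with elevation).
#' @param noise_corr_frac correlation length of the smooth noise fields, as
#'   a fraction of the grid extent.
#' @param suppression_a shape parameter a of the Beta(a, 1) sub-envelope
#'   suppression factor. a = 5 keeps the 99th percentile of the suppression
#'   at 0.99^(1/5) ~ 0.998, so the 99 percent quantile envelope remains
#'   recoverable.
#' @param noise_sd standard deviation of additive measurement noise on
#'   realized fCover (percent points), approximating retrieval error.
#' @param forest_frac fraction of pixels assigned to a forest-dominated
#'   patch (for mask bookkeeping tests).
#' @param coupling_scale cell size (m) at which cover responds to the
#'   drivers: the envelope is evaluated on block-mean drivers at this scale
#'   and replicated back to the native grid, so sub-scale cover variation is
#'   pure noise. `NULL` (default) couples at the native cell size.
#' @param soil_block_factor block size (in cells) over which the soil layers
#'   (ALD, AGT) are piecewise constant, emulating a coarse soil product.
#' @param seed integer seed; all generator randomness derives from it.
#' @return a list of class `shrub_genconfig`.
#' @export
generator_config <- function(nrow = 120, ncol = 120, cell_size = 25,
                             relief = c(0, 650), spectral_exponent = 2.6,
                             lapse_tmax = -0.0065, lapse_tmin = -0.004,
                             noise_corr_frac = 0.15,
                             suppression_a = 5, noise_sd = 3,
                             forest_frac = 0.1, soil_block_factor = 8,
                             coupling_scale = NULL, seed = 1L) {
  stopifnot(nrow >= 8, ncol >= 8, cell_size > 0, relief[2] > relief[1],
            suppression_a > 0, noise_sd >= 0,
            forest_frac >= 0, forest_frac < 1, soil_block_factor >= 1)
  structure(as.list(environment()), class = "shrub_genconfig")
}

# deterministic child seeds below 2^31
child_seed <- function(seed, k) (as.integer(seed) %% 1000003L) * 1009L + 7L * k

#' Fractal DEM by spectral synthesis
#'
#' White Gaussian noise shaped in the Fourier domain by a power-law spectrum
#' and rescaled to the configured relief range. Deterministic given the
#' config seed.
#'
#' @param config a [generator_config()].
#' @return an elevation `shrub_grid` (m).
#' @export
generate_dem <- function(config) {
  stopifnot(inherits(config, "shrub_genconfig"))
  set.seed(child_seed(config$seed, 1L))
  nr <- config$nrow; nc <- config$ncol
  fr <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / nr
  fc <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / nc
  f2 <- outer(fr^2, fc^2, `+`)
  amp <- ifelse(f2 > 0, f2^(-config$spectral_exponent / 2), 0)
  phase <- matrix(complex(real = rnorm(nr * nc), imaginary = rnorm(nr * nc)), nr, nc)
  z <- Re(fft(phase * amp, inverse = TRUE)) / (nr * nc)
  z <- (z - min(z)) / (max(z) - min(z))
  z <- config$relief[1] + z * (config$relief[2] - config$relief[1])
  grid(z, cell_size = config$cell_size, units = "m", name = "elevation")
}

# smooth Gaussian noise field via Gaussian spectral filtering
smooth_noise <- function(nr, nc, corr_cells) {
  fr <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / nr
  fc <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / nc
  f2 <- outer(fr^2, fc^2, `+`)
  amp <- exp(-2 * (pi * corr_cells)^2 * f2 / 2)
  phase <- matrix(complex(real = rnorm(nr * nc), imaginary = rnorm(nr * nc)), nr, nc)
  z <- Re(fft(phase * amp, inverse = TRUE)) / (nr * nc)
  as.vector(scale(as.vector(z)))  # zero mean, unit sd
}

#' Gaussian random field with a spherical covariance
#'
#' Simulates a stationary, isotropic Gaussian field with semivariogram
#' gamma(h) = nugget + psill * sph(h / range) by circulant embedding on a
#' doubled torus (small negative embedding eigenvalues are clipped, a
#' standard approximation for compactly supported covariances).
#'
#' @param nrow,ncol grid shape.
#' @param cell_size cell size (m).
#' @param range_m variogram range (m).
#' @param psill partial sill.
#' @param nugget nugget variance (added as white noise).
#' @param mean_value field mean.
#' @param seed integer seed.
#' @return a `shrub_grid`.
#' @export
simulate_spherical_field <- function(nrow, ncol, cell_size, range_m,
                                     psill = 1, nugget = 0, mean_value = 0,
                                     seed = 1L) {
  set.seed(as.integer(seed))
  M <- 2L * nrow; N <- 2L * ncol
  dx <- pmin(0:(N - 1), N - (0:(N - 1))) * cell_size
  dy <- pmin(0:(M - 1), M - (0:(M - 1))) * cell_size
  h <- sqrt(outer(dy^2, dx^2, `+`))
  u <- pmin(h / range_m, 1)
  cov <- psill * (1 - (1.5 * u - 0.5 * u^3))
  lam <- Re(fft(cov))
  lam[lam < 0] <- 0
  zc <- matrix(complex(real = rnorm(M * N), imaginary = rnorm(M * N)), M, N)
  fld <- Re(fft(sqrt(lam) * zc, inverse = TRUE)) / sqrt(M * N)
  z <- fld[seq_len(nrow), seq_len(ncol)]
  if (nugget > 0) z <- z + rnorm(nrow * ncol, sd = sqrt(nugget))
  grid(z + mean_value, cell_size = cell_size, units = "", name = "grf")
}

#' Environmental driver fields coupled to a DEM
#'
#' Builds the 13 canonical driver layers: slope and TWI from the terrain
#' module; Tmax and Tmin decreasing linearly with elevation (lapse rates in
#' the config) plus smooth noise; rain and snow increasing with elevation;
#' ET0, AET, deficit and radiation as smooth fields partially coupled to
#' Tmax; ALD and AGT coupled to Tmin plus noise, generated at a coarser cell
#' and block-replicated to emulate a coarse soil product.
#'
#' @param dem elevation grid from [generate_dem()].
#' @param config a [generator_config()].
#' @return a `shrub_envstack`.
#' @export
derive_env_fields <- function(dem, config) {
  stopifnot(is_grid(dem), inherits(config, "shrub_genconfig"))
  set.seed(child_seed(config$seed, 2L))
  nr <- nrow(dem$values); nc <- ncol(dem$values)
  cl <- config$noise_corr_frac * max(nr, nc)
  elev <- dem$values
  w <- dem$cell_size
  mk_grid <- function(v, units, name) {
    grid(matrix(v, nr, nc), cell_size = w, units = units, name = name)
  }
  nz <- function() matrix(smooth_noise(nr, nc, cl), nr, nc)
  # noise amplitudes set so driver-driver correlations sit in the moderate
  # band typical of downscaled climate/soil products over a ~650 m gradient
  # (orographic precipitation vs elevation r ~ 0.6-0.75, ground temperature
  # vs air temperature r ~ 0.8)
  tmax <- 285 + config$lapse_tmax * elev + 1.2 * nz()
  tmin <- 248 + config$lapse_tmin * elev + 1.5 * nz()
  rain <- 250 + 0.35 * elev + 70 * nz()
  snow <- 120 + 0.25 * elev + 50 * nz()
  et0 <- 320 + 18 * (tmax - mean(tmax)) / sd(tmax) + 15 * nz()
  aet <- et0 - (60 + 20 * nz() + 0.03 * elev)
  deficit <- et0 - aet
  radiation <- 115 + 6 * (tmax - mean(tmax)) / sd(tmax) + 5 * nz()
  # coarse soil product: generate at block scale, replicate
  f <- as.integer(config$soil_block_factor)
  nrb <- max(1L, nr %/% f + (nr %% f > 0L))
  ncb <- max(1L, nc %/% f + (nc %% f > 0L))
  blk_idx_r <- rep(seq_len(nrb), each = f)[seq_len(nr)]
  blk_idx_c <- rep(seq_len(ncb), each = f)[seq_len(nc)]
  tmin_blk <- matrix(0, nrb, ncb)
  cnt <- matrix(0, nrb, ncb)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    tmin_blk[blk_idx_r[i], blk_idx_c[j]] <- tmin_blk[blk_idx_r[i], blk_idx_c[j]] + tmin[i, j]
    cnt[blk_idx_r[i], blk_idx_c[j]] <- cnt[blk_idx_r[i], blk_idx_c[j]] + 1
  }
  tmin_blk <- tmin_blk / cnt
  ald_blk <- 0.6 + 0.02 * (tmin_blk - mean(tmin_blk)) + 0.05 * matrix(rnorm(nrb * ncb), nrb, ncb)
  agt_blk <- 271 + 0.5 * (tmin_blk - mean(tmin_blk)) + 0.7 * matrix(rnorm(nrb * ncb), nrb, ncb)
  ald <- ald_blk[blk_idx_r, blk_idx_c, drop = FALSE]
  agt <- agt_blk[blk_idx_r, blk_idx_c, drop = FALSE]
  tl <- terrain_layers(dem, method = "mfd")
  env_stack(list(
    ET0 = mk_grid(et0, "mm", "ET0"),
    AET = mk_grid(aet, "mm", "AET"),
    deficit = mk_grid(deficit, "mm", "deficit"),
    radiation = mk_grid(radiation, "W/m2", "radiation"),
    rain = mk_grid(rain, "mm", "rain"),
    snow = mk_grid(snow, "mm", "snow"),
    Tmax = mk_grid(tmax, "K", "Tmax"),
    Tmin = mk_grid(tmin, "K", "Tmin"),
    elevation = dem,
    slope = tl$slope_deg,
    TWI = tl$twi,
    ALD = mk_grid(ald, "m", "ALD"),
    AGT = mk_grid(agt, "K", "AGT")
  ))
}

# Limiting-curve families ----------------------------------------------------

#' Construct a limiting response curve
#'
#' A limiting curve maps a driver value to the maximum attainable fCover
#' (percent). Two families are supported: a unimodal Gaussian bump scaled to
#' a peak height, and a monotone logistic ramp. A flat curve (never binding)
#' is the degenerate bump with infinite width.
#'
#' @param type `"bump"`, `"logistic"` or `"flat"`.
#' @param peak maximum fCover reached by the curve (percent).
#' @param center bump center / logistic midpoint, in driver units.
#' @param width bump standard deviation / logistic scale.
#' @param floor minimum fCover far from the optimum (percent).
#' @param direction for `"logistic"`: `1` if cover rises with the driver,
#'   `-1` if it falls.
#' @return a function of class `shrub_limitcurve` mapping driver values to
#'   \[0, 100\].
#' @export
limit_curve <- function(type = c("bump", "logistic", "flat"), peak = 95,
                        center = 0, width = 1, floor = 0, direction = 1) {
  type <- match.arg(type)
  f <- switch(type,
    bump = function(x) floor + (peak - floor) * exp(-0.5 * ((x - center) / width)^2),
    logistic = function(x) floor + (peak - floor) / (1 + exp(-direction * (x - center) / width)),
    flat = function(x) rep(peak, length(x))
  )
  structure(f, class = c("shrub_limitcurve", "function"),
            params = list(type = type, peak = peak, center = center,
                          width = width, floor = floor, direction = direction))
}

#' Default ground-truth limiting curves for the two genera
#'
#' Alnus cover peaks at mid elevations (200-400 m) on steep slopes
#' (10-25 degrees) at moderate wetness with an envelope peak near 94
#' percent; Salix peaks at lower elevations (50-300 m) on gentle slopes
#' (3-10 degrees) at high wetness with a lower envelope peak near 77
#' percent. Climate and soil drivers are given weakly binding curves
#' (high flat-ish bumps) so topography dominates, mirroring a landscape
#' where shrub cover is topographically limited.
#'
#' @param genus `"Alnus"` or `"Salix"`.
#' @param binding character vector of drivers allowed to bind; others get
#'   flat curves at the genus ceiling. Default: elevation, slope, TWI
#'   binding plus weakly binding Tmin and snow.
#' @return named list of 13 `shrub_limitcurve`s with attribute `"active"`.
#' @export
true_limit_set <- function(genus = c("Alnus", "Salix"),
                           binding = c("elevation", "slope", "TWI", "Tmin", "snow")) {
  genus <- match.arg(genus)
  peak <- if (genus == "Alnus") 94 else 77
  curves <- setNames(vector("list", 13L), driver_names())
  for (v in driver_names()) curves[[v]] <- limit_curve("flat", peak = peak)
  if (genus == "Alnus") {
    # mid-elevation, steep-slope, moderately dry niche: suppressed in
    # waterlogged (high-TWI) valleys
    curves$elevation <- limit_curve("bump", peak = peak, center = 300, width = 130, floor = 5)
    curves$slope <- limit_curve("bump", peak = peak, center = 17, width = 12, floor = 8)
    curves$TWI <- limit_curve("logistic", peak = peak, center = 7.5, width = 0.9,
                              floor = 8, direction = -1)
    curves$Tmin <- limit_curve("logistic", peak = peak, center = 245.5, width = 1.2,
                               floor = 30, direction = 1)
    curves$snow <- limit_curve("bump", peak = peak, center = 170, width = 120, floor = 40)
  } else {
    # low-elevation, gentle-slope, wet niche: suppressed on dry (low-TWI)
    # shoulders and summits
    curves$elevation <- limit_curve("bump", peak = peak, center = 175, width = 120, floor = 5)
    curves$slope <- limit_curve("bump", peak = peak, center = 6.5, width = 10, floor = 18)
    curves$TWI <- limit_curve("logistic", peak = peak, center = 7, width = 1,
                              floor = 8, direction = 1)
    curves$Tmin <- limit_curve("logistic", peak = peak, center = 244.5, width = 1.5,
                               floor = 35, direction = 1)
    curves$snow <- limit_curve("bump", peak = peak, center = 200, width = 140, floor = 45)
  }
  for (v in driver_names()) {
    if (!(v %in% binding)) curves[[v]] <- limit_curve("flat", peak = peak)
  }
  attr(curves, "active") <- binding
  attr(curves, "genus") <- genus
  curves
}

#' Realize fractional cover from environmental fields and true limits
#'
#' Per pixel the envelope is E = min over drivers of L(x); the realized
#' cover is clip(E * U + eps, 0, 100) with suppression U ~ Beta(a, 1)
#' i.i.d. and measurement noise eps ~ Normal(0, noise_sd). Ground truth is
#' returned: the envelope grid, the argmin (limiting-driver) label grid and
#' the margin between the two smallest per-driver limits.
#'
#' @param stack a `shrub_envstack`.
#' @param limits a [true_limit_set()] (or any named list of limit curves).
#' @param config a [generator_config()]; `suppression_a` and `noise_sd`
#'   control the sub-envelope structure. `suppression_a = Inf` and
#'   `noise_sd = 0` yield cover exactly on the envelope.
#' @param genus genus tag for the output map.
#' @param seed_offset offset added to the config seed stream so Alnus and
#'   Salix realizations are independent.
#' @return list: `fcover` (`shrub_fcover`), `envelope`, `elf_label`
#'   (categorical grid, codes = canonical driver order), `margin` grids.
#' @export
realize_fcover <- function(stack, limits, config, genus = "Alnus",
                           seed_offset = 0L) {
  stopifnot(inherits(stack, "shrub_envstack"))
  set.seed(child_seed(config$seed, 3L + seed_offset))
  ref <- stack$layers[[1L]]
  nr <- nrow(ref$values); nc <- ncol(ref$values)
  active <- attr(limits, "active")
  if (is.null(active)) active <- driver_names()
  cs <- config$coupling_scale
  if (!is.null(cs) && cs > ref$cell_size) {
    # cover responds to block-mean drivers at the coupling scale; the
    # envelope is computed coarse and replicated back to the native grid
    f <- as.integer(round(cs / ref$cell_size))
    lay <- lapply(stack$layers, aggregate_grid, target_cell_size = cs)
    nrb <- nrow(lay[[1L]]$values); ncb <- ncol(lay[[1L]]$values)
    potb <- array(NA_real_, dim = c(nrb, ncb, length(driver_names())))
    for (k in seq_along(driver_names())) {
      v <- driver_names()[k]
      potb[, , k] <- matrix(limits[[v]](as.vector(lay[[v]]$values)), nrb, ncb)
    }
    ir <- pmin(rep(seq_len(nrb), each = f)[seq_len(nr)], nrb)
    ic <- pmin(rep(seq_len(ncb), each = f)[seq_len(nc)], ncb)
    pot <- array(NA_real_, dim = c(nr, nc, length(driver_names())))
    for (k in seq_along(driver_names())) {
      pot[, , k] <- potb[ir, ic, k]
    }
  } else {
    pot <- array(NA_real_, dim = c(nr, nc, length(driver_names())))
    for (k in seq_along(driver_names())) {
      v <- driver_names()[k]
      pot[, , k] <- matrix(limits[[v]](as.vector(stack$layers[[v]]$values)), nr, nc)
    }
  }
  env <- apply(pot, c(1, 2), min)
  lab <- apply(pot, c(1, 2), which.min)
  sorted2 <- apply(pot, c(1, 2), function(z) sort(z)[2L])
  margin <- sorted2 - env
  a <- config$suppression_a
  U <- if (is.finite(a)) matrix(rbeta(nr * nc, a, 1), nr, nc) else matrix(1, nr, nc)
  eps <- if (config$noise_sd > 0) matrix(rnorm(nr * nc, sd = config$noise_sd), nr, nc) else 0
  fc <- pmin(pmax(env * U + eps, 0), 100)
  fc[ref$mask] <- NA_real_
  labels <- setNames(seq_along(driver_names()), driver_names())
  list(
    fcover = fcover_map(grid(fc, cell_size = ref$cell_size, mask = ref$mask,
                             units = "percent", name = paste0("fcover_", genus)),
                        genus = genus),
    envelope = grid(env, cell_size = ref$cell_size, mask = ref$mask,
                    units = "percent", name = "envelope"),
    elf_label = grid(lab, cell_size = ref$cell_size, mask = ref$mask,
                     units = "", name = "elf_true", labels = labels),
    margin = grid(margin, cell_size = ref$cell_size, mask = ref$mask,
                  units = "percent", name = "margin")
  )
}

#' Generate a tree-cover layer with a contiguous forest patch
#'
#' Marks approximately `forest_frac` of the pixels (a compact block in the
#' grid corner) as forest with tree cover above any masking threshold;
#' everything else gets zero tree cover. Used to exercise the forest mask.
#'
#' @param config a [generator_config()].
#' @return a `shrub_grid` of tree percent cover.
#' @export
generate_tree_cover <- function(config) {
  nr <- config$nrow; nc <- config$ncol
  v <- matrix(0, nr, nc)
  n_target <- round(config$forest_frac * nr * nc)
  if (n_target > 0) {
    ncols_full <- n_target %/% nr
    rem <- n_target %% nr
    if (ncols_full > 0) v[, seq_len(ncols_full)] <- 90
    if (rem > 0) v[seq_len(rem), ncols_full + 1L] <- 90
  }
  grid(v, cell_size = config$cell_size, units = "percent", name = "tree_fcover")
}

#' Full synthetic landscape
#'
#' DEM, driver stack, two fCover realizations with ground truth, and a
#' tree-cover layer, all deterministic under the config seed.
#'
#' @param config a [generator_config()].
#' @param limits_alnus,limits_salix limit sets (defaults from
#'   [true_limit_set()]).
#' @return list with `config`, `dem`, `stack`, `alnus`, `salix`,
#'   `tree_cover`; `alnus`/`salix` are [realize_fcover()] results.
#' @export
synthetic_landscape <- function(config = generator_config(),
                                limits_alnus = true_limit_set("Alnus"),
                                limits_salix = true_limit_set("Salix")) {
  dem <- generate_dem(config)
  stack <- derive_env_fields(dem, config)
  alnus <- realize_fcover(stack, limits_alnus, config, genus = "Alnus",
                          seed_offset = 0L)
  salix <- realize_fcover(stack, limits_salix, config, genus = "Salix",
                          seed_offset = 100L)
  list(config = config, dem = dem, stack = stack, alnus = alnus,
       salix = salix, tree_cover = generate_tree_cover(config),
       true_limits = list(Alnus = limits_alnus, Salix = limits_salix))
}

#' Two-regime niche table: shared niche at low cover, divergent above
#'
#' Builds a non-spatial analysis table in which every pixel carries at
#' least moderate cover of both genera drawn from a common environmental
#' distribution (the shared, "equalizing" regime), while pixels where a
#' genus exceeds 40 percent cover sit in genus-specific environments whose
#' displacement grows with the cover excess (the divergent, "stabilizing"
#' regime). The between-genus centroid-distance curve is therefore flat
#' (zero) at thresholds below the shared-cover floor and strictly
#' increasing above 40 percent.
#'
#' @param n number of pixels.
#' @param divergence displacement (in driver standard deviations) of each
#'   genus's environment per 60 points of cover excess above 40.
#' @param background_range cover range (percent) of the shared regime.
#' @param high_frac fraction of pixels in the divergent regime per genus.
#' @param seed integer seed.
#' @return data.frame with the 13 driver columns, `fcover_Alnus`,
#'   `fcover_Salix`, `row`, `col`.
#' @export
two_regime_niche_table <- function(n = 4000, divergence = 2,
                                   background_range = c(35, 40),
                                   high_frac = 0.4, seed = 1L) {
  set.seed(as.integer(seed))
  env <- as.data.frame(matrix(rnorm(n * 13L), n, 13L,
                              dimnames = list(NULL, driver_names())))
  draw <- function() {
    hi <- runif(n) < high_frac
    f <- runif(n, background_range[1], background_range[2])
    f[hi] <- runif(sum(hi), 40, 100)
    f
  }
  fA <- draw(); fS <- draw()
  shift_A <- divergence * pmax(fA - 40, 0) / 60
  shift_S <- divergence * pmax(fS - 40, 0) / 60
  env$elevation <- env$elevation + shift_A - shift_S
  env$TWI <- env$TWI - shift_A + shift_S
  env$slope <- env$slope + 0.5 * (shift_A - shift_S)
  env$fcover_Alnus <- fA
  env$fcover_Salix <- fS
  env$row <- seq_len(n)
  env$col <- 1L
  env
}

# Leaf-level generators -------------------------------------------------------

#' Generate gas-exchange records from the stomatal optimization model
#'
#' Draws assimilation, vapour pressure deficit and leaf-surface CO2 from
#' realistic ranges and computes stomatal conductance from
#' gs = 1.6 (1 + g1 / sqrt(VPDs)) An / CO2s (g0 = 0), plus Gaussian noise.
#' Draws yielding non-positive VPDs or CO2s are rejected and resampled.
#'
#' @param g1_true true stomatal slope (kPa^0.5), > 0.
#' @param n number of records (>= 3).
#' @param noise_sd sd of additive noise on gs (mol m-2 s-1).
#' @param genus,community_type covariate labels recorded on each row.
#' @param soil_moisture_range range (percent) for the uniform soil-moisture
#'   covariate.
#' @param seed integer seed.
#' @return data.frame with columns gs, An, VPDs, CO2s, genus,
#'   community_type, soil_moisture.
#' @export
generate_gas_exchange <- function(g1_true, n = 50, noise_sd = 0,
                                  genus = "Alnus",
                                  community_type = "alder shrubland",
                                  soil_moisture_range = c(10, 60),
                                  seed = 1L) {
  stopifnot(g1_true > 0, n >= 3)
  set.seed(as.integer(seed))
  draw_pos <- function(n, lo, hi) {
    x <- runif(n, lo, hi)
    while (any(x <= 0)) x[x <= 0] <- runif(sum(x <= 0), lo, hi)
    x
  }
  An <- runif(n, 2, 20)                    # umol m-2 s-1
  VPDs <- draw_pos(n, 0.4, 2.5)            # kPa
  CO2s <- draw_pos(n, 360, 420)            # umol mol-1
  gs <- 1.6 * (1 + g1_true / sqrt(VPDs)) * An / CO2s
  if (noise_sd > 0) gs <- pmax(gs + rnorm(n, sd = noise_sd), 0)
  data.frame(
    gs = gs, An = An, VPDs = VPDs, CO2s = CO2s,
    genus = genus,
    community_type = rep_len(community_type, n),
    soil_moisture = runif(n, soil_moisture_range[1], soil_moisture_range[2])
  )
}

#' Default genus-level trait distributions
#'
#' Trait means and standard deviations used by [generate_trait_samples()],
#' set to field-scale values for low-Arctic Alnus and Salix: LMA (g m-2),
#' LNC (mg g-1), C:N, Vcmax25 and Jmax25 (umol m-2 s-1).
#'
#' @return list with `means`, `sds` (genus x trait matrices) and `n` (the
#'   per-trait measurement counts of the reference field campaigns).
#' @export
default_trait_distributions <- function() {
  traits <- c("LMA", "LNC", "CN", "Vcmax25", "Jmax25")
  means <- rbind(
    Alnus = c(93.3, 24.6, 20.5, 63.5, 116.6),
    Salix = c(98.7, 20.8, 24.3, 76.7, 157.4)
  )
  sds <- rbind(
    Alnus = c(12.3, 3.5, 2.9, 10.5, 17.8),
    Salix = c(17.1, 3.7, 4.4, 20.9, 37.0)
  )
  colnames(means) <- colnames(sds) <- traits
  n <- rbind(Alnus = c(130, 130, 130, 30, 30),
             Salix = c(202, 202, 202, 13, 13))
  colnames(n) <- traits
  list(means = means, sds = sds, n = n)
}

#' Generate leaf-trait samples
#'
#' Gaussian draws per trait per genus, truncated at zero (redraw).
#'
#' @param genus_means,genus_sds genus x trait matrices (defaults from
#'   [default_trait_distributions()]).
#' @param n_per_genus named vector of sample sizes per genus, or a genus x
#'   trait matrix of counts.
#' @param seed integer seed.
#' @return data.frame with columns genus, trait, value.
#' @export
generate_trait_samples <- function(genus_means = default_trait_distributions()$means,
                                   genus_sds = default_trait_distributions()$sds,
                                   n_per_genus = c(Alnus = 50, Salix = 50),
                                   seed = 1L) {
  stopifnot(all(genus_sds > 0))
  set.seed(as.integer(seed))
  out <- list()
  for (g in rownames(genus_means)) {
    for (tr in colnames(genus_means)) {
      n <- if (is.matrix(n_per_genus)) n_per_genus[g, tr] else n_per_genus[[g]]
      x <- rnorm(n, genus_means[g, tr], genus_sds[g, tr])
      while (any(x <= 0)) {
        x[x <= 0] <- rnorm(sum(x <= 0), genus_means[g, tr], genus_sds[g, tr])
      }
      out[[length(out) + 1L]] <- data.frame(genus = g, trait = tr, value = x)
    }
  }
  do.call(rbind, out)
}
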