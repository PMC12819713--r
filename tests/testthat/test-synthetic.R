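test_that("DEM generation is deterministic, spans the relief range, and is autocorrelated", {
  cfg <- generator_config(nrow = 48, ncol = 48, seed = 9)
  d1 <- generate_dem(cfg)
  d2 <- generate_dem(cfg)
  expect_identical(d1$values, d2$values)
  expect_equal(range(d1$values), c(0, 650))
  # semivariance grows with lag on a power-law surface
  ev <- empirical_variogram(d1, sample_fraction = 1, n_lags = 10,
                            max_lag = 500, seed = 1)
  expect_lt(mean(ev$gamma[1:3]), mean(ev$gamma[8:10]))
})

test_that("derived environmental fields honour the configured couplings", {
  land <- small_landscape()
  tab <- small_table()
  expect_named(land$stack$layers, driver_names())
  # lapse-rate coupling: temperature falls with elevation
  expect_lt(cor(tab$Tmax, tab$elevation), 0)
  expect_lt(cor(tab$Tmin, tab$elevation), 0)
  # orographic coupling: precipitation rises with elevation
  expect_gt(cor(tab$rain, tab$elevation), 0)
  expect_gt(cor(tab$snow, tab$elevation), 0)
  # soil layers are piecewise constant over the coarse product blocks
  f <- land$config$soil_block_factor
  blk <- land$stack$layers$ALD$values[1:f, 1:f]
  expect_equal(max(blk) - min(blk), 0)
  # deficit is ET0 - AET by definition
  expect_equal(tab$deficit, tab$ET0 - tab$AET, tolerance = 1e-9)
})

test_that("degenerate suppression reproduces the envelope exactly", {
  cfg <- generator_config(nrow = 40, ncol = 40, cell_size = 25,
                          suppression_a = Inf, noise_sd = 0, seed = 5)
  dem <- generate_dem(cfg)
  stack <- derive_env_fields(dem, cfg)
  rf <- realize_fcover(stack, true_limit_set("Alnus"), cfg)
  expect_equal(rf$fcover$grid$values, rf$envelope$values, tolerance = 1e-12)
})

test_that("realized cover hugs the envelope from below", {
  land <- small_landscape()
  fc <- land$alnus$fcover$grid$values
  env <- land$alnus$envelope$values
  frac_below <- mean(fc <= env + 3 * land$config$noise_sd)
  expect_gte(frac_below, 0.995)
})

test_that("true argmin label switches where two limit curves cross", {
  # elevation limit falls, TWI limit constant; they cross where the bump
  # equals the constant
  curves <- setNames(lapply(driver_names(), function(v) limit_curve("flat", peak = 95)),
                     driver_names())
  curves$elevation <- limit_curve("bump", peak = 95, center = 0, width = 200, floor = 5)
  curves$TWI <- limit_curve("flat", peak = 60)
  attr(curves, "active") <- c("elevation", "TWI")
  # crossing: 5 + 90 exp(-0.5 (x/200)^2) = 60 -> x* = 200 sqrt(2 log(90/55))
  xstar <- 200 * sqrt(2 * log(90 / 55))
  cfg <- generator_config(nrow = 8, ncol = 50, cell_size = 25,
                          suppression_a = Inf, noise_sd = 0, seed = 1)
  dem <- generate_dem(cfg)
  stack <- derive_env_fields(dem, cfg)
  # overwrite elevation with a clean gradient crossing xstar
  ramp <- matrix(rep(seq(0, 650, length.out = 50), each = 8), 8, 50)
  stack$layers$elevation$values <- ramp
  rf <- realize_fcover(stack, curves, cfg)
  lab <- driver_names()[rf$elf_label$values]
  # below the crossing the falling elevation limit still sits above 60, so
  # the constant TWI limit binds; beyond it the elevation limit takes over
  expect_true(all(lab[ramp < xstar - 10] == "TWI"))
  expect_true(all(lab[ramp > xstar + 10] == "elevation"))
})

test_that("gas-exchange generator follows the stomatal model deterministically", {
  g <- generate_gas_exchange(1.59, n = 30, noise_sd = 0, seed = 4)
  expect_identical(g, generate_gas_exchange(1.59, n = 30, noise_sd = 0, seed = 4))
  expect_equal(g$gs, 1.6 * (1 + 1.59 / sqrt(g$VPDs)) * g$An / g$CO2s,
               tolerance = 1e-12)
  # direct evaluation: An = 10, VPDs = 1, CO2s = 400, g1 = 1.59
  expect_equal(predict_gs(1.59, 10, 1, 400), 1.6 * 2.59 * 10 / 400,
               tolerance = 1e-12)
  expect_equal(predict_gs(1.59, 10, 1, 400), 0.1036, tolerance = 1e-12)
  # g0 = 0: no assimilation, no conductance
  expect_equal(predict_gs(1.59, 0, 1, 400), 0)
  expect_true(all(g$VPDs > 0) && all(g$CO2s > 0) && all(g$gs >= 0))
})

test_that("trait sampling is positive, sized as requested, and centered correctly", {
  tt <- generate_trait_samples(n_per_genus = c(Alnus = 400, Salix = 400), seed = 8)
  expect_true(all(tt$value > 0))
  dists <- default_trait_distributions()
  for (g in c("Alnus", "Salix")) {
    for (tr in colnames(dists$means)) {
      x <- tt$value[tt$genus == g & tt$trait == tr]
      expect_equal(length(x), 400)
      expect_lt(abs(mean(x) - dists$means[g, tr]),
                3 * dists$sds[g, tr] / sqrt(400) + 0.05 * dists$sds[g, tr])
    }
  }
  # per-trait field-campaign counts honoured when given as a matrix
  tt2 <- generate_trait_samples(n_per_genus = dists$n, seed = 1)
  expect_equal(sum(tt2$genus == "Alnus" & tt2$trait == "LMA"), 130)
  expect_equal(sum(tt2$genus == "Salix" & tt2$trait == "LMA"), 202)
  expect_equal(sum(tt2$genus == "Salix" & tt2$trait == "Vcmax25"), 13)
})

test_that("spherical-field simulator reproduces the requested variance", {
  vs <- vapply(1:4, function(s) {
    var(as.vector(simulate_spherical_field(64, 64, 25, 300, psill = 2, seed = s)$values))
  }, numeric(1))
  expect_equal(mean(vs), 2, tolerance = 0.25)
})

test_that("two-regime niche table separates genera only above 40 percent cover", {
  tab <- two_regime_niche_table(n = 2000, seed = 5)
  lowA <- tab$fcover_Alnus <= 40
  expect_true(all(tab$fcover_Alnus > 0))
  # below the shared floor both genera occupy every pixel
  expect_equal(sum(tab$fcover_Alnus > 30), nrow(tab))
  # divergence confined to the high-cover regime
  expect_gt(mean(tab$elevation[tab$fcover_Alnus > 60]),
            mean(tab$elevation[lowA]))
})
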