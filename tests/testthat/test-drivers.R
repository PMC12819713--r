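make_signal_table <- function(n = 400, seed = 1L, signal = function(d) 3 * d$elevation) {
  tab <- iid_driver_table(n, seed)
  tab$fcover_Alnus <- pmin(pmax(50 + signal(tab) + rnorm(n, sd = 1), 0), 100)
  tab
}

test_that("ensemble fitting is reproducible and validates its inputs", {
  tab <- make_signal_table(150, seed = 2)
  e1 <- fit_rf_ensemble(tab, "fcover_Alnus", n_models = 3, n_trees = 50, seed = 5)
  e2 <- fit_rf_ensemble(tab, "fcover_Alnus", n_models = 3, n_trees = 50, seed = 5)
  expect_identical(e1$holdout, e2$holdout)
  expect_identical(predict(e1$models[[2]], data = tab[driver_names()])$predictions,
                   predict(e2$models[[2]], data = tab[driver_names()])$predictions)
  expect_error(fit_rf_ensemble(tab[, -1], "fcover_Alnus"), "ET0")
  expect_error(fit_rf_ensemble(tab[1:50, ], "fcover_Alnus"), "100 rows")
  # single-model ensemble works
  e3 <- fit_rf_ensemble(tab, "fcover_Alnus", n_models = 1, n_trees = 50, seed = 5)
  expect_equal(e3$n_models, 1)
})

test_that("ensemble-mean prediction beats the average single model on held-out data", {
  tab <- make_signal_table(300, seed = 3,
                           signal = function(d) 8 * sin(d$elevation) + 5 * d$TWI)
  test_tab <- make_signal_table(300, seed = 99,
                                signal = function(d) 8 * sin(d$elevation) + 5 * d$TWI)
  ens <- fit_rf_ensemble(tab, "fcover_Alnus", n_models = 8, n_trees = 100, seed = 4)
  preds <- sapply(ens$models, function(m) {
    predict(m, data = test_tab[driver_names()])$predictions
  })
  y <- test_tab$fcover_Alnus
  mse_single <- mean(apply(preds, 2, function(p) mean((y - p)^2)))
  mse_ens <- mean((y - rowMeans(preds))^2)
  expect_lte(mse_ens, mse_single)
})

test_that("permutation importance isolates the informative driver", {
  tab <- make_signal_table(400, seed = 6, signal = function(d) 10 * d$elevation)
  ens <- fit_rf_ensemble(tab, "fcover_Alnus", n_models = 8, n_trees = 100, seed = 7)
  vip <- variable_importance(ens, seed = 7)
  expect_equal(vip$driver[vip$rank == 1], "elevation")
  expect_gt(vip$vip_mean[vip$driver == "elevation"],
            3 * max(vip$vip_mean[vip$driver != "elevation"]))
  # irrelevant drivers hover near zero importance
  irrel <- vip[vip$driver != "elevation", ]
  expect_true(all(abs(irrel$vip_mean) <= pmax(2 * irrel$vip_sd, 5)))
  expect_setequal(vip$rank, 1:13)
})

test_that("permuting a constant column changes nothing", {
  tab <- make_signal_table(200, seed = 8)
  tab$ALD <- 1  # constant driver
  ens <- fit_rf_ensemble(tab, "fcover_Alnus", n_models = 2, n_trees = 50, seed = 9)
  vip <- variable_importance(ens, seed = 9)
  expect_equal(vip$vip_mean[vip$driver == "ALD"], 0)
  expect_equal(vip$vip_sd[vip$driver == "ALD"], 0)
})

test_that("symmetric drivers earn equal importance within ensemble spread", {
  tab <- iid_driver_table(500, seed = 10)
  tab$fcover_Alnus <- pmin(pmax(50 + 6 * tab$rain + 6 * tab$snow +
                                  rnorm(500, sd = 1), 0), 100)
  ens <- fit_rf_ensemble(tab, "fcover_Alnus", n_models = 10, n_trees = 150, seed = 11)
  vip <- variable_importance(ens, seed = 11)
  vr <- vip[vip$driver == "rain", ]
  vs <- vip[vip$driver == "snow", ]
  expect_lt(abs(vr$vip_mean - vs$vip_mean), 2 * (vr$vip_sd + vs$vip_sd))
})

test_that("at_means profile tracks a linear response with slope ~ 2", {
  tab <- iid_driver_table(600, seed = 12)
  tab$fcover_Alnus <- pmin(pmax(50 + 2 * tab$Tmax, 0), 100)
  ens <- fit_rf_ensemble(tab, "fcover_Alnus", n_models = 4, n_trees = 200, seed = 13)
  prof <- partial_profile(ens, "Tmax", n_grid = 30)
  # interior slope (forests flatten at the range edges)
  inner <- prof[prof$value > quantile(tab$Tmax, 0.15) &
                prof$value < quantile(tab$Tmax, 0.85), ]
  slope <- coef(lm(response_mean ~ value, inner))[2]
  expect_equal(unname(slope), 2, tolerance = 0.3)
  expect_error(partial_profile(ens, "sunshine"), "unknown driver")
})

test_that("constant-response model gives a flat profile", {
  tab <- iid_driver_table(200, seed = 14)
  tab$fcover_Alnus <- rep(42, 200)
  ens <- fit_rf_ensemble(tab, "fcover_Alnus", n_models = 2, n_trees = 50, seed = 15)
  prof <- partial_profile(ens, "slope")
  expect_equal(diff(range(prof$response_mean)), 0, tolerance = 1e-9)
})

test_that("classical pdp recovers an additive component up to a constant", {
  tab <- iid_driver_table(200, seed = 16)
  gfun <- function(x) 8 * sin(1.5 * x)
  tab$fcover_Alnus <- pmin(pmax(
    50 + gfun(tab$elevation) + 4 * tab$TWI, 0), 100)
  ens <- fit_rf_ensemble(tab, "fcover_Alnus", n_models = 3, n_trees = 200, seed = 17)
  prof <- partial_profile(ens, "elevation", n_grid = 25, mode = "pdp")
  inner <- prof$value > -1.5 & prof$value < 1.5
  got <- prof$response_mean[inner] - mean(prof$response_mean[inner])
  want <- gfun(prof$value[inner]) - mean(gfun(prof$value[inner]))
  expect_gt(cor(got, want), 0.95)
})

test_that("profile of unimodal single-driver data peaks at the generator optimum", {
  set.seed(18)
  tab <- iid_driver_table(800, seed = 18)
  tab$elevation <- runif(800, 0, 650)
  tab$fcover_Alnus <- 90 * exp(-0.5 * ((tab$elevation - 300) / 130)^2)
  ens <- fit_rf_ensemble(tab, "fcover_Alnus", n_models = 3, n_trees = 200, seed = 19)
  prof <- partial_profile(ens, "elevation", n_grid = 50)
  step <- diff(prof$value[1:2])
  expect_lt(abs(prof$value[which.max(prof$response_mean)] - 300), 1.5 * step)
})

test_that("VIF matches closed forms for orthogonal, correlated and duplicated drivers", {
  # mutually orthogonal columns -> VIF = 1
  set.seed(23)
  n <- 64
  # orthonormal, column-centered basis: internal standardization preserves
  # exact orthogonality
  qq <- qr.Q(qr(scale(matrix(rnorm(n * 13), n, 13), scale = FALSE)))
  ortho <- as.data.frame(qq)
  names(ortho) <- driver_names()
  expect_equal(unname(compute_vif(ortho)), rep(1, 13), tolerance = 1e-9)
  # exact sample correlation 0.8 between two drivers, rest orthogonal
  rho <- ortho
  rho$AET <- 0.8 * ortho$ET0 + 0.6 * ortho$AET
  v <- compute_vif(rho)
  expect_equal(unname(v["ET0"]), 1 / (1 - 0.64), tolerance = 1e-6)
  expect_equal(unname(v["AET"]), 1 / (1 - 0.64), tolerance = 1e-6)
  # duplicated column -> infinite VIF with warning
  dup <- ortho
  dup$AET <- dup$ET0
  expect_warning(vd <- compute_vif(dup), "collinear")
  expect_true(is.infinite(vd["ET0"]) && is.infinite(vd["AET"]))
  expect_error(compute_vif(ortho[1:10, ]), "14 rows")
})

test_that("scale scan flags uninformative cover and respects resolution bounds", {
  cfg <- generator_config(nrow = 60, ncol = 60, cell_size = 25, seed = 20)
  dem <- generate_dem(cfg)
  stack <- derive_env_fields(dem, cfg)
  set.seed(21)
  noise <- fcover_map(grid(matrix(runif(3600, 0, 100), 60, 60), cell_size = 25),
                      "Alnus")
  sc <- scale_scan(noise, stack, resolutions = c(25, 100), n_trees = 100, seed = 22)
  expect_true(all(sc$scan$variance_explained <= 0.05))
  expect_error(scale_scan(noise, stack, resolutions = c(10, 25)), "native")
})
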