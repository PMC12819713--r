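# deterministic 300-point envelope instance used against the frozen LP optimum
rq_instance <- function() {
  set.seed(42)
  n <- 300
  x <- sort(runif(n, 0, 10))
  y <- pmin(pmax(80 * exp(-0.5 * ((x - 5) / 2)^2) * rbeta(n, 5, 1) +
                   rnorm(n, 0, 2), 0), 100)
  list(x = x, y = y)
}

test_that("quantile spline objective matches the linear-programming optimum", {
  inst <- rq_instance()
  fit <- suppressWarnings(fit_quantile_spline(inst$x, inst$y, tau = 0.99))
  # optimum of the identical LP (basis + pinball objective), solved with an
  # independent simplex/interior-point LP solver and frozen
  lp_optimum <- 28.768847595497
  expect_lt(abs(fit$pinball - lp_optimum), 1e-6)
})

test_that("interior-point solver agrees with an exact simplex oracle at run time", {
  skip_if_not_installed("boot")
  set.seed(7)
  x <- runif(60)
  y <- 2 + 3 * x + rnorm(60)
  B <- cbind(1, x)
  co <- shrubelf:::rq_fit(B, y, 0.5)
  ours <- pinball_loss(y - as.vector(B %*% co), 0.5)
  n <- 60; p <- 2; tau <- 0.5
  sx <- boot::simplex(a = c(rep(0, 2 * p), rep(tau, n), rep(1 - tau, n)),
                      A3 = cbind(B, -B, diag(n), -diag(n)), b3 = y)
  expect_lt(abs(ours - sx$value), 1e-6)
})

test_that("constant response fits the empirical tau-quantile; degenerate x errors", {
  set.seed(43)
  x <- runif(500, 0, 10)
  y <- rep(50, 500)
  fit <- suppressWarnings(fit_quantile_spline(x, y))
  expect_equal(predict(fit, c(2, 5, 8)), rep(50, 3), tolerance = 1e-6)
  expect_error(fit_quantile_spline(rep(1, 500), runif(500, 0, 10)), "degenerate")
  expect_error(fit_quantile_spline(x[1:100], y[1:100]), "200")
})

test_that("envelope recovery on Beta(5,1)-suppressed data is tight at n = 20000", {
  set.seed(44)
  n <- 20000
  x <- runif(n, 0, 650)
  E <- function(z) 5 + 89 * exp(-0.5 * ((z - 300) / 130)^2)
  y <- pmin(pmax(E(x) * rbeta(n, 5, 1), 0), 100)
  fit <- fit_quantile_spline(x, y, tau = 0.99)
  xs <- seq(min(x), max(x), length.out = 400)
  # the 99th percentile of Beta(5,1) suppression is 0.99^(1/5)
  mae <- mean(abs(predict(fit, xs) - E(xs) * 0.99^(1 / 5)))
  expect_lt(mae, 3)
  expect_gte(fit$exceedance, 0.002)
  expect_lte(fit$exceedance, 0.03)
})

test_that("no extrapolation: boundary values are held outside the training range", {
  set.seed(45)
  x <- runif(400, 2, 8)
  y <- pmin(pmax(10 * x * rbeta(400, 5, 1), 0), 100)
  fit <- suppressWarnings(fit_quantile_spline(x, y))
  expect_equal(predict(fit, -5), predict(fit, min(x)))
  expect_equal(predict(fit, 50), predict(fit, max(x)))
  expect_true(all(predict(fit, seq(-10, 60, 1)) >= 0))
  expect_true(all(predict(fit, seq(-10, 60, 1)) <= 100))
})

test_that("all 13 curves fit, reload exactly, and ignore row order", {
  tab <- small_table()
  curves <- suppressWarnings(fit_all_limit_curves(tab, "Alnus"))
  expect_length(curves, 13)
  expect_named(curves, driver_names())
  p <- tempfile(fileext = ".json")
  write_limit_curves(curves, p)
  back <- read_limit_curves(p)
  xs <- seq(0, 650, length.out = 101)
  expect_identical(predict(back$elevation, xs), predict(curves$elevation, xs))
  # permuting rows leaves the convex fit unchanged
  set.seed(46)
  perm <- tab[sample.int(nrow(tab)), ]
  curves2 <- suppressWarnings(fit_all_limit_curves(perm, "Alnus"))
  expect_equal(predict(curves2$slope, 0:40), predict(curves$slope, 0:40),
               tolerance = 1e-6)
})

test_that("envelope fits are stable across 4 to 8 interior knots", {
  tab <- small_table()
  xs <- seq(quantile(tab$elevation, 0.05), quantile(tab$elevation, 0.95),
            length.out = 100)
  preds <- sapply(c(4, 6, 8), function(k) {
    f <- suppressWarnings(
      fit_quantile_spline(tab$elevation, tab$fcover_Alnus, n_interior_knots = k))
    predict(f, xs)
  })
  expect_lt(mean(abs(preds[, 1] - preds[, 3])), 2)
})

test_that("binned-maximum validation: near-perfect recovery and equal-count bins", {
  tab <- small_table()
  curves <- suppressWarnings(fit_all_limit_curves(tab, "Alnus"))
  # score the curves against data lying exactly on a shallow envelope
  tab2 <- tab
  shallow <- suppressWarnings(
    fit_quantile_spline(tab$elevation, 60 + 0.01 * tab$elevation +
                          runif(nrow(tab), -0.01, 0.01), tau = 0.99))
  one <- structure(list(elevation = shallow), class = "shrub_limitset",
                   genus = "Alnus", tau = 0.99)
  tab2$fcover_Alnus <- predict(shallow, tab2$elevation)
  val1 <- binned_max_validation(one, tab2)
  expect_equal(val1$pooled$slope, 1, tolerance = 0.05)
  expect_gt(val1$pooled$r2, 0.99)
  expect_lt(val1$pooled$rmse, 1)
  # equal-count binning balances bin populations to within one row
  val <- binned_max_validation(curves, tab)
  pops <- val$bins$n[val$bins$driver == "elevation"]
  expect_lte(max(pops) - min(pops), 1)
  expect_equal(val$pooled$n_bins, nrow(val$bins))
})

test_that("potential prediction obeys the Liebig minimum over driver subsets", {
  land <- small_landscape()
  tab <- small_table()
  curves <- suppressWarnings(fit_all_limit_curves(tab, "Alnus"))
  parts <- lapply(c("climate", "topography", "soil", "combined"),
                  function(s) predict_potential(curves, land$stack, s))
  names(parts) <- c("climate", "topography", "soil", "combined")
  expect_length(parts$climate$per_driver, 8)
  expect_length(parts$topography$per_driver, 3)
  expect_length(parts$soil$per_driver, 2)
  for (s in c("climate", "topography", "soil")) {
    expect_true(all(parts$combined$potential$values <=
                      parts[[s]]$potential$values + 1e-9))
  }
  # single-driver subset equals that curve's prediction
  solo <- predict_potential(curves, land$stack, "soil")
  expect_equal(solo$per_driver$ALD$values,
               matrix(predict(curves$ALD, as.vector(land$stack$layers$ALD$values)),
                      100, 100))
  expect_true(all(grid_values(parts$combined$potential) >= 0 &
                    grid_values(parts$combined$potential) <= 100))
})

test_that("ELF labels take the argmin with canonical-order tie breaking", {
  mk <- function(v) grid(matrix(v, 1, 1), cell_size = 1)
  res <- determine_elf(list(radiation = mk(60), elevation = mk(30), Tmax = mk(80)))
  expect_equal(names(res$elf_label$labels)[res$elf_label$values[1, 1]], "elevation")
  expect_equal(res$potential$values[1, 1], 30)
  expect_equal(res$tie$values[1, 1], 0)
  # exact tie between slope and TWI resolves to slope (earlier canonical order)
  res2 <- determine_elf(list(TWI = mk(30), slope = mk(30), rain = mk(90)))
  expect_equal(names(res2$elf_label$labels)[res2$elf_label$values[1, 1]], "slope")
  expect_equal(res2$tie$values[1, 1], 1)
  expect_error(determine_elf(list(a = mk(1))), "2")
})

test_that("growth potential differences and negative-count bookkeeping", {
  pot <- grid(matrix(c(52, 80), 1, 2), cell_size = 1)
  obs <- grid(matrix(c(20, 90), 1, 2), cell_size = 1)
  gp <- growth_potential(pot, obs)
  expect_equal(as.vector(gp$values), c(32, -10))
  expect_equal(attr(gp, "n_negative"), 1)
})

test_that("mean growth potential reflects the Beta suppression gap", {
  # with cover = E * U, E[U] = a/(a+1) = 5/6: mean gap ~ mean(E)/6
  cfg <- generator_config(nrow = 60, ncol = 60, cell_size = 25,
                          noise_sd = 0, seed = 47)
  dem <- generate_dem(cfg)
  stack <- derive_env_fields(dem, cfg)
  rf <- realize_fcover(stack, true_limit_set("Alnus"), cfg)
  gp <- growth_potential(rf$envelope, rf$fcover)
  want <- mean(grid_values(rf$envelope)) / 6
  expect_equal(unname(attr(gp, "summary")["mean"]), want, tolerance = 0.1 * want)
})

test_that("ELF frequencies sum to one overall and per stratum", {
  land <- small_landscape()
  tab <- small_table()
  curves <- suppressWarnings(fit_all_limit_curves(tab, "Salix"))
  pots <- predict_potential(curves, land$stack, "combined")
  elf <- determine_elf(pots$per_driver)
  fr <- elf_frequency(elf)
  expect_equal(sum(fr$overall$frequency), 1, tolerance = 1e-12)
  for (L in unique(fr$by_class$class)) {
    expect_equal(sum(fr$by_class$frequency[fr$by_class$class == L]), 1,
                 tolerance = 1e-12)
  }
  # single-label map
  mk <- function(v) grid(matrix(v, 2, 2), cell_size = 1)
  solo <- determine_elf(list(snow = mk(20), rain = mk(70)))
  fs <- elf_frequency(solo)
  expect_equal(fs$overall$frequency[fs$overall$driver == "snow"], 1)
})
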