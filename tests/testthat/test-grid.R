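test_that("grid constructor enforces shape, cell size and mask invariants", {
  expect_error(grid(matrix(1, 2, 2), cell_size = -1), "cell_size")
  expect_error(grid(matrix(1, 2, 2), cell_size = 1, mask = matrix(FALSE, 3, 2)),
               "dimensions")
  g <- grid(matrix(c(1, NA, 3, Inf), 2, 2), cell_size = 1)
  expect_equal(sum(g$mask), 2)  # non-finite cells always masked
  expect_equal(grid_values(g), c(1, 3))
})

test_that("raster write/read round-trips values, mask and metadata", {
  set.seed(11)
  g <- grid(matrix(rnorm(120, sd = 200), 10, 12),
            cell_size = 5.2, mask = matrix(runif(120) < 0.15, 10, 12),
            units = "percent", name = "cover")
  p <- tempfile(fileext = ".tif")
  write_raster(g, p)
  g2 <- read_raster(p)
  expect_identical(g2$mask, g$mask)
  expect_lt(max(abs(g2$values - g$values), na.rm = TRUE), 1e-4)
  expect_equal(g2$cell_size, 5.2)
  expect_equal(g2$units, "percent")
  expect_error(read_raster(tempfile(fileext = ".tif")), "not found")
})

test_that("categorical rasters round-trip integer codes and label tables", {
  set.seed(3)
  labels <- setNames(1:4, c("elevation", "slope", "TWI", "snow"))
  g <- grid(matrix(sample(1:4, 48, TRUE), 6, 8), cell_size = 250,
            labels = labels)
  p <- tempfile(fileext = ".tif")
  write_raster(g, p)
  g2 <- read_raster(p)
  expect_identical(g2$values, g$values)
  expect_equal(unlist(g2$labels), labels)
})

test_that("values outside float32 range are rejected on write", {
  g <- grid(matrix(c(1, 1e39), 1, 2), cell_size = 1)
  expect_error(write_raster(g, tempfile(fileext = ".tif")), "float32")
})

test_that("non-square cells are rejected on read", {
  g <- grid(matrix(1:6, 2, 3), cell_size = 10)
  p <- tempfile(fileext = ".tif")
  write_raster(g, p)
  meta <- jsonlite::read_json(paste0(p, ".json"), simplifyVector = TRUE)
  meta$cell_size_y <- 20
  jsonlite::write_json(meta, paste0(p, ".json"), auto_unbox = TRUE, digits = NA)
  expect_error(read_raster(p), "non-square cells")
})

test_that("block aggregation follows the mean/mask contract", {
  g <- grid(matrix(c(10, 30, 20, 40), 2, 2), cell_size = 5)
  a <- aggregate_grid(g, 10)
  expect_equal(as.vector(a$values), 25)
  expect_equal(a$cell_size, 10)
  # block with 3 of 4 masked at min_valid_frac 0.5 -> masked
  gm <- grid(matrix(c(10, NA, NA, NA), 2, 2), cell_size = 5)
  expect_true(aggregate_grid(gm, 10)$mask[1, 1])
  expect_equal(as.vector(aggregate_grid(gm, 10, min_valid_frac = 0.25)$values), 10)
  # no upsampling
  expect_error(aggregate_grid(g, 2), "smaller")
  # 100x100 of 5 m cells to 250 m -> 2x2
  big <- grid(matrix(runif(1e4, 0, 100), 100, 100), cell_size = 5)
  agg <- aggregate_grid(big, 250)
  expect_equal(dim(agg$values), c(2L, 2L))
  expect_true(all(agg$values >= 0 & agg$values <= 100))
  # conservation of the global mean on fully valid grids
  expect_equal(mean(agg$values), mean(big$values), tolerance = 1e-12)
  # max and majority methods
  expect_equal(as.vector(aggregate_grid(g, 10, method = "max")$values), 40)
  gc <- grid(matrix(c(1, 1, 2, 1), 2, 2), cell_size = 5)
  expect_equal(as.vector(aggregate_grid(gc, 10, method = "majority")$values), 1)
})

test_that("forest masking removes tree-dominated pixels and logs the count", {
  fc <- fcover_map(grid(matrix(50, 2, 2), cell_size = 1), "Alnus")
  trees <- grid(matrix(c(60, 10, 0, 55), 2, 2), cell_size = 1)
  out <- suppressMessages(apply_forest_mask(fc, trees, threshold = 50))
  expect_equal(attr(out, "n_masked"), 2)
  expect_true(out$grid$mask[1, 1])
  # all-zero tree layers change nothing
  none <- suppressMessages(apply_forest_mask(fc, grid(matrix(0, 2, 2), cell_size = 1), 50))
  expect_equal(attr(none, "n_masked"), 0)
  # misaligned grids error
  expect_error(
    suppressMessages(apply_forest_mask(fc, grid(matrix(0, 3, 3), cell_size = 1), 50)),
    "misaligned")
})

test_that("forest masking on the synthetic stack masks exactly the generator's forest fraction", {
  land <- small_landscape()
  n_before <- sum(!land$alnus$fcover$grid$mask)
  out <- suppressMessages(
    apply_forest_mask(land$alnus$fcover, land$tree_cover, threshold = 50))
  expect_equal(attr(out, "n_masked") / n_before, land$config$forest_frac,
               tolerance = 1e-9)
})

test_that("stack_to_table flattens aligned grids and inverts cleanly", {
  land <- small_landscape()
  nsmall <- 2L
  # hand-built 2x2 stack with one masked pixel
  layers <- lapply(driver_names(), function(v) {
    grid(matrix(seq_len(4) + match(v, driver_names()), nsmall, nsmall),
         cell_size = 1, name = v)
  })
  names(layers) <- driver_names()
  layers$ET0$values[1, 1] <- NA
  layers$ET0$mask[1, 1] <- TRUE
  st <- env_stack(layers)
  fc <- fcover_map(grid(matrix(c(10, 20, 30, 40), nsmall, nsmall), cell_size = 1),
                   "Alnus")
  tab <- stack_to_table(st, fc)
  expect_equal(nrow(tab), 3)
  expect_equal(names(tab)[1:13], driver_names())
  # column means match per-grid unmasked means (shared mask)
  expect_equal(mean(tab$AET), mean(grid_values(st$layers$AET)))
  # table -> grid -> table identity on valid pixels
  g2 <- table_to_grid(tab, "fcover_Alnus", fc$grid)
  tab2 <- stack_to_table(st, fcover_map(g2, "Alnus"))
  expect_equal(tab2$fcover_Alnus, tab$fcover_Alnus)
  # empty intersection errors
  allmask <- grid(matrix(NA_real_, nsmall, nsmall), cell_size = 1)
  expect_error(stack_to_table(st, fcover_map(allmask, "Salix")), "no pixel")
})

test_that("resampling matches template geometry; nearest keeps categories", {
  src <- grid(outer(1:10, 1:10, `+`), cell_size = 10)
  tmpl <- grid(matrix(0, 5, 5), cell_size = 20)
  out <- resample_to_match(src, tmpl)
  expect_equal(dim(out$values), c(5L, 5L))
  expect_equal(out$cell_size, 20)
  catg <- grid(matrix(sample(1:3, 100, TRUE), 10, 10), cell_size = 10,
               labels = c(a = 1, b = 2, c = 3))
  outc <- resample_to_match(catg, tmpl)
  expect_true(all(outc$values %in% 1:3))
})
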