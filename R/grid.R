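#' @importFrom stats aggregate approx coef complete.cases cor lm median na.omit
#'   optim prcomp predict quantile rbeta rnorm runif sd setNames t.test var
#' @importFrom utils head read.csv tail write.csv
NULL

# Canonical driver vocabulary ------------------------------------------------

#' Canonical environmental driver names and groups
#'
#' The 13 drivers used throughout the package, in canonical order:
#' eight climate layers (reference and actual evapotranspiration, their
#' difference as water deficit, shortwave radiation, rain, snow water
#' equivalent, annual maximum and minimum air temperature), three topographic
#' layers (elevation, slope, topographic wetness index) and two permafrost
#' soil layers (active layer depth, annual ground temperature).
#'
#' @return `driver_names()` returns a character vector of length 13.
#'   `driver_groups()` returns a named character vector mapping each driver
#'   to one of `"climate"`, `"topography"`, `"soil"`.
#' @export
driver_names <- function() {
  c("ET0", "AET", "deficit", "radiation", "rain", "snow", "Tmax", "Tmin",
    "elevation", "slope", "TWI", "ALD", "AGT")
}

#' @rdname driver_names
#' @export
driver_groups <- function() {
  setNames(
    c(rep("climate", 8), rep("topography", 3), rep("soil", 2)),
    driver_names()
  )
}

# Grid -----------------------------------------------------------------------

#' Construct a grid (single-band raster)
#'
#' A `shrub_grid` is the universal spatial carrier: a matrix of values, a
#' logical nodata mask of the same shape, a square cell size in meters, a
#' units string and a name. Masked cells are ignored by all statistics.
#'
#' @param values numeric matrix.
#' @param cell_size cell edge length in meters (> 0). Cells are square.
#' @param mask logical matrix, `TRUE` where the cell carries no data.
#'   Non-finite values are always masked in addition.
#' @param units free-text units label.
#' @param name identifier used in tables and file output.
#' @param labels optional named integer vector mapping category labels to
#'   stored integer codes, for categorical grids.
#' @return an object of class `shrub_grid`.
#' @export
grid <- function(values, cell_size, mask = NULL, units = "", name = "grid",
                 labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || !is.finite(cell_size) ||
      cell_size <= 0) {
    stop("cell_size must be a single positive number (meters)")
  }
  if (is.null(mask)) mask <- matrix(FALSE, nrow(values), ncol(values))
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(values))) {
    stop("mask and values must have identical dimensions")
  }
  mask <- mask | !is.finite(values)
  values[mask] <- NA_real_
  structure(
    list(values = values, mask = mask, cell_size = as.numeric(cell_size),
         units = units, name = name, labels = labels),
    class = "shrub_grid"
  )
}

#' @export
print.shrub_grid <- function(x, ...) {
  v <- grid_values(x)
  cat(sprintf("<shrub_grid '%s'> %d x %d cells @ %g m [%s]\n",
              x$name, nrow(x$values), ncol(x$values), x$cell_size, x$units))
  cat(sprintf("  valid: %d / %d", length(v), length(x$values)))
  if (length(v)) {
    cat(sprintf("; range %.4g .. %.4g; mean %.4g", min(v), max(v), mean(v)))
  }
  cat("\n")
  invisible(x)
}

#' @rdname grid
#' @param x object to test or extract from.
#' @export
is_grid <- function(x) inherits(x, "shrub_grid")

#' Unmasked cell values of a grid
#' @param x a `shrub_grid`.
#' @return numeric vector of valid (unmasked) cell values.
#' @export
grid_values <- function(x) {
  stopifnot(is_grid(x))
  x$values[!x$mask]
}

check_aligned <- function(...) {
  gs <- list(...)
  ref <- gs[[1L]]
  for (g in gs[-1L]) {
    if (!identical(dim(g$values), dim(ref$values))) {
      stop(sprintf("misaligned grids: '%s' is %dx%d but '%s' is %dx%d",
                   g$name, nrow(g$values), ncol(g$values),
                   ref$name, nrow(ref$values), ncol(ref$values)))
    }
    if (abs(g$cell_size - ref$cell_size) > 1e-9 * ref$cell_size) {
      stop(sprintf("misaligned grids: cell sizes %g and %g differ",
                   g$cell_size, ref$cell_size))
    }
  }
  invisible(TRUE)
}

# Fractional cover map -------------------------------------------------------

#' Construct a fractional-cover map for one genus
#'
#' Wraps a percent-cover grid (values in \[0, 100\]) together with the genus
#' it describes.
#'
#' @param grid a `shrub_grid` with unmasked values in \[0, 100\].
#' @param genus `"Alnus"` or `"Salix"`.
#' @return an object of class `shrub_fcover` (which also inherits
#'   `shrub_grid` behaviour through its `$grid` field).
#' @export
fcover_map <- function(grid, genus = c("Alnus", "Salix")) {
  genus <- match.arg(genus)
  stopifnot(is_grid(grid))
  v <- grid_values(grid)
  if (length(v) && (min(v) < -1e-9 || max(v) > 100 + 1e-9)) {
    stop("fCover values must lie in [0, 100] percent")
  }
  grid$units <- "percent"
  structure(list(grid = grid, genus = genus), class = "shrub_fcover")
}

#' @export
print.shrub_fcover <- function(x, ...) {
  cat(sprintf("<shrub_fcover> genus %s\n", x$genus))
  print(x$grid)
  invisible(x)
}

# Raster I/O -----------------------------------------------------------------
# Storage: single-channel (or data+mask two-channel) TIFF with values scaled
# to [0,1]; a JSON sidecar (<path>.json) carries cell size, units, name,
# scaling range, nodata convention and category labels. Mask is stored as a
# second channel so it round-trips exactly.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a grid to disk
#'
#' Writes a TIFF raster plus a JSON sidecar holding the geospatial metadata
#' (cell size, units, value scaling, category labels). Nodata cells are
#' encoded in a mask channel and restored exactly on read. Categorical grids
#' (those with a `labels` table) are stored as integer codes.
#'
#' @param grid a `shrub_grid`.
#' @param path output path (conventionally `.tif`).
#' @return `path`, invisibly.
#' @seealso [read_raster()]
#' @export
write_raster <- function(grid, path) {
  stopifnot(is_grid(grid))
  v <- grid$values
  fin <- v[is.finite(v)]
  if (length(fin) && max(abs(fin)) > 3.4e38) {
    stop("values outside float32 range cannot be stored")
  }
  vmin <- if (length(fin)) min(fin) else 0
  vmax <- if (length(fin)) max(fin) else 1
  span <- if (vmax > vmin) vmax - vmin else 1
  scaled <- (v - vmin) / span
  scaled[grid$mask] <- 0
  arr <- array(0, dim = c(nrow(v), ncol(v), 2L))
  arr[, , 1L] <- scaled
  arr[, , 2L] <- ifelse(grid$mask, 1, 0)
  ok <- try(tiff::writeTIFF(arr, path, bits.per.sample = 32L,
                            compression = "deflate", reduce = FALSE),
            silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop(sprintf("cannot write raster to '%s': %s", path, as.character(ok)))
  }
  meta <- list(
    name = grid$name, units = grid$units,
    cell_size_x = grid$cell_size, cell_size_y = grid$cell_size,
    vmin = vmin, vmax = vmax, nodata = -9999,
    labels = as.list(grid$labels)
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a grid from disk
#'
#' Reads a raster written by [write_raster()] (TIFF + JSON sidecar). Nodata
#' cells are masked; the cell size comes from the sidecar; units from the
#' sidecar unless overridden by the caller.
#'
#' @param path raster path.
#' @param name optional name override.
#' @param units optional units override.
#' @return a `shrub_grid`.
#' @export
read_raster <- function(path, name = NULL, units = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read raster: '%s' not found", path))
  # the data+mask layout triggers a benign ExtraSamples note from libtiff
  arr <- try(suppressWarnings(tiff::readTIFF(path)), silent = TRUE)
  if (inherits(arr, "try-error")) {
    stop(sprintf("cannot read raster '%s': not a readable TIFF", path))
  }
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop(sprintf("missing raster metadata sidecar '%s'", sp))
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  csx <- as.numeric(meta$cell_size_x)
  csy <- as.numeric(meta$cell_size_y)
  if (abs(csx - csy) > 1e-9 * max(csx, csy)) {
    stop(sprintf("non-square cells: %g m x %g m", csx, csy))
  }
  if (length(dim(arr)) == 3L) {
    vals <- arr[, , 1L]
    mask <- arr[, , 2L] > 0.5
  } else {
    vals <- arr
    mask <- matrix(FALSE, nrow(vals), ncol(vals))
  }
  span <- if (meta$vmax > meta$vmin) meta$vmax - meta$vmin else 1
  vals <- vals * span + meta$vmin
  labels <- NULL
  if (length(meta$labels)) labels <- unlist(meta$labels)
  g <- grid(vals, cell_size = csx, mask = mask,
            units = if (is.null(units)) meta$units else units,
            name = if (is.null(name)) meta$name else name,
            labels = labels)
  if (!is.null(g$labels)) g$values[!g$mask] <- round(g$values[!g$mask])
  g
}

# Aggregation ----------------------------------------------------------------

#' Block-aggregate a grid to a coarser cell size
#'
#' Aggregates by the integer block factor `round(target / source)`. An output
#' cell is masked when the fraction of valid contributing cells falls below
#' `min_valid_frac`. Trailing rows/columns that do not fill a block are
#' dropped.
#'
#' @param grid a `shrub_grid`.
#' @param target_cell_size requested cell size in meters (>= current).
#' @param method `"mean"`, `"max"` or `"majority"` (modal value, for
#'   categorical grids).
#' @param min_valid_frac minimum fraction of valid input cells per block.
#' @return a coarser `shrub_grid`.
#' @export
aggregate_grid <- function(grid, target_cell_size, method = c("mean", "max", "majority"),
                           min_valid_frac = 0.5) {
  stopifnot(is_grid(grid))
  method <- match.arg(method)
  if (target_cell_size < grid$cell_size * (1 - 1e-9)) {
    stop("target cell size is smaller than the source cell size (no upsampling)")
  }
  f <- max(1L, as.integer(round(target_cell_size / grid$cell_size)))
  if (f == 1L) return(grid)
  nr <- nrow(grid$values) %/% f
  nc <- ncol(grid$values) %/% f
  if (nr < 1L || nc < 1L) stop("grid too small for requested aggregation factor")
  v <- grid$values[seq_len(nr * f), seq_len(nc * f), drop = FALSE]
  m <- grid$mask[seq_len(nr * f), seq_len(nc * f), drop = FALSE]
  # block index per cell
  bi <- (rep(seq_len(nr), each = f))[row(v)]
  bj <- (rep(seq_len(nc), each = f))[col(v)]
  idx <- (bj - 1L) * nr + bi
  valid <- !m
  nvalid <- tabulate(idx[valid], nbins = nr * nc)
  out <- rep(NA_real_, nr * nc)
  if (method == "mean") {
    s <- rep(0, nr * nc)
    t <- tapply(v[valid], idx[valid], sum)
    s[as.integer(names(t))] <- t
    out[nvalid > 0] <- s[nvalid > 0] / nvalid[nvalid > 0]
  } else if (method == "max") {
    t <- tapply(v[valid], idx[valid], max)
    out[as.integer(names(t))] <- t
  } else {
    t <- tapply(v[valid], idx[valid], function(z) {
      tb <- table(z)
      as.numeric(names(tb)[which.max(tb)])
    })
    out[as.integer(names(t))] <- t
  }
  outmask <- nvalid < min_valid_frac * f * f | nvalid == 0L
  out[outmask] <- NA_real_
  grid(matrix(out, nr, nc), cell_size = grid$cell_size * f,
       mask = matrix(outmask, nr, nc), units = grid$units, name = grid$name,
       labels = grid$labels)
}

#' Resample a grid onto the geometry of a template grid
#'
#' Explicit alignment helper: nearest-neighbour for categorical grids,
#' bilinear for continuous ones. Cell centers are assumed to share the same
#' origin. All analysis stages require pre-aligned grids; this helper is
#' never invoked implicitly.
#'
#' @param grid grid to resample.
#' @param template grid whose shape and cell size define the target geometry.
#' @param method `"bilinear"` or `"nearest"`.
#' @return a `shrub_grid` aligned with `template`.
#' @export
resample_to_match <- function(grid, template, method = c("bilinear", "nearest")) {
  stopifnot(is_grid(grid), is_grid(template))
  method <- match.arg(method)
  if (!is.null(grid$labels)) method <- "nearest"
  nr <- nrow(template$values); nc <- ncol(template$values)
  # target cell-center coordinates in source fractional index space
  rx <- ((seq_len(nr) - 0.5) * template$cell_size) / grid$cell_size + 0.5
  cx <- ((seq_len(nc) - 0.5) * template$cell_size) / grid$cell_size + 0.5
  src <- grid$values
  out <- matrix(NA_real_, nr, nc)
  if (method == "nearest") {
    ri <- pmin(pmax(round(rx), 1L), nrow(src))
    ci <- pmin(pmax(round(cx), 1L), ncol(src))
    out <- src[ri, ci, drop = FALSE]
  } else {
    r0 <- pmin(pmax(floor(rx), 1L), nrow(src)); r1 <- pmin(r0 + 1L, nrow(src))
    c0 <- pmin(pmax(floor(cx), 1L), ncol(src)); c1 <- pmin(c0 + 1L, ncol(src))
    fr <- pmin(pmax(rx - r0, 0), 1); fc <- pmin(pmax(cx - c0, 0), 1)
    A <- src[r0, c0, drop = FALSE]; B <- src[r1, c0, drop = FALSE]
    C <- src[r0, c1, drop = FALSE]; D <- src[r1, c1, drop = FALSE]
    FR <- matrix(fr, nr, nc); FC <- matrix(fc, nr, nc, byrow = TRUE)
    out <- A * (1 - FR) * (1 - FC) + B * FR * (1 - FC) +
      C * (1 - FR) * FC + D * FR * FC
  }
  grid(out, cell_size = template$cell_size, units = grid$units,
       name = grid$name, labels = grid$labels)
}

# Forest mask ----------------------------------------------------------------

#' Mask forest-dominated pixels out of a cover map
#'
#' Pixels where the summed tree-PFT fractional cover exceeds `threshold` are
#' removed from the shrub cover map: in closed forest the shrub signal is
#' confounded by canopy interactions and under-observation of the understorey.
#'
#' @param fcover a `shrub_fcover`.
#' @param tree_fcover_layers list of `shrub_grid`s of tree-PFT percent cover,
#'   aligned with `fcover`.
#' @param threshold percent cover above which a pixel counts as forest
#'   dominated (in (0, 100\]).
#' @return a `shrub_fcover` with forest pixels masked; the number of newly
#'   masked pixels is attached as attribute `"n_masked"` and reported via
#'   `message()`.
#' @export
apply_forest_mask <- function(fcover, tree_fcover_layers, threshold) {
  stopifnot(inherits(fcover, "shrub_fcover"))
  if (!(threshold > 0 && threshold <= 100)) stop("threshold must be in (0, 100]")
  if (is_grid(tree_fcover_layers)) tree_fcover_layers <- list(tree_fcover_layers)
  do.call(check_aligned, c(list(fcover$grid), tree_fcover_layers))
  total <- Reduce(`+`, lapply(tree_fcover_layers, function(g) {
    v <- g$values; v[g$mask] <- 0; v
  }))
  newmask <- total > threshold & !fcover$grid$mask
  n_new <- sum(newmask)
  g <- fcover$grid
  g$mask <- g$mask | newmask
  g$values[g$mask] <- NA_real_
  message(sprintf("apply_forest_mask: masked %d forest-dominated pixels", n_new))
  out <- fcover_map(g, fcover$genus)
  attr(out, "n_masked") <- n_new
  out
}

# Environmental stack and table ----------------------------------------------

#' Bundle the 13 driver grids into an aligned stack
#'
#' @param layers named list of `shrub_grid`s containing exactly the 13
#'   canonical drivers (see [driver_names()]); order is normalized to
#'   canonical order and the combined nodata mask is pushed to every layer.
#' @return an object of class `shrub_envstack`.
#' @export
env_stack <- function(layers) {
  need <- driver_names()
  if (!all(need %in% names(layers))) {
    stop(sprintf("missing driver layers: %s",
                 paste(setdiff(need, names(layers)), collapse = ", ")))
  }
  layers <- layers[need]
  do.call(check_aligned, unname(layers))
  combined <- Reduce(`|`, lapply(layers, `[[`, "mask"))
  layers <- lapply(layers, function(g) {
    g$mask <- combined
    g$values[combined] <- NA_real_
    g
  })
  structure(list(layers = layers), class = "shrub_envstack")
}

#' @export
print.shrub_envstack <- function(x, ...) {
  g <- x$layers[[1L]]
  cat(sprintf("<shrub_envstack> 13 drivers, %d x %d cells @ %g m (%d valid)\n",
              nrow(g$values), ncol(g$values), g$cell_size, sum(!g$mask)))
  invisible(x)
}

#' Aggregate every layer of a stack (and cover maps) to a coarser scale
#' @param stack a `shrub_envstack`.
#' @param target_cell_size target cell size in meters.
#' @param min_valid_frac passed to [aggregate_grid()].
#' @return a `shrub_envstack` at the coarser resolution.
#' @export
aggregate_stack <- function(stack, target_cell_size, min_valid_frac = 0.5) {
  stopifnot(inherits(stack, "shrub_envstack"))
  env_stack(lapply(stack$layers, aggregate_grid,
                   target_cell_size = target_cell_size,
                   min_valid_frac = min_valid_frac))
}

#' Flatten an environmental stack (plus cover maps) to an analysis table
#'
#' One row per pixel that is unmasked in every input; driver columns come
#' first in canonical order, then one column per cover map (named
#' `fcover_<genus>`), then the pixel grid indices `row`, `col`.
#'
#' @param stack a `shrub_envstack`.
#' @param ... optional `shrub_fcover` maps aligned with the stack.
#' @return a `data.frame`.
#' @export
stack_to_table <- function(stack, ...) {
  stopifnot(inherits(stack, "shrub_envstack"))
  fmaps <- list(...)
  grids <- stack$layers
  extra <- lapply(fmaps, function(f) {
    stopifnot(inherits(f, "shrub_fcover"))
    f$grid
  })
  do.call(check_aligned, c(unname(grids), unname(extra)))
  allmask <- Reduce(`|`, lapply(c(grids, extra), `[[`, "mask"))
  keep <- which(!allmask)
  if (!length(keep)) stop("no pixel is valid in every input layer")
  nr <- nrow(grids[[1L]]$values)
  df <- as.data.frame(lapply(grids, function(g) g$values[keep]))
  names(df) <- driver_names()
  for (f in fmaps) df[[paste0("fcover_", f$genus)]] <- f$grid$values[keep]
  df$row <- ((keep - 1L) %% nr) + 1L
  df$col <- ((keep - 1L) %/% nr) + 1L
  df
}

#' Rebuild a grid from a column of an analysis table
#'
#' Inverse of [stack_to_table()] for a single column, given the original
#' geometry.
#'
#' @param table data.frame with `row`/`col` columns.
#' @param column column name to spatialize.
#' @param template `shrub_grid` supplying shape and cell size.
#' @return a `shrub_grid` masked where the table has no row.
#' @export
table_to_grid <- function(table, column, template) {
  v <- matrix(NA_real_, nrow(template$values), ncol(template$values))
  v[cbind(table$row, table$col)] <- table[[column]]
  grid(v, cell_size = template$cell_size, units = "", name = column)
}
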