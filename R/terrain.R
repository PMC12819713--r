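# Terrain derivatives: depression filling, slope, flow accumulation, TWI.
#
# Neighbourhood convention: 8-connected (D8 directions). Rows/columns index
# the value matrix directly; cell_size is the edge length in meters.

neighbor_offsets <- function() {
  # dr, dc, distance factor (1 for rook moves, sqrt(2) for diagonals)
  cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
        dc = c(-1, 0, 1, -1, 1, -1, 0, 1),
        dist = c(sqrt(2), 1, sqrt(2), 1, 1, sqrt(2), 1, sqrt(2)))
}

#' Fill closed depressions in a DEM
#'
#' Priority-flood filling: cells are processed outward from the grid
#' boundary in order of increasing spill elevation, and any cell lower than
#' the spill level of its processed neighbourhood is raised to that level.
#' The result is a surface on which every cell has a non-ascending path to
#' the boundary; cells that already drained are unchanged and the output is
#' everywhere >= the input.
#'
#' @param dem a `shrub_grid` of elevations (m). At least one boundary cell
#'   must be unmasked.
#' @return a `shrub_grid` of filled elevations.
#' @export
fill_depressions <- function(dem) {
  stopifnot(is_grid(dem))
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  n <- nr * nc
  if (all(dem$mask)) stop("DEM is fully masked")
  # boundary = grid edge cells and cells adjacent to masked cells
  off <- neighbor_offsets()
  filled <- z
  closed <- dem$mask          # masked cells never processed
  # binary heap keyed on elevation (vector-based)
  heap_key <- numeric(n); heap_val <- integer(n); heap_n <- 0L
  hpush <- function(key, val) {
    heap_n <<- heap_n + 1L
    i <- heap_n
    heap_key[i] <<- key; heap_val[i] <<- val
    while (i > 1L) {
      p <- i %/% 2L
      if (heap_key[p] <= heap_key[i]) break
      tk <- heap_key[p]; heap_key[p] <<- heap_key[i]; heap_key[i] <<- tk
      tv <- heap_val[p]; heap_val[p] <<- heap_val[i]; heap_val[i] <<- tv
      i <- p
    }
  }
  hpop <- function() {
    topv <- heap_val[1L]; topk <- heap_key[1L]
    heap_key[1L] <<- heap_key[heap_n]; heap_val[1L] <<- heap_val[heap_n]
    heap_n <<- heap_n - 1L
    i <- 1L
    while (TRUE) {
      l <- 2L * i; r <- l + 1L; s <- i
      if (l <= heap_n && heap_key[l] < heap_key[s]) s <- l
      if (r <= heap_n && heap_key[r] < heap_key[s]) s <- r
      if (s == i) break
      tk <- heap_key[s]; heap_key[s] <<- heap_key[i]; heap_key[i] <<- tk
      tv <- heap_val[s]; heap_val[s] <<- heap_val[i]; heap_val[i] <<- tv
      i <- s
    }
    list(key = topk, val = topv)
  }
  in_heap <- matrix(FALSE, nr, nc)
  is_edge <- matrix(FALSE, nr, nc)
  is_edge[1, ] <- TRUE; is_edge[nr, ] <- TRUE
  is_edge[, 1] <- TRUE; is_edge[, nc] <- TRUE
  # cells adjacent to masked cells also drain "off grid"
  if (any(dem$mask)) {
    mm <- dem$mask
    adj <- matrix(FALSE, nr, nc)
    for (k in seq_len(nrow(off))) {
      dr <- off[k, 1L]; dc <- off[k, 2L]
      rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
      ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
      sh <- matrix(FALSE, nr, nc)
      sh[ok_r, ok_c] <- mm[rs[ok_r], cs[ok_c]]
      adj <- adj | sh
    }
    is_edge <- is_edge | adj
  }
  seeds <- which(is_edge & !dem$mask)
  if (!length(seeds)) stop("no unmasked boundary cell to drain to")
  for (i in seeds) {
    hpush(z[i], i)
    in_heap[i] <- TRUE
  }
  while (heap_n > 0L) {
    top <- hpop()
    i <- top$val
    if (closed[i]) next
    closed[i] <- TRUE
    filled[i] <- max(filled[i], top$key)
    r0 <- ((i - 1L) %% nr) + 1L
    c0 <- ((i - 1L) %/% nr) + 1L
    for (k in seq_len(8L)) {
      r <- r0 + off[k, 1L]; cc <- c0 + off[k, 2L]
      if (r < 1L || r > nr || cc < 1L || cc > nc) next
      j <- (cc - 1L) * nr + r
      if (closed[j] || in_heap[j]) next
      hpush(max(z[j], filled[i]), j)
      in_heap[j] <- TRUE
    }
  }
  grid(filled, cell_size = dem$cell_size, mask = dem$mask,
       units = dem$units, name = paste0(dem$name, "_filled"))
}

#' Slope from a DEM (Horn's method)
#'
#' Horn 3x3 finite-difference gradient; edge cells use one-sided
#' differences. Returns both degree and radian grids.
#'
#' @param dem a `shrub_grid` of elevations (m), at least 3x3.
#' @return list with elements `slope_deg` and `slope_rad`.
#' @export
compute_slope <- function(dem) {
  stopifnot(is_grid(dem))
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3L || nc < 3L) stop("DEM must be at least 3x3 for slope computation")
  w <- dem$cell_size
  # pad by edge replication => one-sided differences at edges
  zp <- rbind(z[1, , drop = FALSE], z, z[nr, , drop = FALSE])
  zp <- cbind(zp[, 1, drop = FALSE], zp, zp[, nc, drop = FALSE])
  # fill masked cells with nearest finite value is overkill; Horn on NA
  # simply yields NA, which stays masked.
  sub <- function(dr, dc) zp[(1 + dr):(nr + dr), (1 + dc):(nc + dc)]
  a <- sub(0, 0); b <- sub(0, 1); cc <- sub(0, 2)
  d <- sub(1, 0);              f <- sub(1, 2)
  g <- sub(2, 0); h <- sub(2, 1); i <- sub(2, 2)
  # x increases with column, y with row; signs are irrelevant for |grad|
  dzdx <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * w)
  dzdy <- ((g + 2 * h + i) - (a + 2 * b + cc)) / (8 * w)
  # edge replication halves the effective step across the replicated edge:
  # correct by doubling the one-sided component there
  # edge replication collapses the central difference to half the one-sided
  # step; double the gradient component on edge rows/columns
  edge_r <- matrix(1, nr, nc); edge_r[c(1, nr), ] <- 2
  edge_c <- matrix(1, nr, nc); edge_c[, c(1, nc)] <- 2
  dzdy <- dzdy * edge_r
  dzdx <- dzdx * edge_c
  rad <- atan(sqrt(dzdx^2 + dzdy^2))
  mk <- dem$mask | !is.finite(rad)
  list(
    slope_deg = grid(rad * 180 / pi, cell_size = w, mask = mk,
                     units = "degree", name = "slope"),
    slope_rad = grid(rad, cell_size = w, mask = mk,
                     units = "radian", name = "slope_rad")
  )
}

# Resolve flats: returns adjusted elevation with an infinitesimal gradient
# across flat regions toward their spill cells, so that every non-boundary
# cell has a strictly lower neighbour.
resolve_flats <- function(z, mask, nr, nc) {
  off <- neighbor_offsets()
  n <- nr * nc
  has_lower <- matrix(FALSE, nr, nc)
  for (k in seq_len(8L)) {
    dr <- off[k, 1L]; dc <- off[k, 2L]
    zl <- matrix(Inf, nr, nc)
    rs <- seq_len(nr); cs <- seq_len(nc)
    rr <- rs + dr; ccx <- cs + dc
    okr <- rr >= 1 & rr <= nr; okc <- ccx >= 1 & ccx <= nc
    zl[okr, okc] <- z[rr[okr], ccx[okc]]
    zl[!is.finite(zl)] <- Inf
    has_lower <- has_lower | (zl < z)
  }
  is_edge <- matrix(FALSE, nr, nc)
  is_edge[1, ] <- TRUE; is_edge[nr, ] <- TRUE; is_edge[, 1] <- TRUE; is_edge[, nc] <- TRUE
  if (any(mask)) {
    for (k in seq_len(8L)) {
      dr <- off[k, 1L]; dc <- off[k, 2L]
      sh <- matrix(FALSE, nr, nc)
      rs <- seq_len(nr); cs <- seq_len(nc)
      rr <- rs + dr; ccx <- cs + dc
      okr <- rr >= 1 & rr <= nr; okc <- ccx >= 1 & ccx <= nc
      sh[okr, okc] <- mask[rr[okr], ccx[okc]]
      is_edge <- is_edge | sh
    }
  }
  flat <- which(!has_lower & !mask & !is_edge)
  if (!length(flat)) return(z)
  # BFS across equal-elevation cells from spill cells (flat cells adjacent to
  # a draining cell of the same elevation, or flat cells on the boundary)
  dist <- matrix(NA_integer_, nr, nc)
  frontier <- integer(0)
  for (i in flat) {
    r0 <- ((i - 1L) %% nr) + 1L; c0 <- ((i - 1L) %/% nr) + 1L
    for (k in seq_len(8L)) {
      r <- r0 + off[k, 1L]; cc2 <- c0 + off[k, 2L]
      if (r < 1L || r > nr || cc2 < 1L || cc2 > nc) next
      j <- (cc2 - 1L) * nr + r
      if (mask[j]) next
      if (abs(z[j] - z[i]) < 1e-12 && (has_lower[j] || is_edge[j])) {
        dist[i] <- 1L
        frontier <- c(frontier, i)
        break
      }
    }
  }
  if (!length(frontier)) {
    stop("unfilled pits detected (interior cells with no lower neighbor); run fill_depressions first")
  }
  flatset <- rep(FALSE, n); flatset[flat] <- TRUE
  d <- 1L
  while (length(frontier)) {
    nxt <- integer(0)
    for (i in frontier) {
      r0 <- ((i - 1L) %% nr) + 1L; c0 <- ((i - 1L) %/% nr) + 1L
      for (k in seq_len(8L)) {
        r <- r0 + off[k, 1L]; cc2 <- c0 + off[k, 2L]
        if (r < 1L || r > nr || cc2 < 1L || cc2 > nc) next
        j <- (cc2 - 1L) * nr + r
        if (!flatset[j] || !is.na(dist[j])) next
        if (abs(z[j] - z[i]) < 1e-12) {
          dist[j] <- d + 1L
          nxt <- c(nxt, j)
        }
      }
    }
    frontier <- nxt
    d <- d + 1L
  }
  if (any(flatset & is.na(dist))) {
    stop("unfilled pits detected (flat region with no spill point); run fill_depressions first")
  }
  eps <- max(abs(z[is.finite(z)]), 1) * 1e-9
  z[flat] <- z[flat] + eps * dist[flat]
  z
}

#' Flow accumulation and specific catchment area
#'
#' Routes per-cell area downslope over a depression-filled DEM and returns
#' the specific catchment area SCA = accumulated area / cell width (m).
#' `"d8"` sends all area to the steepest downslope neighbour; `"mfd"`
#' (default) splits it among all lower neighbours proportionally to
#' slope^1.1 (Freeman multiple flow direction). Every cell contributes its
#' own area; boundary cells with no lower in-grid neighbour export across
#' the grid boundary, so total exported area equals total unmasked grid
#' area. Flats produced by filling are drained toward their spill cells.
#'
#' @param dem_filled a depression-filled `shrub_grid` (see
#'   [fill_depressions()]).
#' @param method `"mfd"` or `"d8"`.
#' @return a `shrub_grid` of SCA (m) with attribute `"boundary_export"`, the
#'   total area (m^2) leaving the grid.
#' @export
flow_accumulation <- function(dem_filled, method = c("mfd", "d8")) {
  stopifnot(is_grid(dem_filled))
  method <- match.arg(method)
  z <- dem_filled$values
  nr <- nrow(z); nc <- ncol(z)
  w <- dem_filled$cell_size
  mask <- dem_filled$mask
  z[mask] <- NA_real_
  zr <- resolve_flats(z, mask, nr, nc)
  off <- neighbor_offsets()
  ord <- order(zr, decreasing = TRUE, na.last = NA)  # high to low, masked dropped
  acc <- matrix(w * w, nr, nc)  # own area
  acc[mask] <- 0
  export <- 0
  is_edge <- matrix(FALSE, nr, nc)
  is_edge[1, ] <- TRUE; is_edge[nr, ] <- TRUE; is_edge[, 1] <- TRUE; is_edge[, nc] <- TRUE
  mfd_exp <- 1.1
  for (i in ord) {
    r0 <- ((i - 1L) %% nr) + 1L; c0 <- ((i - 1L) %/% nr) + 1L
    zi <- zr[i]
    lower_j <- integer(0); lower_s <- numeric(0)
    next_to_mask <- FALSE
    for (k in seq_len(8L)) {
      r <- r0 + off[k, 1L]; cc2 <- c0 + off[k, 2L]
      if (r < 1L || r > nr || cc2 < 1L || cc2 > nc) next
      j <- (cc2 - 1L) * nr + r
      if (mask[j]) {
        next_to_mask <- TRUE  # masked cells act as sinks
        next
      }
      if (zr[j] < zi) {
        lower_j <- c(lower_j, j)
        lower_s <- c(lower_s, (zi - zr[j]) / (off[k, 3L] * w))
      }
    }
    if (!length(lower_j)) {
      if (is_edge[i]) {
        export <- export + acc[i]
      } else if (!next_to_mask) {
        stop("unfilled pits detected (cell with no lower neighbor, not on boundary); run fill_depressions first")
      }
      # area reaching a masked sink is dropped from the balance
      next
    }
    if (method == "d8") {
      j <- lower_j[which.max(lower_s)]
      acc[j] <- acc[j] + acc[i]
    } else {
      wgt <- lower_s^mfd_exp
      wgt <- wgt / sum(wgt)
      for (t in seq_along(lower_j)) {
        acc[lower_j[t]] <- acc[lower_j[t]] + acc[i] * wgt[t]
      }
    }
  }
  sca <- acc / w
  sca[mask] <- NA_real_
  out <- grid(sca, cell_size = w, mask = mask, units = "m", name = "sca")
  attr(out, "boundary_export") <- export
  out
}

#' Topographic wetness index
#'
#' TWI = ln(SCA / tan(phi)) with the slope floored at `slope_floor` radians
#' so flats yield a large but finite index: high TWI marks flat,
#' high-accumulation (wet) positions.
#'
#' @param sca specific catchment area grid (m), from [flow_accumulation()].
#' @param slope_rad slope grid in radians, from [compute_slope()].
#' @param slope_floor minimum slope (radians) used in the denominator.
#' @return a dimensionless `shrub_grid`.
#' @export
compute_twi <- function(sca, slope_rad, slope_floor = 0.001) {
  check_aligned(sca, slope_rad)
  if (any(grid_values(sca) < 0)) stop("SCA must be non-negative")
  tanphi <- tan(pmax(slope_rad$values, slope_floor))
  v <- log(pmax(sca$values, sca$cell_size * 1e-12) / tanphi)
  mk <- sca$mask | slope_rad$mask
  grid(v, cell_size = sca$cell_size, mask = mk, units = "", name = "TWI")
}

#' All terrain derivatives from a DEM
#'
#' Convenience wrapper: fill depressions, compute Horn slope, flow
#' accumulation and TWI.
#'
#' @param dem elevation `shrub_grid` (m).
#' @param method flow router, `"mfd"` or `"d8"`.
#' @param slope_floor minimum slope (radians) for the TWI denominator.
#' @return list with `dem`, `dem_filled`, `slope_deg`, `slope_rad`, `sca`,
#'   `twi` grids.
#' @export
terrain_layers <- function(dem, method = "mfd", slope_floor = 0.001) {
  filled <- fill_depressions(dem)
  sl <- compute_slope(dem)
  sca <- flow_accumulation(filled, method = method)
  twi <- compute_twi(sca, sl$slope_rad, slope_floor = slope_floor)
  list(dem = dem, dem_filled = filled, slope_deg = sl$slope_deg,
       slope_rad = sl$slope_rad, sca = sca, twi = twi)
}
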