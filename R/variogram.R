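# Patch-structure analysis: empirical semivariograms on random pixel
# subsamples, spherical-model fitting, and shrub-density class frequencies.

#' Empirical (Matheron) semivariogram of a cover map
#'
#' Randomly samples a fraction of the valid pixels and computes the
#' omnidirectional Matheron estimator
#' gamma(h) = 1/(2 N(h)) sum (z_i - z_j)^2 over point pairs, binned into
#' equal-width lag classes.
#'
#' @param fcover a `shrub_fcover` or `shrub_grid`.
#' @param sample_fraction fraction of valid pixels to sample (default 0.05).
#' @param n_lags number of equal-width lag bins.
#' @param max_lag maximum pair distance considered (m); defaults to 2000 m,
#'   capped at half the grid diagonal.
#' @param seed integer seed for the pixel subsample.
#' @param max_points hard cap on sampled points (memory guard).
#' @return object of class `shrub_variogram`: data.frame with `lag`
#'   (bin center, m), `gamma`, `n_pairs`, plus attributes.
#' @export
empirical_variogram <- function(fcover, sample_fraction = 0.05, n_lags = 30,
                                max_lag = 2000, seed = 1L, max_points = 4000) {
  g <- if (inherits(fcover, "shrub_fcover")) fcover$grid else fcover
  stopifnot(is_grid(g))
  idx <- which(!g$mask)
  if (length(idx) < 2) stop("variogram needs at least 2 valid pixels (all-masked grid?)")
  nr <- nrow(g$values)
  diag_len <- sqrt((nr * g$cell_size)^2 + (ncol(g$values) * g$cell_size)^2)
  max_lag <- min(max_lag, diag_len / 2)
  set.seed(as.integer(seed))
  n_take <- min(max(100L, round(sample_fraction * length(idx))), max_points,
                length(idx))
  s <- sample(idx, n_take)
  rr <- ((s - 1L) %% nr) + 1L
  cc <- ((s - 1L) %/% nr) + 1L
  x <- cc * g$cell_size
  y <- rr * g$cell_size
  z <- g$values[s]
  d <- as.vector(dist(cbind(x, y)))
  dz2 <- as.vector(dist(z))^2
  keep <- d > 0 & d <= max_lag
  d <- d[keep]; dz2 <- dz2[keep]
  breaks <- seq(0, max_lag, length.out = n_lags + 1L)
  bin <- findInterval(d, breaks, rightmost.closed = TRUE)
  bin[bin < 1L] <- 1L; bin[bin > n_lags] <- n_lags
  npairs <- tabulate(bin, nbins = n_lags)
  gsum <- rep(0, n_lags)
  t <- tapply(dz2, bin, sum)
  gsum[as.integer(names(t))] <- t
  gamma <- ifelse(npairs > 0, gsum / (2 * npairs), NA_real_)
  centers <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  empty <- npairs == 0
  if (any(empty)) warning(sprintf("%d empty lag bins dropped", sum(empty)))
  out <- data.frame(lag = centers[!empty], gamma = gamma[!empty],
                    n_pairs = npairs[!empty])
  structure(out, class = c("shrub_variogram", "data.frame"),
            sample_fraction = sample_fraction, seed = seed,
            n_points = n_take, max_lag = max_lag)
}

# spherical model curve
sph_model <- function(h, nugget, psill, range_m) {
  u <- pmin(h / range_m, 1)
  nugget + psill * (1.5 * u - 0.5 * u^3)
}

#' Fit a spherical model to an empirical variogram
#'
#' Weighted least squares (weights = pair counts) over (nugget, partial
#' sill, range) with box constraints and multi-start, minimizing
#' sum N(h) (gamma_hat(h) - gamma_model(h))^2.
#'
#' @param empirical a `shrub_variogram` (>= 4 lag bins).
#' @return object of class `shrub_variogram_fit`: list with `nugget`,
#'   `psill`, `range_m`, `sse`, `model = "spherical"`.
#' @export
fit_spherical <- function(empirical) {
  stopifnot(inherits(empirical, "shrub_variogram"))
  if (nrow(empirical) < 4) stop("need at least 4 lag bins to fit a spherical model")
  h <- empirical$lag; gam <- empirical$gamma; w <- empirical$n_pairs
  obj <- function(p) {
    sum(w * (gam - sph_model(h, p[1], p[2], p[3]))^2)
  }
  sill0 <- max(gam)
  hmax <- max(h)
  starts <- expand.grid(n0 = c(0, 0.2 * sill0),
                        c0 = c(0.8, 0.5) * sill0,
                        a0 = hmax * c(0.2, 0.5, 0.9))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- try(optim(as.numeric(starts[i, ]), obj, method = "L-BFGS-B",
                     lower = c(0, 1e-10, min(h) / 2),
                     upper = c(2 * sill0 + 1e-9, 3 * sill0 + 1e-9, 4 * hmax)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("spherical variogram fit did not converge from any start")
  structure(list(nugget = best$par[1], psill = best$par[2],
                 range_m = best$par[3], sse = best$value,
                 model = "spherical"),
            class = "shrub_variogram_fit")
}

#' @export
print.shrub_variogram_fit <- function(x, ...) {
  cat(sprintf("spherical variogram: nugget %.4g, partial sill %.4g, range %.4g m (SSE %.4g)\n",
              x$nugget, x$psill, x$range_m, x$sse))
  invisible(x)
}

#' Predict a fitted variogram model at given lags
#' @param object a `shrub_variogram_fit`.
#' @param lags numeric lags (m).
#' @param ... unused.
#' @return numeric semivariances.
#' @export
predict.shrub_variogram_fit <- function(object, lags, ...) {
  sph_model(lags, object$nugget, object$psill, object$range_m)
}

#' Repeated-subsample variogram ensemble
#'
#' Repeats the random subsampling and spherical fitting `reps` times and
#' summarizes per-lag semivariance and fitted parameters by their mean and
#' standard deviation, the standard guard against subsampling uncertainty.
#'
#' @inheritParams empirical_variogram
#' @param reps number of repetitions (default 20).
#' @return list with `empirical` (data.frame lag/mean/sd), `fits`
#'   (data.frame of per-rep parameters), `fit_mean`, `fit_sd`, `n_failed`.
#' @export
variogram_ensemble <- function(fcover, reps = 20, sample_fraction = 0.05,
                               n_lags = 30, max_lag = 2000, seed = 1L,
                               max_points = 4000) {
  gam_mat <- NULL; lag_ref <- NULL
  fits <- list(); n_failed <- 0L
  for (r in seq_len(reps)) {
    ev <- empirical_variogram(fcover, sample_fraction = sample_fraction,
                              n_lags = n_lags, max_lag = max_lag,
                              seed = as.integer(seed) + 1000L * r,
                              max_points = max_points)
    ft <- try(fit_spherical(ev), silent = TRUE)
    if (inherits(ft, "try-error")) {
      n_failed <- n_failed + 1L
      next
    }
    if (is.null(lag_ref)) lag_ref <- ev$lag
    gm <- rep(NA_real_, length(lag_ref))
    gm[match(round(ev$lag, 6), round(lag_ref, 6))] <- ev$gamma
    gam_mat <- rbind(gam_mat, gm)
    fits[[length(fits) + 1L]] <- data.frame(nugget = ft$nugget, psill = ft$psill,
                                            range_m = ft$range_m, sse = ft$sse)
  }
  if (n_failed > 0.25 * reps) {
    stop(sprintf("variogram ensemble: %d of %d repetitions failed", n_failed, reps))
  }
  fits <- do.call(rbind, fits)
  list(
    empirical = data.frame(lag = lag_ref,
                           gamma_mean = colMeans(gam_mat, na.rm = TRUE),
                           gamma_sd = apply(gam_mat, 2, sd, na.rm = TRUE)),
    fits = fits,
    fit_mean = colMeans(fits),
    fit_sd = apply(fits, 2, sd),
    n_failed = n_failed
  )
}

#' Shrub-density community class frequencies
#'
#' Classifies pixels into sparse (5, 25\], medium (25, 75\] and high
#' (75, 100\] percent cover communities and reports each class's share.
#' Pixels at or below 5 percent are unclassified. The primary denominator
#' is the classified pixel count; the share of the whole valid area is also
#' reported.
#'
#' @param fcover a `shrub_fcover` or `shrub_grid` of percent cover.
#' @param classes named list of `(lo, hi]` boundaries.
#' @return data.frame with class, count, frequency (of classified pixels)
#'   and frequency_of_valid.
#' @export
community_frequency <- function(fcover,
                                classes = list(sparse = c(5, 25),
                                               medium = c(25, 75),
                                               high = c(75, 100))) {
  g <- if (inherits(fcover, "shrub_fcover")) fcover$grid else fcover
  v <- grid_values(g)
  lo_all <- min(vapply(classes, `[`, numeric(1), 1))
  counts <- vapply(classes, function(b) sum(v > b[1] & v <= b[2]), numeric(1))
  n_class <- sum(counts)
  if (n_class == 0) stop("no communities: no pixel exceeds the lowest class bound")
  data.frame(
    class = names(classes),
    count = as.integer(counts),
    frequency = counts / n_class,
    frequency_of_valid = counts / length(v),
    row.names = NULL
  )
}
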