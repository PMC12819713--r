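# Environmental-limiting-factor modeling: per-driver 99th-quantile B-spline
# envelope curves, binned-maximum validation, potential-cover prediction
# under driver subsets, argmin ELF maps and growth potential.

# Quantile regression solver -------------------------------------------------
# Primal-dual interior point (Frisch-Newton) for
#   min_b  sum_i rho_tau(y_i - x_i' b)
# via the bounded dual max y'a s.t. X'a = (1-tau) X'1, a in [0,1]^n.
# p is small (spline basis), n may be tens of thousands; each iteration
# costs O(n p^2).

rq_fit <- function(X, y, tau, max_iter = 100, tol = 1e-10) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) stop("design matrix is rank deficient (degenerate x)")
  b <- as.vector(qr.coef(qrX, y))
  e <- as.vector(y - X %*% b)
  scale0 <- max(mean(abs(e)), 1e-8)
  delta <- 0.1 * scale0
  u <- pmax(e, 0) + delta
  v <- pmax(-e, 0) + delta
  a <- rep(1 - tau, n)
  s <- 1 - a
  rhs_target <- (1 - tau) * colSums(X)
  mu <- sum(u * s + v * a) / (2 * n)
  for (it in seq_len(max_iter)) {
    r_d <- as.vector(y - X %*% b - u + v)
    r_p <- rhs_target - as.vector(crossprod(X, a))
    gap <- sum(u * s + v * a)
    if (gap / n < tol * (1 + scale0) &&
        max(abs(r_d)) < 1e-9 * (1 + scale0) &&
        max(abs(r_p)) < 1e-9 * (1 + max(abs(rhs_target)))) break
    mu <- 0.1 * gap / (2 * n)
    d <- 1 / (u / s + v / a)
    g <- r_d + u - v - mu / s + mu / a
    XD <- X * d
    H <- crossprod(X, XD)
    rhs <- as.vector(crossprod(XD, g)) - r_p
    db <- tryCatch(solve(H, rhs), error = function(err) {
      solve(H + diag(1e-10 * max(diag(H)), p), rhs)
    })
    da <- d * (g - as.vector(X %*% db))
    ds <- -da
    du <- mu / s - u + (u / s) * da
    dv <- mu / a - v - (v / a) * da
    pos_step <- function(z, dz) {
      bad <- dz < 0
      if (!any(bad)) return(1)
      min(1, 0.9995 * min(-z[bad] / dz[bad]))
    }
    alpha_p <- min(pos_step(a, da), pos_step(s, ds))
    alpha_d <- min(pos_step(u, du), pos_step(v, dv))
    a <- a + alpha_p * da
    s <- s + alpha_p * ds
    u <- u + alpha_d * du
    v <- v + alpha_d * dv
    b <- b + alpha_d * db
  }
  as.vector(b)
}

#' Pinball (check) loss
#'
#' rho_tau(r) = r (tau - 1\[r < 0\]), summed over residuals. The objective
#' minimized by quantile regression.
#'
#' @param residuals numeric residuals y - fitted.
#' @param tau quantile level in (0, 1).
#' @return total pinball loss.
#' @export
pinball_loss <- function(residuals, tau) {
  sum(residuals * (tau - (residuals < 0)))
}

# B-spline basis from a stored specification (full knot sequence)
limit_basis <- function(x, boundary, interior, degree) {
  x <- pmin(pmax(x, boundary[1]), boundary[2])  # boundary-value clamping
  knots_full <- c(rep(boundary[1], degree + 1L), interior,
                  rep(boundary[2], degree + 1L))
  splines::splineDesign(knots_full, x, ord = degree + 1L)
}

#' Fit a quantile B-spline envelope (limiting curve)
#'
#' Minimizes the pinball loss of a cubic B-spline in the driver value at
#' quantile `tau` (default 0.99), approximating the upper envelope ("maximum
#' response") of cover with respect to the driver. Interior knots sit at
#' empirical quantiles of x; the solver is a primal-dual interior-point
#' method on the quantile-regression linear program. Predictions are
#' clipped to \[0, 100\] and evaluation outside the training range uses the
#' boundary value (no extrapolation).
#'
#' @param x driver values (finite, >= 200 observations).
#' @param y cover values in \[0, 100\].
#' @param tau quantile level (default 0.99).
#' @param degree spline degree (default 3).
#' @param n_interior_knots number of interior knots (default 5).
#' @param genus,driver labels stored with the curve.
#' @return object of class `shrub_limitfit` with the spline specification,
#'   coefficients, training range and the empirical exceedance fraction
#'   P(y > s(x)).
#' @export
fit_quantile_spline <- function(x, y, tau = 0.99, degree = 3,
                                n_interior_knots = 5, genus = NA_character_,
                                driver = NA_character_) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 200) stop("need at least 200 observations to fit an envelope")
  if (min(y) < -1e-9 || max(y) > 100 + 1e-9) stop("y must lie in [0, 100]")
  if (diff(range(x)) == 0) stop("degenerate x: all values identical")
  boundary <- range(x)
  interior <- unique(as.numeric(
    quantile(x, probs = seq_len(n_interior_knots) / (n_interior_knots + 1))
  ))
  interior <- interior[interior > boundary[1] & interior < boundary[2]]
  B <- limit_basis(x, boundary, interior, degree)
  coefs <- rq_fit(B, y, tau)
  fitted <- pmin(pmax(as.vector(B %*% coefs), 0), 100)
  exceed <- mean(y > fitted + 1e-9)
  if (exceed < 0.002 || exceed > 0.03) {
    warning(sprintf("envelope exceedance fraction %.3f%% outside [0.2%%, 3%%]",
                    100 * exceed))
  }
  structure(list(genus = genus, driver = driver, tau = tau, degree = degree,
                 boundary = boundary, interior_knots = interior,
                 coef = coefs, n = length(x), exceedance = exceed,
                 pinball = pinball_loss(y - as.vector(B %*% coefs), tau)),
            class = "shrub_limitfit")
}

#' Evaluate a fitted limiting curve
#' @param object a `shrub_limitfit`.
#' @param x driver values (clamped to the training range).
#' @param ... unused.
#' @return predicted potential cover, clipped to \[0, 100\].
#' @export
predict.shrub_limitfit <- function(object, x, ...) {
  B <- limit_basis(x, object$boundary, object$interior_knots, object$degree)
  pmin(pmax(as.vector(B %*% object$coef), 0), 100)
}

#' @export
print.shrub_limitfit <- function(x, ...) {
  cat(sprintf("limit curve %s/%s: tau %.2f, degree %d, %d interior knots, n %d, exceedance %.2f%%\n",
              x$genus, x$driver, x$tau, x$degree, length(x$interior_knots),
              x$n, 100 * x$exceedance))
  invisible(x)
}

#' Fit limiting curves for all 13 drivers of one genus
#'
#' @param table data.frame at the analysis scale with the 13 driver columns
#'   and the genus cover column `fcover_<genus>`.
#' @param genus `"Alnus"` or `"Salix"`.
#' @param tau quantile level.
#' @param n_interior_knots interior knots per curve.
#' @return named list of 13 `shrub_limitfit`s, class `shrub_limitset`.
#' @export
fit_all_limit_curves <- function(table, genus = c("Alnus", "Salix"), tau = 0.99,
                                 n_interior_knots = 5) {
  genus <- match.arg(genus)
  resp <- paste0("fcover_", genus)
  stopifnot(all(c(driver_names(), resp) %in% names(table)))
  fits <- list(); fails <- character(0)
  for (v in driver_names()) {
    f <- try(fit_quantile_spline(table[[v]], table[[resp]], tau = tau,
                                 n_interior_knots = n_interior_knots,
                                 genus = genus, driver = v), silent = TRUE)
    if (inherits(f, "try-error")) {
      fails <- c(fails, sprintf("%s (%s)", v, attr(f, "condition")$message))
    } else {
      fits[[v]] <- f
    }
  }
  if (length(fails)) {
    stop(sprintf("limit-curve fitting failed for: %s", paste(fails, collapse = "; ")))
  }
  structure(fits, class = "shrub_limitset", genus = genus, tau = tau)
}

#' Persist / reload limiting curves
#'
#' Curves are stored as JSON with full double precision so reloading
#' reproduces predictions exactly.
#'
#' @param curves a `shrub_limitset`.
#' @param path output JSON path.
#' @return `path` (write) / a `shrub_limitset` (read).
#' @export
write_limit_curves <- function(curves, path) {
  stopifnot(inherits(curves, "shrub_limitset"))
  ser <- lapply(curves, function(f) {
    out <- f[c("genus", "driver", "tau", "degree", "boundary",
               "interior_knots", "coef", "n", "exceedance", "pinball")]
    # hex-float copies guarantee bit-exact reload (JSON decimal printing
    # can drop the last bit)
    out$boundary_hex <- sprintf("%a", f$boundary)
    out$interior_knots_hex <- sprintf("%a", f$interior_knots)
    out$coef_hex <- sprintf("%a", f$coef)
    out
  })
  jsonlite::write_json(list(genus = attr(curves, "genus"),
                            tau = attr(curves, "tau"), curves = ser),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_limit_curves
#' @export
read_limit_curves <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fits <- lapply(obj$curves, function(f) {
    f$boundary <- if (!is.null(f$boundary_hex)) {
      as.numeric(f$boundary_hex)
    } else as.numeric(f$boundary)
    f$interior_knots <- if (!is.null(f$interior_knots_hex)) {
      as.numeric(f$interior_knots_hex)
    } else as.numeric(f$interior_knots)
    f$coef <- if (!is.null(f$coef_hex)) as.numeric(f$coef_hex) else as.numeric(f$coef)
    structure(f[setdiff(names(f), c("boundary_hex", "interior_knots_hex",
                                    "coef_hex"))],
              class = "shrub_limitfit")
  })
  structure(fits, class = "shrub_limitset", genus = obj$genus, tau = obj$tau)
}

#' Binned-maximum validation of limiting curves
#'
#' Bins each driver into `n_bins` intervals (equal-count by default, robust
#' to skewed driver distributions; `"width"` for equal-width), takes the
#' observed bin-wise maximum cover and the mean predicted envelope in the
#' bin, and regresses observed on predicted (OLS): slope, R^2 and RMSE per
#' driver plus pooled per-genus metrics over all bins. Bins with fewer than
#' 3 points are merged with their neighbour.
#'
#' @param curves a `shrub_limitset`.
#' @param table analysis table with driver columns and `fcover_<genus>`.
#' @param n_bins number of bins (default 20).
#' @param binning `"count"` (equal-count) or `"width"` (equal-width).
#' @return list of class `shrub_elf_validation`: `per_driver` data.frame,
#'   `pooled` (slope, r2, rmse, n_bins), `bins` (all bin rows).
#' @export
binned_max_validation <- function(curves, table, n_bins = 20,
                                  binning = c("count", "width")) {
  stopifnot(inherits(curves, "shrub_limitset"))
  binning <- match.arg(binning)
  genus <- attr(curves, "genus")
  resp <- paste0("fcover_", genus)
  stopifnot(resp %in% names(table))
  all_bins <- list(); per <- list()
  for (v in names(curves)) {
    x <- table[[v]]; y <- table[[resp]]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (binning == "count") {
      br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1L)))
    } else {
      br <- seq(min(x), max(x), length.out = n_bins + 1L)
    }
    bin <- findInterval(x, br, rightmost.closed = TRUE)
    bin[bin < 1L] <- 1L; bin[bin > length(br) - 1L] <- length(br) - 1L
    # merge bins with < 3 points into the left neighbour
    cnt <- tabulate(bin, nbins = length(br) - 1L)
    relabel <- seq_along(cnt)
    for (k in seq_along(cnt)) {
      if (cnt[k] < 3 && k > 1) relabel[k] <- relabel[k - 1]
    }
    bin <- relabel[bin]
    pred <- predict(curves[[v]], x)
    obs_max <- tapply(y, bin, max)
    pred_mean <- tapply(pred, bin, mean)
    bn <- tapply(y, bin, length)
    rows <- data.frame(driver = v, bin = as.integer(names(obs_max)),
                       n = as.integer(bn), observed_max = as.numeric(obs_max),
                       predicted_mean = as.numeric(pred_mean))
    all_bins[[v]] <- rows
    fitv <- lm(observed_max ~ predicted_mean, data = rows)
    per[[v]] <- data.frame(
      driver = v,
      slope = unname(coef(fitv)[2]),
      r2 = summary(fitv)$r.squared,
      rmse = sqrt(mean((rows$observed_max - rows$predicted_mean)^2)),
      n_bins = nrow(rows)
    )
  }
  bins <- do.call(rbind, all_bins)
  pooled_fit <- lm(observed_max ~ predicted_mean, data = bins)
  structure(list(
    per_driver = do.call(rbind, per),
    pooled = data.frame(
      genus = genus,
      slope = unname(coef(pooled_fit)[2]),
      r2 = summary(pooled_fit)$r.squared,
      rmse = sqrt(mean((bins$observed_max - bins$predicted_mean)^2)),
      n_bins = nrow(bins)
    ),
    bins = bins
  ), class = "shrub_elf_validation")
}

# driver subsets (Liebig groups)
subset_drivers <- function(subset = c("combined", "climate", "topography", "soil")) {
  subset <- match.arg(subset)
  if (subset == "combined") return(driver_names())
  names(driver_groups())[driver_groups() == subset]
}

#' Potential cover under a driver subset
#'
#' Applies each limiting curve of the subset to its driver layer and takes
#' the per-pixel minimum (Liebig's rule): the subset potential is the cover
#' allowed by the most restrictive driver of the subset.
#'
#' @param curves a `shrub_limitset`.
#' @param stack a `shrub_envstack` (any resolution; curves clamp to their
#'   training range).
#' @param subset `"combined"` (all 13), `"climate"` (8), `"topography"` (3)
#'   or `"soil"` (2).
#' @return list: `per_driver` (named list of potential grids) and
#'   `potential` (the subset-minimum grid).
#' @export
predict_potential <- function(curves, stack,
                              subset = c("combined", "climate", "topography", "soil")) {
  stopifnot(inherits(curves, "shrub_limitset"), inherits(stack, "shrub_envstack"))
  subset <- match.arg(subset)
  drs <- subset_drivers(subset)
  miss <- setdiff(drs, names(stack$layers))
  if (length(miss)) stop(sprintf("missing driver layer(s): %s", paste(miss, collapse = ", ")))
  ref <- stack$layers[[1L]]
  per <- list()
  for (v in drs) {
    g <- stack$layers[[v]]
    vals <- matrix(predict(curves[[v]], as.vector(g$values)),
                   nrow(g$values), ncol(g$values))
    per[[v]] <- grid(vals, cell_size = g$cell_size, mask = g$mask,
                     units = "percent", name = paste0("potential_", v))
  }
  stackpot <- array(unlist(lapply(per, `[[`, "values")),
                    dim = c(nrow(ref$values), ncol(ref$values), length(per)))
  pmin_all <- apply(stackpot, c(1, 2), min)
  list(per_driver = per,
       potential = grid(pmin_all, cell_size = ref$cell_size, mask = ref$mask,
                        units = "percent", name = paste0("potential_", subset)))
}

#' Determine the environmental limiting factor per pixel
#'
#' The ELF at a pixel is the driver whose limiting curve yields the minimum
#' potential cover there. Ties are broken by canonical driver order and
#' flagged in a tie band.
#'
#' @param per_driver_potentials named list (>= 2) of aligned potential
#'   grids, names = driver names.
#' @return object of class `shrub_elf_result`: `potential` grid (the
#'   minimum), `elf_label` categorical grid (codes follow the order of the
#'   input list; label table attached), `tie` logical grid.
#' @export
determine_elf <- function(per_driver_potentials) {
  stopifnot(length(per_driver_potentials) >= 2)
  drs <- names(per_driver_potentials)
  # canonical ordering for tie-breaks
  canon <- intersect(driver_names(), drs)
  per_driver_potentials <- per_driver_potentials[c(canon, setdiff(drs, canon))]
  drs <- names(per_driver_potentials)
  do.call(check_aligned, unname(per_driver_potentials))
  ref <- per_driver_potentials[[1L]]
  nr <- nrow(ref$values); nc <- ncol(ref$values)
  arr <- array(unlist(lapply(per_driver_potentials, `[[`, "values")),
               dim = c(nr, nc, length(drs)))
  pot <- apply(arr, c(1, 2), min)
  lab <- apply(arr, c(1, 2), which.min)  # first minimum = canonical order
  nmin <- apply(arr, c(1, 2), function(z) sum(abs(z - min(z)) < 1e-9))
  tie <- nmin > 1
  mask <- Reduce(`|`, lapply(per_driver_potentials, `[[`, "mask"))
  labels <- setNames(seq_along(drs), drs)
  structure(list(
    potential = grid(pot, cell_size = ref$cell_size, mask = mask,
                     units = "percent", name = "potential_min"),
    elf_label = grid(lab, cell_size = ref$cell_size, mask = mask,
                     units = "", name = "elf", labels = labels),
    tie = grid(tie + 0, cell_size = ref$cell_size, mask = mask,
               units = "", name = "elf_tie")
  ), class = "shrub_elf_result")
}

#' Growth potential (potential minus observed cover)
#'
#' Positive values mark headroom for expansion; negative values (observed
#' above the envelope) are retained and counted as envelope misfit.
#'
#' @param potential_combined potential-cover grid (all-driver minimum).
#' @param observed_fcover a `shrub_fcover` or grid of observed cover.
#' @return a `shrub_grid` with attributes `"n_negative"` and `"summary"`.
#' @export
growth_potential <- function(potential_combined, observed_fcover) {
  obs <- if (inherits(observed_fcover, "shrub_fcover")) observed_fcover$grid else observed_fcover
  check_aligned(potential_combined, obs)
  v <- potential_combined$values - obs$values
  mask <- potential_combined$mask | obs$mask
  g <- grid(v, cell_size = obs$cell_size, mask = mask, units = "percent",
            name = "growth_potential")
  vals <- grid_values(g)
  attr(g, "n_negative") <- sum(vals < 0)
  attr(g, "summary") <- c(mean = mean(vals), sd = sd(vals),
                          min = min(vals), max = max(vals))
  g
}

#' ELF label frequencies, overall and by potential-cover class
#'
#' @param elf_result a `shrub_elf_result`.
#' @param potential_classes breaks (percent) stratifying potential cover;
#'   default classes < 25, 25-50, > 50.
#' @return list: `overall` (driver shares summing to 1) and `by_class`
#'   (shares within each potential class).
#' @export
elf_frequency <- function(elf_result, potential_classes = c(25, 50)) {
  stopifnot(inherits(elf_result, "shrub_elf_result"))
  lab <- elf_result$elf_label
  drs <- names(lab$labels)
  lv <- lab$values[!lab$mask]
  pv <- elf_result$potential$values[!lab$mask]
  tab <- tabulate(lv, nbins = length(drs))
  overall <- data.frame(driver = drs, count = tab, frequency = tab / sum(tab))
  br <- c(-Inf, potential_classes, Inf)
  cls <- cut(pv, br)
  by_class <- do.call(rbind, lapply(levels(cls), function(L) {
    sel <- cls == L
    if (!any(sel)) return(NULL)
    t2 <- tabulate(lv[sel], nbins = length(drs))
    data.frame(class = L, driver = drs, count = t2, frequency = t2 / sum(t2))
  }))
  list(overall = overall, by_class = by_class)
}
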