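# Random-forest driver analysis: multi-resolution variance-explained scan,
# bootstrap forest ensembles, permutation importance, partial profiles and
# variance-inflation-factor screening.

#' Multi-resolution variance-explained scan
#'
#' For each candidate resolution, aggregates the cover map and every driver
#' layer (block mean), flattens to a table, fits one random-forest
#' regression of cover on the 13 drivers, and records the out-of-bag
#' variance explained. Cover-environment coupling is strongest at the scale
#' where fine-scale cover variability not attributable to the drivers has
#' been averaged out but landscape gradients are not yet blurred; the scan
#' locates that scale as the argmax of the curve.
#'
#' @param fcover a `shrub_fcover` at native resolution.
#' @param stack a `shrub_envstack` aligned with `fcover`.
#' @param resolutions candidate cell sizes (m), >= the native cell size.
#' @param n_trees trees per forest (default 500).
#' @param min_pixels resolutions yielding fewer valid pixels are skipped
#'   with a warning.
#' @param seed integer seed.
#' @return list of class `shrub_scalescan`: data.frame `scan`
#'   (resolution_m, variance_explained, n_pixels) and `best_scale` (m).
#' @export
scale_scan <- function(fcover, stack, resolutions, n_trees = 500,
                       min_pixels = 50, seed = 1L) {
  stopifnot(inherits(fcover, "shrub_fcover"), inherits(stack, "shrub_envstack"))
  resolutions <- sort(resolutions)
  native <- fcover$grid$cell_size
  if (any(resolutions < native * (1 - 1e-9))) {
    stop("all scan resolutions must be >= the native cell size")
  }
  rows <- list()
  for (res in resolutions) {
    st <- if (res > native) aggregate_stack(stack, res) else stack
    fc <- if (res > native) {
      fcover_map(aggregate_grid(fcover$grid, res), fcover$genus)
    } else fcover
    tab <- try(stack_to_table(st, fc), silent = TRUE)
    if (inherits(tab, "try-error") || nrow(tab) < min_pixels) {
      warning(sprintf("resolution %g m yields < %d valid pixels; skipped",
                      res, min_pixels))
      next
    }
    resp <- paste0("fcover_", fcover$genus)
    rf <- ranger::ranger(
      x = tab[driver_names()], y = tab[[resp]],
      num.trees = n_trees, seed = as.integer(seed), num.threads = 1,
      verbose = FALSE
    )
    rows[[length(rows) + 1L]] <- data.frame(
      resolution_m = res, variance_explained = rf$r.squared,
      n_pixels = nrow(tab)
    )
  }
  if (!length(rows)) stop("no resolution produced enough pixels to scan")
  scan <- do.call(rbind, rows)
  structure(list(scan = scan,
                 best_scale = scan$resolution_m[which.max(scan$variance_explained)]),
            class = "shrub_scalescan")
}

#' @export
print.shrub_scalescan <- function(x, ...) {
  cat(sprintf("scale scan over %d resolutions; best scale %g m (R2 = %.3f)\n",
              nrow(x$scan), x$best_scale, max(x$scan$variance_explained)))
  invisible(x)
}

#' Bootstrap random-forest ensemble
#'
#' Trains `n_models` forests, each on an independent random 75 percent
#' subsample of the table rows; the complementary 25 percent of each model
#' is retained as its held-out evaluation set for permutation importance.
#' Per-model seeds derive deterministically from the master seed.
#'
#' @param table data.frame with the 13 driver columns and one response
#'   column.
#' @param response response column name (e.g. `"fcover_Alnus"`).
#' @param n_models number of forests (default 100).
#' @param sample_frac training fraction per model (default 0.75).
#' @param n_trees trees per forest (default 500).
#' @param seed master seed.
#' @return object of class `shrub_rf_ensemble`.
#' @export
fit_rf_ensemble <- function(table, response, n_models = 100,
                            sample_frac = 0.75, n_trees = 500, seed = 1L) {
  miss <- setdiff(driver_names(), names(table))
  if (length(miss)) stop(sprintf("missing driver column(s): %s",
                                 paste(miss, collapse = ", ")))
  if (!response %in% names(table)) stop(sprintf("missing response column '%s'", response))
  if (nrow(table) < 100) stop("need at least 100 rows to fit the ensemble")
  models <- vector("list", n_models)
  holdout <- vector("list", n_models)
  n <- nrow(table)
  for (m in seq_len(n_models)) {
    sd_m <- (as.integer(seed) %% 1000003L) * 131L + m
    set.seed(sd_m)
    tr <- sample.int(n, round(sample_frac * n))
    models[[m]] <- ranger::ranger(
      x = table[tr, driver_names()], y = table[[response]][tr],
      num.trees = n_trees, seed = sd_m, num.threads = 1, verbose = FALSE
    )
    holdout[[m]] <- setdiff(seq_len(n), tr)
  }
  structure(list(models = models, holdout = holdout, table = table,
                 response = response, n_models = n_models,
                 sample_frac = sample_frac, n_trees = n_trees, seed = seed),
            class = "shrub_rf_ensemble")
}

#' Permutation variable importance (percent increase in MSE)
#'
#' For each model and driver, permutes the driver column on the model's
#' held-out rows and reports
#' 100 * (MSE_permuted - MSE_baseline) / MSE_baseline, summarized over the
#' ensemble by mean and sd. Negative values are reported, not clipped.
#'
#' @param ensemble a `shrub_rf_ensemble`.
#' @param seed seed for the permutations.
#' @return data.frame of class `shrub_vip` with driver, vip_mean, vip_sd,
#'   rank (1 = most important).
#' @export
variable_importance <- function(ensemble, seed = 1L) {
  stopifnot(inherits(ensemble, "shrub_rf_ensemble"))
  drs <- driver_names()
  imp <- matrix(NA_real_, ensemble$n_models, length(drs),
                dimnames = list(NULL, drs))
  for (m in seq_len(ensemble$n_models)) {
    ho <- ensemble$holdout[[m]]
    X <- ensemble$table[ho, drs]
    y <- ensemble$table[[ensemble$response]][ho]
    base_pred <- predict(ensemble$models[[m]], data = X, num.threads = 1)$predictions
    base_mse <- mean((y - base_pred)^2)
    set.seed((as.integer(seed) %% 1000003L) * 257L + m)
    for (v in drs) {
      Xp <- X
      Xp[[v]] <- Xp[[v]][sample.int(nrow(Xp))]
      pred <- predict(ensemble$models[[m]], data = Xp, num.threads = 1)$predictions
      imp[m, v] <- 100 * (mean((y - pred)^2) - base_mse) / base_mse
    }
  }
  out <- data.frame(driver = drs,
                    vip_mean = colMeans(imp),
                    vip_sd = apply(imp, 2, sd), row.names = NULL)
  out$rank <- rank(-out$vip_mean, ties.method = "first")
  structure(out, class = c("shrub_vip", "data.frame"), raw = imp)
}

#' Partial response profile of one driver
#'
#' `"at_means"` (default): predict on synthetic rows where the target
#' driver sweeps its observed range while every other driver is held at its
#' training mean. `"pdp"`: the classical partial dependence profile,
#' averaging predictions over all training rows at each grid value. Both
#' are summarized over the ensemble by mean and sd.
#'
#' @param ensemble a `shrub_rf_ensemble`.
#' @param driver driver name.
#' @param n_grid number of evaluation points.
#' @param mode `"at_means"` or `"pdp"`.
#' @return data.frame of class `shrub_profile` with value, response_mean,
#'   response_sd.
#' @export
partial_profile <- function(ensemble, driver, n_grid = 50,
                            mode = c("at_means", "pdp")) {
  stopifnot(inherits(ensemble, "shrub_rf_ensemble"))
  mode <- match.arg(mode)
  if (!driver %in% driver_names()) stop(sprintf("unknown driver '%s'", driver))
  tab <- ensemble$table
  xs <- seq(min(tab[[driver]]), max(tab[[driver]]), length.out = n_grid)
  resp <- matrix(NA_real_, ensemble$n_models, n_grid)
  if (mode == "at_means") {
    base <- as.data.frame(lapply(tab[driver_names()], mean))
    newdat <- base[rep(1L, n_grid), , drop = FALSE]
    newdat[[driver]] <- xs
    for (m in seq_len(ensemble$n_models)) {
      resp[m, ] <- predict(ensemble$models[[m]], data = newdat,
                           num.threads = 1)$predictions
    }
  } else {
    X <- tab[driver_names()]
    for (m in seq_len(ensemble$n_models)) {
      for (k in seq_len(n_grid)) {
        Xk <- X
        Xk[[driver]] <- xs[k]
        resp[m, k] <- mean(predict(ensemble$models[[m]], data = Xk,
                                   num.threads = 1)$predictions)
      }
    }
  }
  structure(data.frame(value = xs,
                       response_mean = colMeans(resp),
                       response_sd = apply(resp, 2, sd)),
            class = c("shrub_profile", "data.frame"),
            driver = driver, mode = mode)
}

#' Variance inflation factors of the driver set
#'
#' VIF_v = 1 / (1 - R^2_v) where R^2_v comes from the least-squares
#' regression of (standardized) driver v on all other drivers. Exact
#' collinearity yields `Inf` with a warning.
#'
#' @param env_table data.frame containing the 13 driver columns (>= 14
#'   rows).
#' @return named numeric vector of VIFs (>= 1).
#' @export
compute_vif <- function(env_table) {
  drs <- driver_names()
  miss <- setdiff(drs, names(env_table))
  if (length(miss)) stop(sprintf("missing driver column(s): %s",
                                 paste(miss, collapse = ", ")))
  if (nrow(env_table) < 14) stop("need at least 14 rows for VIF")
  X <- scale(as.matrix(env_table[drs]))
  out <- setNames(numeric(length(drs)), drs)
  for (v in drs) {
    fit <- lm(X[, v] ~ X[, setdiff(drs, v)])
    r2 <- summary(fit)$r.squared
    if (r2 > 1 - 1e-12) {
      warning(sprintf("driver '%s' is exactly collinear with the others", v))
      out[v] <- Inf
    } else {
      out[v] <- 1 / (1 - r2)
    }
  }
  out
}
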