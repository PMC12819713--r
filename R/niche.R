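# Niche differentiation in standardized 13-driver environmental space:
# threshold-scanned PCA, centroid distances, and per-driver group contrasts
# for dominated pixels.

#' PCA of the environmental space at increasing cover thresholds
#'
#' For each threshold t, pools the pixels where either genus exceeds t
#' percent cover, z-scores the 13 drivers on that pooled set, and
#' eigen-decomposes the correlation structure (via [stats::prcomp()]).
#'
#' @param env_table data.frame with the 13 driver columns plus
#'   `fcover_Alnus` and `fcover_Salix`.
#' @param thresholds percent-cover thresholds (default 10, 20, ..., 70).
#' @param min_n minimum pixels per genus for a threshold to be evaluated.
#' @return named list (one element per usable threshold) with `threshold`,
#'   `loadings`, `variance_explained` (percent per component, summing to
#'   100), `scores` and `genus` (per-score genus label).
#' @export
pca_by_threshold <- function(env_table, thresholds = seq(10, 70, by = 10),
                             min_n = 30) {
  drs <- driver_names()
  stopifnot(all(c(drs, "fcover_Alnus", "fcover_Salix") %in% names(env_table)))
  out <- list()
  for (t in thresholds) {
    selA <- env_table$fcover_Alnus > t
    selS <- env_table$fcover_Salix > t
    if (sum(selA) < min_n || sum(selS) < min_n) {
      warning(sprintf("threshold %g leaves a genus below %d pixels; skipped", t, min_n))
      next
    }
    pooled <- rbind(env_table[selA, drs], env_table[selS, drs])
    genus <- c(rep("Alnus", sum(selA)), rep("Salix", sum(selS)))
    pc <- prcomp(pooled, center = TRUE, scale. = TRUE)
    ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
    out[[as.character(t)]] <- list(
      threshold = t, loadings = pc$rotation,
      variance_explained = ve, scores = pc$x, genus = genus
    )
  }
  out
}

#' Centroid distances in standardized environmental space by threshold
#'
#' Standardizes the 13 drivers on the union of pixels where either genus
#' has positive cover, then for each threshold t computes the per-genus
#' centroid (mean of standardized drivers over pixels with that genus's
#' cover > t) and reports three Euclidean distances: each genus to the
#' combined (union) centroid and between the two genus centroids. Distances
#' relative to the combined centroid quantify how far each genus's occupied
#' environment drifts from the jointly occupied environment as communities
#' grow denser.
#'
#' @param env_table data.frame with drivers plus `fcover_Alnus`,
#'   `fcover_Salix`.
#' @param thresholds percent thresholds (default 0, 2, ..., 70).
#' @param min_n curve is reported only where both genera retain >= `min_n`
#'   pixels.
#' @return data.frame of class `shrub_centroid_curve`: threshold,
#'   d_alnus_combined, d_salix_combined, d_between, n_alnus, n_salix.
#' @export
centroid_distance_curve <- function(env_table, thresholds = seq(0, 70, by = 2),
                                    min_n = 30) {
  drs <- driver_names()
  stopifnot(all(c(drs, "fcover_Alnus", "fcover_Salix") %in% names(env_table)))
  union_sel <- env_table$fcover_Alnus > 0 | env_table$fcover_Salix > 0
  if (!any(union_sel)) stop("no pixel has positive cover for either genus")
  ref <- env_table[union_sel, drs]
  mu <- colMeans(ref)
  sdev <- vapply(ref, sd, numeric(1))
  sdev[sdev == 0] <- 1
  Z <- sweep(sweep(as.matrix(env_table[drs]), 2, mu), 2, sdev, `/`)
  rows <- list()
  for (t in thresholds) {
    selA <- env_table$fcover_Alnus > t
    selS <- env_table$fcover_Salix > t
    if (sum(selA) < min_n || sum(selS) < min_n) break
    cA <- colMeans(Z[selA, , drop = FALSE])
    cS <- colMeans(Z[selS, , drop = FALSE])
    cU <- colMeans(Z[selA | selS, , drop = FALSE])
    rows[[length(rows) + 1L]] <- data.frame(
      threshold = t,
      d_alnus_combined = sqrt(sum((cA - cU)^2)),
      d_salix_combined = sqrt(sum((cS - cU)^2)),
      d_between = sqrt(sum((cA - cS)^2)),
      n_alnus = sum(selA), n_salix = sum(selS)
    )
  }
  if (!length(rows)) stop("no threshold retains enough pixels in both genera")
  structure(do.call(rbind, rows),
            class = c("shrub_centroid_curve", "data.frame"))
}

#' Per-driver contrasts between genus-dominated pixels
#'
#' Extracts pixels dominated by each genus (cover above
#' `dominance_threshold`) and tests each driver for a difference in means
#' with Welch's unequal-variance t-test, two-sided.
#'
#' @param env_table data.frame with drivers plus `fcover_Alnus`,
#'   `fcover_Salix`.
#' @param dominance_threshold percent cover defining dominance (default 50).
#' @param alpha significance level for the flag.
#' @param p_adjust optional multiple-testing correction passed to
#'   [stats::p.adjust()] (e.g. `"BH"`); default `"none"`.
#' @return data.frame ordered by p value: driver, mean_alnus, mean_salix,
#'   t, p, significant.
#' @export
group_difference_tests <- function(env_table, dominance_threshold = 50,
                                   alpha = 0.05, p_adjust = "none") {
  drs <- driver_names()
  selA <- env_table$fcover_Alnus > dominance_threshold
  selS <- env_table$fcover_Salix > dominance_threshold
  if (sum(selA) < 2 || sum(selS) < 2) {
    stop("need at least 2 dominated pixels per genus")
  }
  rows <- lapply(drs, function(v) {
    a <- env_table[[v]][selA]; s <- env_table[[v]][selS]
    if (sd(a) == 0 && sd(s) == 0) {
      return(data.frame(driver = v, mean_alnus = mean(a), mean_salix = mean(s),
                        t = if (mean(a) == mean(s)) 0 else NA_real_,
                        p = NA_real_, note = "zero variance in both groups"))
    }
    tt <- t.test(a, s, var.equal = FALSE)
    data.frame(driver = v, mean_alnus = mean(a), mean_salix = mean(s),
               t = unname(tt$statistic), p = tt$p.value, note = "")
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = p_adjust)
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  out[order(out$p), ]
}
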