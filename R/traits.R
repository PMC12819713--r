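# Stomatal slope (g1) estimation from gas-exchange data via the unified
# stomatal optimization model, and genus-level trait comparisons.
#
# Model: gs = g0 + 1.6 (1 + g1 / sqrt(VPDs)) An / CO2s, with g0 fixed
# (default 0). With g0 fixed the model is linear in g1:
#   gs - g0 - 1.6 An / CO2s = g1 * [1.6 An / (CO2s sqrt(VPDs))]
# so the least-squares estimate is a regression through the origin. A
# diagnostic estimate from the classical linearization
#   gs CO2s / (1.6 An) - 1 = g1 / sqrt(VPDs)
# is also reported; the two agree on noiseless data.

#' Fit the stomatal slope g1
#'
#' Least-squares estimate of g1 in the unified stomatal optimization model
#' with g0 fixed, per group. Rows with An <= 0 carry no slope information
#' (gs = g0 there) and are excluded with a logged count.
#'
#' @param gas_table data.frame with columns `gs` (mol m-2 s-1), `An`
#'   (umol m-2 s-1), `VPDs` (kPa, > 0), `CO2s` (umol mol-1, > 0), plus any
#'   grouping columns.
#' @param g0 fixed intercept conductance (default 0).
#' @param groupby character vector of grouping columns (default `"genus"`);
#'   `NULL` pools everything.
#' @return data.frame of class `shrub_g1_fits`: one row per group with
#'   `g1` (kPa^0.5), `g1_linearized`, `residual_sd`, `n`, `n_excluded`.
#'   Groups with fewer than 3 usable rows are returned with `g1 = NA` and
#'   flagged `unfit`.
#' @export
fit_g1 <- function(gas_table, g0 = 0, groupby = "genus") {
  need <- c("gs", "An", "VPDs", "CO2s")
  stopifnot(all(need %in% names(gas_table)))
  if (any(gas_table$VPDs <= 0, na.rm = TRUE)) stop("VPDs must be > 0 (kPa)")
  if (any(gas_table$CO2s <= 0, na.rm = TRUE)) stop("CO2s must be > 0")
  if (is.null(groupby)) {
    gas_table$.group <- "all"
    groupby <- ".group"
  }
  key <- interaction(gas_table[groupby], drop = TRUE, sep = " / ")
  rows <- lapply(levels(key), function(k) {
    d <- gas_table[key == k, ]
    usable <- d$An > 0 & is.finite(d$gs)
    n_exc <- sum(!usable)
    d <- d[usable, ]
    meta <- d[1, groupby, drop = FALSE]
    if (nrow(d) < 3) {
      return(cbind(meta, data.frame(g1 = NA_real_, g1_linearized = NA_real_,
                                    residual_sd = NA_real_, n = nrow(d),
                                    n_excluded = n_exc, unfit = TRUE)))
    }
    z <- 1.6 * d$An / (d$CO2s * sqrt(d$VPDs))
    w <- d$gs - g0 - 1.6 * d$An / d$CO2s
    g1 <- sum(z * w) / sum(z^2)
    # classical linearization (regression of transformed gs on 1/sqrt(VPD)
    # through the origin), kept as a diagnostic
    tr <- (d$gs - g0) * d$CO2s / (1.6 * d$An) - 1
    xs <- 1 / sqrt(d$VPDs)
    g1_lin <- sum(xs * tr) / sum(xs^2)
    res <- w - g1 * z
    cbind(meta, data.frame(g1 = g1, g1_linearized = g1_lin,
                           residual_sd = if (nrow(d) > 1) sd(res) else 0,
                           n = nrow(d), n_excluded = n_exc, unfit = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (all(out$unfit)) {
    stop("no group retains enough usable rows (An > 0) to fit g1")
  }
  structure(out, class = c("shrub_g1_fits", "data.frame"), g0 = g0)
}

#' Predicted stomatal conductance from a fitted g1
#'
#' @param g1 stomatal slope (kPa^0.5).
#' @param An assimilation (umol m-2 s-1).
#' @param VPDs vapour pressure deficit (kPa).
#' @param CO2s leaf-surface CO2 (umol mol-1).
#' @param g0 intercept conductance.
#' @return gs (mol m-2 s-1).
#' @export
predict_gs <- function(g1, An, VPDs, CO2s, g0 = 0) {
  g0 + 1.6 * (1 + g1 / sqrt(VPDs)) * An / CO2s
}

#' g1 across community types and soil-moisture bins
#'
#' Grouped fits of g1 per genus x community type, and per genus x
#' soil-moisture bin (tertiles of the observed moisture by default). Groups
#' below 3 usable rows are reported unfit, not dropped.
#'
#' @param gas_table data.frame as in [fit_g1()], with `genus`,
#'   `community_type` and `soil_moisture` columns.
#' @param moisture_breaks explicit bin breaks for soil moisture, or `NULL`
#'   for tertiles.
#' @param g0 fixed intercept conductance.
#' @return list with `by_community` and `by_moisture` fit tables.
#' @export
g1_by_environment <- function(gas_table, moisture_breaks = NULL, g0 = 0) {
  stopifnot(all(c("genus", "community_type", "soil_moisture") %in% names(gas_table)))
  by_comm <- fit_g1(gas_table, g0 = g0, groupby = c("genus", "community_type"))
  if (is.null(moisture_breaks)) {
    moisture_breaks <- unique(quantile(gas_table$soil_moisture,
                                       probs = c(0, 1 / 3, 2 / 3, 1)))
  }
  gas_table$moisture_bin <- cut(gas_table$soil_moisture, moisture_breaks,
                                include.lowest = TRUE)
  by_moist <- fit_g1(gas_table, g0 = g0, groupby = c("genus", "moisture_bin"))
  list(by_community = by_comm, by_moisture = by_moist)
}

#' Summarize and test genus-level trait distributions
#'
#' Mean, sd and n per genus per trait, with a Welch (unequal-variance)
#' two-sided t-test of the Alnus-Salix contrast per trait.
#'
#' @param trait_table long-format data.frame with columns `genus`, `trait`,
#'   `value` (as produced by [generate_trait_samples()]); traits with fewer
#'   than 2 samples in either genus are skipped with a warning.
#' @param alpha significance level.
#' @return data.frame of class `shrub_trait_summary`: trait, per-genus mean
#'   / sd / n, t, p, significant.
#' @export
summarize_and_test_traits <- function(trait_table, alpha = 0.05) {
  stopifnot(all(c("genus", "trait", "value") %in% names(trait_table)))
  rows <- list()
  for (tr in unique(trait_table$trait)) {
    a <- trait_table$value[trait_table$trait == tr & trait_table$genus == "Alnus"]
    s <- trait_table$value[trait_table$trait == tr & trait_table$genus == "Salix"]
    if (length(a) < 2 || length(s) < 2) {
      warning(sprintf("trait '%s' has < 2 samples in a genus; skipped", tr))
      next
    }
    if (sd(a) == 0 && sd(s) == 0 && mean(a) == mean(s)) {
      rows[[tr]] <- data.frame(trait = tr, mean_alnus = mean(a), sd_alnus = 0,
                               n_alnus = length(a), mean_salix = mean(s),
                               sd_salix = 0, n_salix = length(s),
                               t = 0, p = 1, significant = FALSE)
      next
    }
    tt <- t.test(a, s, var.equal = FALSE)
    rows[[tr]] <- data.frame(
      trait = tr, mean_alnus = mean(a), sd_alnus = sd(a), n_alnus = length(a),
      mean_salix = mean(s), sd_salix = sd(s), n_salix = length(s),
      t = unname(tt$statistic), p = tt$p.value,
      significant = tt$p.value < alpha
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("shrub_trait_summary", "data.frame"))
}
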