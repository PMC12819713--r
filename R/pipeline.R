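# End-to-end orchestration of the study replica on a synthetic landscape
# (or user-supplied pre-aligned rasters): simulate -> terrain -> mask ->
# scale scan -> aggregate -> variogram -> driver importance -> niche ->
# ELF -> traits -> report.

#' Pipeline run configuration
#'
#' @param out_dir output directory (created if absent).
#' @param seed master seed; every stochastic stage receives a seed derived
#'   deterministically from it.
#' @param generator a [generator_config()] describing the synthetic
#'   landscape (ignored when `stack` and cover maps are supplied to
#'   [run_all()] directly).
#' @param stages character vector of stages to run, any of `"variogram"`,
#'   `"scale_scan"`, `"drivers"`, `"niche"`, `"elf"`, `"traits"`.
#' @param analysis_scale analysis cell size in m; `NULL` uses the scale-scan
#'   argmax (or the native scale if the scan stage is disabled).
#' @param scan_resolutions candidate resolutions (m) for the scale scan.
#' @param n_rf_models,n_rf_trees ensemble workload for the driver stage.
#' @param variogram_reps repetitions of the variogram subsample.
#' @param forest_threshold percent tree cover above which pixels are masked.
#' @param tau envelope quantile level.
#' @param g1_true named vector of true stomatal slopes used for the
#'   synthetic gas-exchange data (kPa^0.5).
#' @return list of class `shrub_runconfig`.
#' @export
run_config <- function(out_dir = tempfile("shrubelf_run_"), seed = 1L,
                       generator = generator_config(seed = seed),
                       stages = c("variogram", "scale_scan", "drivers",
                                  "niche", "elf", "traits"),
                       analysis_scale = NULL,
                       scan_resolutions = c(25, 50, 100, 250, 500),
                       n_rf_models = 20, n_rf_trees = 200,
                       variogram_reps = 20, forest_threshold = 50,
                       tau = 0.99, g1_true = c(Alnus = 1.02, Salix = 1.59)) {
  structure(as.list(environment()), class = "shrub_runconfig")
}

stage_file <- function(cfg, ...) file.path(cfg$out_dir, ...)

#' Run the full pipeline
#'
#' Executes the enabled stages in dependency order on a synthetic landscape
#' generated from `config$generator`; each stage writes its outputs (CSV /
#' JSON / rasters) under `config$out_dir` before the next starts, and the
#' run manifest records the config, per-file MD5 hashes and warnings.
#' Identical config and seed reproduce identical outputs.
#'
#' @param config a [run_config()].
#' @return the run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "shrub_runconfig"))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)
  note <- function(fmt, ...) message(sprintf(fmt, ...))

  note("[simulate] generating synthetic landscape (%d x %d @ %g m)",
       cfg$generator$nrow, cfg$generator$ncol, cfg$generator$cell_size)
  land <- synthetic_landscape(cfg$generator)
  write_raster(land$dem, stage_file(cfg, "dem.tif"))
  write_raster(land$alnus$fcover$grid, stage_file(cfg, "fcover_alnus.tif"))
  write_raster(land$salix$fcover$grid, stage_file(cfg, "fcover_salix.tif"))
  write_raster(land$alnus$elf_label, stage_file(cfg, "elf_true_alnus.tif"))
  write_raster(land$salix$elf_label, stage_file(cfg, "elf_true_salix.tif"))

  note("[mask] excluding forest-dominated pixels (threshold %g%%)", cfg$forest_threshold)
  fcA <- suppressMessages(
    apply_forest_mask(land$alnus$fcover, land$tree_cover, cfg$forest_threshold))
  fcS <- suppressMessages(
    apply_forest_mask(land$salix$fcover, land$tree_cover, cfg$forest_threshold))

  results <- list(seed = cfg$seed)

  if ("variogram" %in% cfg$stages) {
    note("[variogram] %d-rep ensembles", cfg$variogram_reps)
    for (side in list(list(f = fcA, tag = "alnus"), list(f = fcS, tag = "salix"))) {
      ens <- variogram_ensemble(side$f, reps = cfg$variogram_reps,
                                seed = cfg$seed)
      write.csv(ens$empirical, stage_file(cfg, sprintf("variogram_%s.csv", side$tag)),
                row.names = FALSE)
      write.csv(ens$fits, stage_file(cfg, sprintf("variogram_fits_%s.csv", side$tag)),
                row.names = FALSE)
      results[[paste0("variogram_", side$tag)]] <- as.list(ens$fit_mean)
      freq <- community_frequency(side$f)
      write.csv(freq, stage_file(cfg, sprintf("community_frequency_%s.csv", side$tag)),
                row.names = FALSE)
      results[[paste0("community_frequency_", side$tag)]] <-
        setNames(freq$frequency, freq$class)
    }
  }

  scale <- cfg$analysis_scale
  if ("scale_scan" %in% cfg$stages) {
    note("[scale_scan] %d resolutions", length(cfg$scan_resolutions))
    sc <- scale_scan(fcA, land$stack, cfg$scan_resolutions,
                     n_trees = cfg$n_rf_trees, seed = cfg$seed)
    write.csv(sc$scan, stage_file(cfg, "scale_scan.csv"), row.names = FALSE)
    results$best_scale_m <- sc$best_scale
    if (is.null(scale)) scale <- sc$best_scale
  }
  if (is.null(scale)) scale <- land$dem$cell_size

  note("[aggregate] analysis scale %g m", scale)
  stack_s <- if (scale > land$dem$cell_size) aggregate_stack(land$stack, scale) else land$stack
  agg_f <- function(f) {
    if (scale > f$grid$cell_size) fcover_map(aggregate_grid(f$grid, scale), f$genus) else f
  }
  fcA_s <- agg_f(fcA); fcS_s <- agg_f(fcS)
  tab <- stack_to_table(stack_s, fcA_s, fcS_s)
  write.csv(tab, stage_file(cfg, "analysis_table.csv"), row.names = FALSE)

  if ("drivers" %in% cfg$stages) {
    note("[drivers] %d-model ensembles, %d trees", cfg$n_rf_models, cfg$n_rf_trees)
    vif <- compute_vif(tab)
    write.csv(data.frame(driver = names(vif), vif = vif),
              stage_file(cfg, "vif.csv"), row.names = FALSE)
    for (side in list(list(resp = "fcover_Alnus", tag = "alnus"),
                      list(resp = "fcover_Salix", tag = "salix"))) {
      ens <- fit_rf_ensemble(tab, side$resp, n_models = cfg$n_rf_models,
                             n_trees = cfg$n_rf_trees, seed = cfg$seed)
      vip <- variable_importance(ens, seed = cfg$seed)
      write.csv(vip, stage_file(cfg, sprintf("vip_%s.csv", side$tag)),
                row.names = FALSE)
      results[[paste0("vip_top3_", side$tag)]] <-
        vip$driver[order(vip$rank)][1:3]
      top <- vip$driver[order(vip$rank)][1:4]
      prof <- do.call(rbind, lapply(top, function(v) {
        p <- partial_profile(ens, v)
        cbind(driver = v, p)
      }))
      write.csv(prof, stage_file(cfg, sprintf("profiles_%s.csv", side$tag)),
                row.names = FALSE)
    }
  }

  if ("niche" %in% cfg$stages) {
    note("[niche] threshold-scanned PCA and centroid distances")
    pcs <- pca_by_threshold(tab)
    ve <- do.call(rbind, lapply(pcs, function(p) {
      data.frame(threshold = p$threshold,
                 pc1 = p$variance_explained[1], pc2 = p$variance_explained[2])
    }))
    if (!is.null(ve)) write.csv(ve, stage_file(cfg, "pca_variance.csv"), row.names = FALSE)
    curve <- try(centroid_distance_curve(tab), silent = TRUE)
    if (!inherits(curve, "try-error")) {
      write.csv(curve, stage_file(cfg, "centroid_distances.csv"), row.names = FALSE)
      results$centroid_curve_max_between <- max(curve$d_between)
    } else {
      warnings_log <- c(warnings_log, "niche: centroid curve not computable")
    }
    tests <- try(group_difference_tests(tab), silent = TRUE)
    if (!inherits(tests, "try-error")) {
      write.csv(tests, stage_file(cfg, "group_difference_tests.csv"), row.names = FALSE)
    } else {
      warnings_log <- c(warnings_log, "niche: too few dominated pixels for group tests")
    }
  }

  if ("elf" %in% cfg$stages) {
    note("[elf] envelope fitting (tau = %g) and limiting-factor maps", cfg$tau)
    for (side in list(list(genus = "Alnus", tag = "alnus", truth = land$alnus),
                      list(genus = "Salix", tag = "salix", truth = land$salix))) {
      curves <- suppressWarnings(fit_all_limit_curves(tab, side$genus, tau = cfg$tau))
      write_limit_curves(curves, stage_file(cfg, sprintf("limit_curves_%s.json", side$tag)))
      val <- binned_max_validation(curves, tab)
      write.csv(val$per_driver, stage_file(cfg, sprintf("validation_%s.csv", side$tag)),
                row.names = FALSE)
      results[[paste0("validation_pooled_", side$tag)]] <-
        as.list(val$pooled[c("slope", "r2", "rmse")])
      pots <- predict_potential(curves, stack_s, "combined")
      elf <- determine_elf(pots$per_driver)
      write_raster(elf$potential, stage_file(cfg, sprintf("potential_%s.tif", side$tag)))
      write_raster(elf$elf_label, stage_file(cfg, sprintf("elf_%s.tif", side$tag)))
      fr <- elf_frequency(elf)
      write.csv(fr$overall, stage_file(cfg, sprintf("elf_frequency_%s.csv", side$tag)),
                row.names = FALSE)
      obs <- if (side$genus == "Alnus") fcA_s else fcS_s
      gp <- growth_potential(elf$potential, obs)
      write_raster(gp, stage_file(cfg, sprintf("growth_potential_%s.tif", side$tag)))
      results[[paste0("growth_potential_mean_", side$tag)]] <-
        unname(attr(gp, "summary")["mean"])
    }
  }

  if ("traits" %in% cfg$stages) {
    note("[traits] g1 fits and trait contrasts")
    gas <- rbind(
      generate_gas_exchange(cfg$g1_true[["Alnus"]], n = 60, noise_sd = 0.004,
                            genus = "Alnus", community_type = "alder shrubland",
                            seed = cfg$seed + 11L),
      generate_gas_exchange(cfg$g1_true[["Salix"]], n = 60, noise_sd = 0.004,
                            genus = "Salix", community_type = "willow shrubland",
                            seed = cfg$seed + 12L)
    )
    write.csv(gas, stage_file(cfg, "gas_exchange.csv"), row.names = FALSE)
    fits <- fit_g1(gas)
    write.csv(fits, stage_file(cfg, "g1_fits.csv"), row.names = FALSE)
    results$g1 <- setNames(fits$g1, fits$genus)
    tt <- generate_trait_samples(seed = cfg$seed + 13L)
    tsum <- summarize_and_test_traits(tt)
    write.csv(tsum, stage_file(cfg, "trait_summary.csv"), row.names = FALSE)
  }

  jsonlite::write_json(results, stage_file(cfg, "results.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  files <- sort(list.files(cfg$out_dir, full.names = TRUE))
  files <- files[!basename(files) %in% "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("shrubelf")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), c("generator", "out_dir"))],
    generator = unclass(cfg$generator),
    hashes = as.list(tools::md5sum(files)),
    warnings = warnings_log
  )
  jsonlite::write_json(manifest, stage_file(cfg, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

#' Consolidated human-readable report of a completed run
#'
#' Collects the stage outputs under `run_dir` into one summary: variogram
#' fits, density-class frequencies, top drivers, centroid distances,
#' envelope validation, ELF shares and g1 estimates. Sections whose stage
#' outputs are missing are omitted with a note.
#'
#' @param run_dir directory written by [run_all()].
#' @return character vector of report lines (also written to `report.txt`),
#'   invisibly.
#' @export
make_report <- function(run_dir) {
  lines <- c("shrubelf run report", strrep("=", 19), "")
  grab <- function(f) {
    p <- file.path(run_dir, f)
    if (file.exists(p)) read.csv(p) else NULL
  }
  res_p <- file.path(run_dir, "results.json")
  res <- if (file.exists(res_p)) jsonlite::read_json(res_p, simplifyVector = TRUE) else list()
  for (tag in c("alnus", "salix")) {
    fits <- grab(sprintf("variogram_fits_%s.csv", tag))
    if (is.null(fits)) {
      lines <- c(lines, sprintf("[%s] variogram: not run", tag))
    } else {
      lines <- c(lines, sprintf(
        "[%s] variogram range %.0f m (sd %.0f), sill %.1f",
        tag, mean(fits$range_m), sd(fits$range_m),
        mean(fits$nugget + fits$psill)))
    }
    fr <- grab(sprintf("community_frequency_%s.csv", tag))
    if (!is.null(fr)) {
      lines <- c(lines, sprintf("[%s] density classes: %s", tag,
        paste(sprintf("%s %.0f%%", fr$class, 100 * fr$frequency), collapse = ", ")))
    }
    vip <- grab(sprintf("vip_%s.csv", tag))
    if (is.null(vip)) {
      lines <- c(lines, sprintf("[%s] drivers: not run", tag))
    } else {
      top <- vip[order(vip$rank), ][1:13, ]
      lines <- c(lines, sprintf("[%s] driver importance (%%IncMSE):", tag),
                 sprintf("    %-10s %7.2f +- %.2f", top$driver, top$vip_mean,
                         top$vip_sd))
    }
    val <- grab(sprintf("validation_%s.csv", tag))
    if (!is.null(val)) {
      pooled <- res[[paste0("validation_pooled_", tag)]]
      if (!is.null(pooled)) {
        lines <- c(lines, sprintf(
          "[%s] envelope validation: slope %.3f, R2 %.3f, RMSE %.2f",
          tag, pooled$slope, pooled$r2, pooled$rmse))
      }
    }
    fr2 <- grab(sprintf("elf_frequency_%s.csv", tag))
    if (!is.null(fr2)) {
      fr2 <- fr2[order(-fr2$frequency), ][1:3, ]
      lines <- c(lines, sprintf("[%s] top limiting factors: %s", tag,
        paste(sprintf("%s %.0f%%", fr2$driver, 100 * fr2$frequency), collapse = ", ")))
    }
  }
  cd <- grab("centroid_distances.csv")
  if (!is.null(cd)) {
    lines <- c(lines, sprintf(
      "niche: between-genus centroid distance %.2f at threshold 0, %.2f at max threshold %g",
      cd$d_between[1], tail(cd$d_between, 1), tail(cd$threshold, 1)))
  }
  g1f <- grab("g1_fits.csv")
  if (!is.null(g1f)) {
    lines <- c(lines, sprintf("g1 (kPa^0.5): %s",
      paste(sprintf("%s %.3f", g1f$genus, g1f$g1), collapse = ", ")))
  }
  writeLines(lines, file.path(run_dir, "report.txt"))
  invisible(lines)
}
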