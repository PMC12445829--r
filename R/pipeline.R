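# End-to-end orchestration: climate + phenology + ring files in, calibrated
# phenology model, frost-risk records and trends, chronologies, residual
# frost-year calls, concordance, climate-growth grids and SEA out. Every
# stage consumes and produces plain files/data.frames so any stage can be
# re-run in isolation; all randomness derives from the config seed.

#' Pipeline configuration
#'
#' @param sites list of per-site lists with fields `site_id`, `latitude`,
#'   `elevation`, `climate_csv`, `rwl_sensitive`, `rwl_reference` and
#'   optionally `exclude_series` (character vector of discarded core ids).
#' @param pheno_csv path to the leaf-out observations CSV used for model
#'   calibration.
#' @param out_dir output directory (created if needed).
#' @param frost_threshold frost threshold in degC, within [-10, 0].
#' @param window damage window offsets around leaf-out (default `c(-5, 14)`).
#' @param moderate_z,severe_z,tree_fraction indicator thresholds, see
#'   [flag_frost_years()].
#' @param spline_nyrs detrending spline cutoff in years (default 30).
#' @param sea_lags,sea_nboot SEA settings, see [superposed_epoch()].
#' @param corr_variables climate variables for the daywise correlation grid.
#' @param corr_start_doys,corr_window_lengths correlation grid axes.
#' @param periods list of year ranges for period counts.
#' @param calib_control control list passed to [calibrate()].
#' @param seed master seed.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(sites, pheno_csv, out_dir,
                            frost_threshold = -1,
                            window = c(-5L, 14L),
                            moderate_z = -1, severe_z = -1.5,
                            tree_fraction = 0.6,
                            spline_nyrs = 30,
                            sea_lags = 0:4, sea_nboot = 999L,
                            corr_variables = c("tmin", "tmax"),
                            corr_start_doys = 1:270,
                            corr_window_lengths = seq(15, 90, by = 5),
                            periods = list(),
                            calib_control = list(max_calls = 3000L),
                            seed = 1L) {
  check_scalar_number(frost_threshold, "frost_threshold", lower = -10, upper = 0)
  check_scalar_number(tree_fraction, "tree_fraction", lower = 0, upper = 1)
  for (s in sites) {
    for (f in c("site_id", "latitude", "climate_csv", "rwl_sensitive", "rwl_reference"))
      if (is.null(s[[f]])) stop_field("sites", paste("missing field", f))
    for (f in c("climate_csv", "rwl_sensitive", "rwl_reference"))
      if (!file.exists(s[[f]]))
        stop_field("sites", sprintf("file not found: %s", s[[f]]))
  }
  if (!file.exists(pheno_csv)) stop_field("pheno_csv", paste("file not found:", pheno_csv))
  structure(list(sites = sites, pheno_csv = pheno_csv, out_dir = out_dir,
                 frost_threshold = frost_threshold, window = window,
                 moderate_z = moderate_z, severe_z = severe_z,
                 tree_fraction = tree_fraction, spline_nyrs = spline_nyrs,
                 sea_lags = sea_lags, sea_nboot = sea_nboot,
                 corr_variables = corr_variables,
                 corr_start_doys = corr_start_doys,
                 corr_window_lengths = corr_window_lengths,
                 periods = periods, calib_control = calib_control,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write a synthetic two-species study fixture to disk
#'
#' Emulates the study design on disk: per site one daily climate CSV and two
#' Tucson/RWL files (frost-sensitive and reference species, two cores per
#' tree), plus one combined leaf-out observation CSV -- the same formats the
#' pipeline reads, so synthetic fixtures and real data are interchangeable.
#'
#' @param configs a [synthetic_config()] or list of them (one per site).
#' @param out_dir writable directory (created if needed).
#' @return data.frame manifest: `file, type, site_id`.
#' @export
make_fixtures <- function(configs, out_dir) {
  if (inherits(configs, "synthetic_config")) configs <- list(configs)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  pheno_all <- list()
  for (cfg in configs) {
    cl <- generate_climate(cfg)
    fy <- unique(vapply(cfg$frost_events, `[[`, numeric(1), "year"))
    climate_path <- file.path(out_dir, sprintf("climate_%s.csv", cfg$site_id))
    write_climate_csv(cl, climate_path)
    files[[length(files) + 1]] <- c(climate_path, "climate", cfg$site_id)
    for (sp in c("frost_sensitive", "reference")) {
      rwl <- generate_ring_series(cl, fy, cfg, species = sp)
      p <- file.path(out_dir, sprintf("rings_%s_%s.rwl", cfg$site_id,
                                      if (sp == "frost_sensitive") "sensitive" else "reference"))
      write_rwl(rwl, p, precision = 0.001)
      files[[length(files) + 1]] <- c(p, "rwl", cfg$site_id)
    }
    pheno_all[[cfg$site_id]] <- generate_phenology(cl, cfg$true_m1_params,
                                                   cfg$pheno_noise_sd,
                                                   seed = cfg$seed + 7L)
  }
  pheno_path <- file.path(out_dir, "phenology.csv")
  write_pheno_csv(do.call(rbind, pheno_all), pheno_path)
  files[[length(files) + 1]] <- c(pheno_path, "phenology", "all")
  out <- as.data.frame(do.call(rbind, files), stringsAsFactors = FALSE)
  names(out) <- c("file", "type", "site_id")
  out
}

run_stage <- function(name, code) {
  tryCatch(code, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full frost-reconstruction pipeline
#'
#' Executes, in order: M1 calibration on the observation CSV; leaf-out
#' prediction for every site-year; last-frost / safety-margin / damage-window
#' records and their Theil-Sen trends; RWL ingest, spline detrending, core
#' averaging, species chronologies and quality statistics; the residual
#' z-score indicator and frost-year calls; the concordance table; daywise
#' climate-growth correlation grids; and superposed epoch analysis. All
#' tabular outputs are written as CSV (trends and the run manifest as JSON)
#' under `config$out_dir`. Deterministic given the config seed: a rerun
#' writes byte-identical files.
#'
#' @param config a [pipeline_config()].
#' @return the run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  warn_log <- character()
  note <- function(path) written <<- c(written, path)
  sites_meta <- do.call(rbind, lapply(config$sites, function(s)
    data.frame(site_id = s$site_id, latitude = s$latitude,
               elevation = s$elevation %||% NA_real_)))

  climate_by_site <- run_stage("climate ingest", {
    out <- list()
    for (s in config$sites)
      out[[s$site_id]] <- read_climate_csv(s$climate_csv, sites_meta)[[s$site_id]]
    out
  })
  observations <- run_stage("phenology ingest", read_pheno_csv(config$pheno_csv))

  ctrl <- utils::modifyList(config$calib_control, list(seed = config$seed))
  fit <- run_stage("M1 calibration",
                   calibrate(climate_by_site, observations, control = ctrl))
  calib_path <- file.path(config$out_dir, "calibration.json")
  jsonlite::write_json(list(params = unclass(fit$params),
                            train_rmse = fit$train_rmse, null_rmse = fit$null_rmse,
                            n_site_years = fit$n_site_years,
                            optimizer_calls = fit$optimizer_calls,
                            seed = fit$seed, bounds = fit$bounds,
                            degenerate = fit$degenerate),
                       calib_path, auto_unbox = TRUE, digits = NA)
  note(calib_path)

  results <- list(calibration = fit)
  margins_by_site <- list()
  trends <- list()
  for (s in config$sites) {
    cl <- climate_by_site[[s$site_id]]
    years <- sort(unique(cl$year))
    years <- years[vapply(years, function(y) {
      d <- cl$doy[cl$year == y]; min(d) == 1 && max(d) >= 200
    }, logical(1))]
    pred <- run_stage("leaf-out prediction",
                      predict_leafout_years(cl, years, fit$params))
    rec <- run_stage("frost risk",
                     safety_margin_records(cl, pred,
                                           threshold = config$frost_threshold,
                                           window = config$window))
    margins_by_site[[s$site_id]] <- rec
    p <- file.path(config$out_dir, sprintf("safety_margin_%s.csv", s$site_id))
    utils::write.csv(rec, p, row.names = FALSE, quote = FALSE)
    note(p)
    trends[[s$site_id]] <- run_stage("trend tests", list(
      leafout = unclass(theil_sen_trend(rec$leafout_doy, rec$year)),
      last_frost = unclass(theil_sen_trend(rec$last_frost_doy, rec$year)),
      safety_margin = unclass(theil_sen_trend(rec$margin_days, rec$year))
    ))
  }
  trend_path <- file.path(config$out_dir, "trends.json")
  jsonlite::write_json(trends, trend_path, auto_unbox = TRUE, digits = NA)
  note(trend_path)
  results$margins <- margins_by_site
  results$trends <- trends

  results$rings <- list()
  for (s in config$sites) {
    cl <- climate_by_site[[s$site_id]]
    site_res <- list()
    for (sp in c("sensitive", "reference")) {
      raw <- run_stage("RWL ingest",
                       read_rwl(s[[paste0("rwl_", sp)]]))
      rwi <- withCallingHandlers(
        run_stage("detrending",
                  detrend_rwl(raw, nyrs = config$spline_nyrs,
                              exclude = s$exclude_series %||% character())),
        warning = function(w) {
          warn_log <<- c(warn_log, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      trees <- average_cores(rwi)
      chron <- biweight_chronology(trees)
      stats_ <- chronology_stats(trees)
      p <- file.path(config$out_dir, sprintf("chronology_%s_%s.csv", s$site_id, sp))
      utils::write.csv(chron, p, row.names = FALSE, quote = FALSE)
      note(p)
      site_res[[sp]] <- list(rwi = rwi, trees = trees, chronology = chron,
                             stats = stats_)
    }
    res_z <- run_stage("residual indicator",
                       residual_series(site_res$sensitive$trees,
                                       site_res$reference$chronology))
    res_chron <- build_site_residual_chronology(res_z)
    calls <- flag_frost_years(res_z, config$moderate_z, config$severe_z,
                              config$tree_fraction)
    p <- file.path(config$out_dir, sprintf("frost_calls_%s.csv", s$site_id))
    utils::write.csv(calls, p, row.names = FALSE, quote = FALSE)
    note(p)
    conc <- run_stage("concordance",
                      concordance_table(calls, margins_by_site[[s$site_id]],
                                        climate = cl,
                                        threshold = config$frost_threshold,
                                        window = config$window))
    if (nrow(conc$table)) {
      p <- file.path(config$out_dir, sprintf("concordance_%s.csv", s$site_id))
      utils::write.csv(conc$table, p, row.names = FALSE, quote = FALSE)
      note(p)
    }
    pc <- if (length(config$periods)) period_counts(calls, config$periods) else NULL
    grids <- run_stage("daywise correlations", {
      do.call(rbind, lapply(config$corr_variables, function(v)
        daywise_correlations(res_chron, cl, variable = v,
                             start_doys = config$corr_start_doys,
                             window_lengths = config$corr_window_lengths)))
    })
    p <- file.path(config$out_dir, sprintf("daywise_correlations_%s.csv", s$site_id))
    utils::write.csv(grids, p, row.names = FALSE, quote = FALSE)
    note(p)
    ev <- calls$year[calls$flagged]
    sea <- list()
    if (length(ev) >= 2) {
      for (sp in c("sensitive", "reference")) {
        sea[[sp]] <- run_stage("superposed epoch analysis",
                               superposed_epoch(site_res[[sp]]$chronology, ev,
                                                lags = config$sea_lags,
                                                n_boot = config$sea_nboot,
                                                seed = config$seed))
        p <- file.path(config$out_dir, sprintf("sea_%s_%s.csv", s$site_id, sp))
        utils::write.csv(as.data.frame(sea[[sp]]), p, row.names = FALSE, quote = FALSE)
        note(p)
      }
    } else {
      warn_log <- c(warn_log,
                    sprintf("site %s: < 2 flagged years, SEA skipped", s$site_id))
    }
    results$rings[[s$site_id]] <-
      list(species = site_res, residual_z = res_z,
           residual_chronology = res_chron, calls = calls,
           concordance = conc, period_counts = pc, grids = grids, sea = sea)
  }

  inputs <- c(vapply(config$sites, `[[`, character(1), "climate_csv"),
              vapply(config$sites, `[[`, character(1), "rwl_sensitive"),
              vapply(config$sites, `[[`, character(1), "rwl_reference"),
              config$pheno_csv)
  input_md5 <- tools::md5sum(inputs)
  names(input_md5) <- basename(names(input_md5))
  manifest <- list(
    package = "frostring",
    version = as.character(utils::packageVersion("frostring")),
    seed = config$seed,
    input_md5 = as.list(input_md5),
    files = basename(written),
    warnings = warn_log
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$results <- results
  invisible(manifest)
}
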