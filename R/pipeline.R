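.config_defaults <- function() {
  list(
    n_iter = 1000,
    master_seed = 1,
    dbh_model = list(family = "weibull", scale = 8.593, shape = 0.737,
                     rate = NULL, d_min = 10, d_max = 400),
    height_model = list(a = 50.453, b = 0.0471, c = 0.8120, sigma = 5.7),
    agb_model = list(alpha = 0.0673, beta = 0.976, sigma_ln = 0.357,
                     coef_rel_sd = 0.004),
    synthetic = list(n_plots = 50, area = 0.5, stem_density = 500,
                     n_taxa = 50, n_calibration = 1000),
    grid = list(pixel_size = 1000, origin_x = 0, origin_y = 0,
                crs = "EPSG:3395"),
    scenario = "best",
    paths = list(out_dir = ".")
  )
}

# overlay user values onto defaults, rejecting unknown keys by name
.merge_config <- function(defaults, user, prefix = "") {
  for (key in names(user)) {
    full <- paste0(prefix, key)
    if (!key %in% names(defaults))
      stop("unknown configuration key: '", full, "'")
    if (is.list(defaults[[key]]) && !is.null(user[[key]])) {
      if (!is.list(user[[key]]))
        stop("configuration key '", full, "' must be a mapping")
      defaults[[key]] <- .merge_config(defaults[[key]], user[[key]],
                                       paste0(full, "."))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration file, fills documented defaults (1000 Monte
#' Carlo iterations; Weibull diameter model with scale 8.593, shape 0.737 on
#' \[10, 400\] cm; default height and AGB allometries; 1-km EPSG:3395 grid)
#' and rejects unknown keys by name.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return an object of class `pipeline_config`.
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- .merge_config(.config_defaults(), user)
  if (!is.numeric(cfg$n_iter) || cfg$n_iter < 1)
    stop("configuration key 'n_iter' must be >= 1")
  if (!cfg$scenario %in% scenario_registry())
    stop("configuration key 'scenario' must be one of: ",
         paste(scenario_registry(), collapse = ", "))
  cfg$n_iter <- as.integer(cfg$n_iter)
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf(
    "Pipeline config: n_iter = %d, seed = %d, scenario = '%s', out_dir = '%s'\n",
    x$n_iter, as.integer(x$master_seed), x$scenario, x$paths$out_dir))
  invisible(x)
}

.config_models <- function(cfg) {
  d <- cfg$dbh_model
  list(dbh = dbh_model(d$family, scale = d$scale, shape = d$shape,
                       rate = d$rate, d_min = d$d_min, d_max = d$d_max),
       height = do.call(height_model, cfg$height_model),
       agb = do.call(agb_model, cfg$agb_model),
       grid = grid_spec(cfg$grid$pixel_size,
                        c(cfg$grid$origin_x, cfg$grid$origin_y),
                        cfg$grid$crs))
}

.config_hash <- function(cfg) {
  .derive_seed(0, paste(deparse(unclass(cfg)), collapse = ""))
}

.provenance_write <- function(df, path, cfg, stage) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# forestAGB %s | seed %d | n_iter %d | config_hash %d",
                     stage, as.integer(cfg$master_seed), cfg$n_iter,
                     .config_hash(cfg)), con)
  utils::write.csv(df, con, row.names = FALSE)
  path
}

.provenance_read <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Run one pipeline stage
#'
#' Executes a stage of the simulate -> estimate -> aggregate / validate
#' pipeline against a [load_config()] configuration, reading and writing
#' delimited-text artifacts (and the five-layer GeoTIFF) under the configured
#' output directory. Every CSV artifact carries a commented provenance header
#' recording the stage, master seed, iteration count and a configuration
#' hash. Outputs are byte-identical under a fixed configuration and seed.
#'
#' \describe{
#'   \item{simulate}{generates the taxon pool and synthetic reference plots,
#'     degrades them per the configured scenario preset, and writes
#'     `taxa.csv`, `reference_trees.csv`/`reference_meta.csv` and
#'     `management.csv`/`management_meta.csv`.}
#'   \item{estimate}{reads the management inventories and writes per-plot
#'     Monte Carlo estimates to `estimates.csv` (fitting and applying the
#'     correction model when the scenario drops the 10-20 cm class).}
#'   \item{aggregate}{reads `estimates.csv` and writes `pixels.csv` plus the
#'     five-band `agb.tif`.}
#'   \item{validate}{runs the configured scenario preset against freshly
#'     generated reference plots and writes the per-source report
#'     `report.csv`.}
#' }
#'
#' @param stage one of `"simulate"`, `"estimate"`, `"aggregate"`,
#'   `"validate"`.
#' @param config a `pipeline_config` from [load_config()].
#' @return named character vector of artifact paths, invisibly.
#' @export
run_stage <- function(stage = c("simulate", "estimate", "aggregate",
                                "validate"),
                      config = load_config()) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "pipeline_config"))
  mods <- .config_models(config)
  dir.create(config$paths$out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(config$paths$out_dir, f)
  seed <- as.integer(config$master_seed)
  preset <- scenario_preset(config$scenario)
  switch(stage,
    simulate = {
      taxa <- generate_taxon_table(config$synthetic$n_taxa,
                                   seed = .derive_seed(seed, "taxa"))
      plots <- generate_plots(config$synthetic$n_plots,
                              area = config$synthetic$area,
                              stem_density = config$synthetic$stem_density,
                              model = mods$dbh, taxa = taxa, seed = seed)
      utils::write.csv(taxa, pth("taxa.csv"), row.names = FALSE)
      write_reference_csv(plots, pth("reference_trees.csv"),
                          pth("reference_meta.csv"))
      invs <- if (is.null(preset$scenario)) NULL else
        lapply(plots, function(p)
          degrade_plot(p, preset$scenario,
                       seed = .derive_seed(seed, paste0("degrade:", p$plot_id))))
      if (!is.null(invs))
        write_management_csv(invs, pth("management.csv"),
                             pth("management_meta.csv"))
      invisible(c(taxa = pth("taxa.csv"), trees = pth("reference_trees.csv"),
                  management = pth("management.csv")))
    },
    estimate = {
      taxa <- utils::read.csv(pth("taxa.csv"), stringsAsFactors = FALSE)
      invs <- if (file.exists(pth("management.csv")))
        read_management_csv(pth("management.csv"), pth("management_meta.csv"),
                            taxa)
      else read_reference_csv(pth("reference_trees.csv"),
                              pth("reference_meta.csv"))
      correction <- if (any(!vapply(invs, function(v)
        isTRUE(v$has_10_20) || inherits(v, "reference_plot"), logical(1)))) {
        calibrate_correction_model(n_plots = config$synthetic$n_calibration,
                                   model = mods$dbh, hmod = mods$height,
                                   amod = mods$agb,
                                   seed = .derive_seed(seed, "calibration"))
      } else NULL
      est <- batch_estimate(invs, dbh_mod = mods$dbh, hmod = mods$height,
                            amod = mods$agb, correction = correction,
                            toggles = preset$toggles, n_iter = config$n_iter,
                            seed = seed)
      .provenance_write(est, pth("estimates.csv"), config, "estimate")
      invisible(c(estimates = pth("estimates.csv")))
    },
    aggregate = {
      est <- .provenance_read(pth("estimates.csv"))
      px <- aggregate_pixels(est, mods$grid)
      .provenance_write(px, pth("pixels.csv"), config, "aggregate")
      write_agb_raster(px, mods$grid, pth("agb.tif"))
      invisible(c(pixels = pth("pixels.csv"), raster = pth("agb.tif")))
    },
    validate = {
      taxa <- generate_taxon_table(config$synthetic$n_taxa,
                                   seed = .derive_seed(seed, "taxa"))
      plots <- generate_plots(config$synthetic$n_plots,
                              area = config$synthetic$area,
                              stem_density = config$synthetic$stem_density,
                              model = mods$dbh, taxa = taxa, seed = seed)
      correction <- calibrate_correction_model(
        n_plots = config$synthetic$n_calibration, model = mods$dbh,
        hmod = mods$height, amod = mods$agb,
        seed = .derive_seed(seed, "calibration"))
      rep <- run_degradation_experiment(
        plots, preset$scenario, preset$toggles, correction = correction,
        dbh_mod = mods$dbh, hmod = mods$height, amod = mods$agb,
        n_iter = config$n_iter, seed = seed, name = preset$name)
      out <- data.frame(scenario = rep$name, mean_cv_pct = rep$mean_cv,
                        cv_lo = rep$cv_ci[1], cv_hi = rep$cv_ci[2],
                        ma_slope = rep$ma$slope,
                        ma_slope_lo = rep$ma$slope_ci[1],
                        ma_slope_hi = rep$ma$slope_ci[2])
      .provenance_write(out, pth("report.csv"), config, "validate")
      invisible(c(report = pth("report.csv")))
    })
}
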