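#' Reproduce the degrade-and-validate experiment suite
#'
#' Runs the full validation design on freshly generated synthetic reference
#' plots: reference AGB under classical errors, per-source degraded
#' re-estimation (diameter assignment with open class at 200 and 120 cm,
#' small-tree expansion under the light and heavy subsampling variants), the
#' combined best- and worst-case scenarios, the major-axis bias check of the
#' diameter-assignment function, and the average share of plot AGB held by
#' the 10-20 cm class. All quantities are recomputed from scratch; nothing is
#' cached between calls.
#'
#' @param seed master seed; every random stage derives a named substream.
#' @param n_plots number of synthetic reference plots (0.5 ha by default).
#' @param n_iter Monte Carlo iterations per plot.
#' @param n_share_plots plots used for the 10-20 cm AGB share.
#' @param n_calibration plots used to calibrate the correction model.
#' @param area,stem_density plot geometry passed to [generate_plots()].
#' @param dbh_mod,hmod,amod models as in [estimate_plot_agb()].
#' @param verbose print progress to stderr.
#' @return list with elements `classical_cv`, `dbh200_cv`, `dbh120_cv`,
#'   `nexp_light_cv`, `nexp_heavy_cv`, `best_cv`, `worst_cv` (mean plot CV,
#'   %), `ma_slope_dbh` (major-axis slope of diameter-assignment estimates
#'   vs reference AGB), `agb_share_10_20_pct` (mean 100 x AGB_10-20 /
#'   AGB_>=20), the per-scenario `reports` (class `scenario_report`), the
#'   `correction` model, and the run sizes `n_plots`, `n_iter`,
#'   `n_share_plots`.
#' @export
reproduce_validation <- function(seed = 1, n_plots = 200, n_iter = 1000,
                                 n_share_plots = 500, n_calibration = 1000,
                                 area = 0.5, stem_density = 500,
                                 dbh_mod = dbh_model(), hmod = height_model(),
                                 amod = agb_model(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  taxa <- generate_taxon_table(50, seed = .derive_seed(seed, "taxa"))
  plots <- generate_plots(n_plots, area = area, stem_density = stem_density,
                          model = dbh_mod, taxa = taxa,
                          seed = .derive_seed(seed, "plots"))
  say("reference AGB on %d plots (%d iterations)", n_plots, n_iter)
  ref <- batch_estimate(plots, dbh_mod = dbh_mod, hmod = hmod, amod = amod,
                        toggles = classical_errors(), n_iter = n_iter,
                        seed = .derive_seed(seed, "reference"))
  correction <- calibrate_correction_model(
    n_plots = n_calibration, area = area, stem_density = stem_density,
    model = dbh_mod, taxa = taxa, hmod = hmod, amod = amod,
    seed = .derive_seed(seed, "calibration"))
  run <- function(name, toggles = NULL, scenario = NULL) {
    ps <- scenario_preset(name)
    say("scenario %s", name)
    run_degradation_experiment(
      plots,
      scenario = if (is.null(scenario)) ps$scenario else scenario,
      toggles = if (is.null(toggles)) ps$toggles else toggles,
      correction = correction, dbh_mod = dbh_mod, hmod = hmod, amod = amod,
      n_iter = n_iter, seed = .derive_seed(seed, paste0("scenario:", name)),
      reference = ref, name = name)
  }
  reports <- list(
    dbh200 = run("dbh200"),
    dbh120 = run("dbh120"),
    nexp_light = run("nexp_light"),
    nexp_heavy = run("nexp_heavy"),
    best = run("best"),
    worst = run("worst"))
  # bias check of the diameter-assignment function: re-estimation carries the
  # classical sources plus the assignment error, against classical reference
  say("diameter-assignment bias check")
  ma_rep <- run_degradation_experiment(
    plots, scenario = scenario_preset("dbh200")$scenario,
    toggles = error_toggles(wd = TRUE, height = TRUE, agb = TRUE,
                            dbh_assign = TRUE),
    correction = correction, dbh_mod = dbh_mod, hmod = hmod, amod = amod,
    n_iter = n_iter, seed = .derive_seed(seed, "scenario:ma-dbh"),
    reference = ref, name = "dbh200+classical")
  reports$ma_dbh <- ma_rep
  # AGB share of the 10-20 cm class relative to AGB >= 20 cm, deterministic
  # allometry over an independent plot set
  say("10-20 cm AGB share on %d plots", n_share_plots)
  splots <- generate_plots(n_share_plots, area = area,
                           stem_density = stem_density, model = dbh_mod,
                           taxa = taxa, seed = .derive_seed(seed, "share"))
  share <- vapply(splots, function(p) {
    tr <- p$trees
    if (nrow(tr) == 0) return(NA_real_)
    a <- tree_agb(tr$wd_mean, tr$dbh, predict_height(tr$dbh, hmod), amod)
    100 * sum(a[tr$dbh < 20]) / sum(a[tr$dbh >= 20])
  }, numeric(1))
  list(classical_cv = mean(ref$cv_pct, na.rm = TRUE),
       dbh200_cv = reports$dbh200$mean_cv,
       dbh120_cv = reports$dbh120$mean_cv,
       nexp_light_cv = reports$nexp_light$mean_cv,
       nexp_heavy_cv = reports$nexp_heavy$mean_cv,
       best_cv = reports$best$mean_cv,
       worst_cv = reports$worst$mean_cv,
       ma_slope_dbh = ma_rep$ma$slope,
       agb_share_10_20_pct = mean(share, na.rm = TRUE),
       reports = reports, correction = correction,
       reference = ref,
       n_plots = n_plots, n_iter = n_iter, n_share_plots = n_share_plots)
}
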