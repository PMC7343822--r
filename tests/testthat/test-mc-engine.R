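test_that("with all error sources off the estimate is exactly deterministic", {
  p <- generate_plot(taxa = fixture_taxa, seed = 1)
  est <- estimate_plot_agb(p, n_iter = 50, seed = 2)
  expect_identical(est$variance, 0)
  expect_equal(est$mean_agb, deterministic_plot_agb(p))
  expect_equal(est$mean_agb, est$agb_ge20_mean + est$agb_10_20_mean)
  # management dialect, fully sampled, all sources off: also deterministic
  inv <- degrade_plot(p, degradation_scenario(open_class = 200), seed = 3)
  est2 <- estimate_plot_agb(inv, n_iter = 50, seed = 4)
  expect_identical(est2$variance, 0)
  expect_false(est2$corrected)
  expect_equal(est2$dbh_floor, 10)
})

test_that("empty inventories yield a flagged zero estimate", {
  p0 <- generate_plot(stem_density = 0, taxa = fixture_taxa, seed = 5)
  est <- estimate_plot_agb(p0, n_iter = 10, seed = 6)
  expect_true(est$empty)
  expect_equal(est$mean_agb, 0)
  expect_equal(est$variance, 0)
  expect_true(is.na(est$cv_pct))
})

test_that("single-tree wood density CV matches a brute-force oracle", {
  p <- generate_plot(stem_density = 0, taxa = fixture_taxa, seed = 7)
  p$trees <- data.frame(dbh = 40, taxon_id = "t0001", wd_mean = 0.6,
                        wd_sd = 0.1, x = 10, y = 10)
  n_iter <- 1e4
  est <- estimate_plot_agb(p, toggles = error_toggles(wd = TRUE),
                           n_iter = n_iter, seed = 8)
  # oracle: push truncated-normal wood density draws through the AGB formula
  # outside the engine
  set.seed(9)
  z <- rnorm(1e6, 0.6, 0.1)
  z <- z[z >= 0.08 & z <= 1.39]
  a <- tree_agb(z, 40, predict_height(40))
  cv_oracle <- 100 * sd(a) / mean(a)
  expect_equal(est$cv_pct, cv_oracle,
               tolerance = 4 / sqrt(2 * n_iter))  # relative, ~3 MC SE of a CV
  # CV identity
  expect_equal(est$cv_pct, 100 * sqrt(est$variance) / est$mean_agb)
})

test_that("adding an error source never decreases the mean plot CV", {
  plots <- generate_plots(25, taxa = fixture_taxa, seed = 10)
  sc <- degradation_scenario(open_class = 120,
                             sampling_fractions = c("10" = 0.25))
  invs <- lapply(seq_along(plots), function(i)
    degrade_plot(plots[[i]], sc, seed = 100 + i))
  ladder <- list(
    error_toggles(dbh_assign = TRUE),
    error_toggles(dbh_assign = TRUE, wd = TRUE),
    error_toggles(dbh_assign = TRUE, wd = TRUE, height = TRUE),
    error_toggles(dbh_assign = TRUE, wd = TRUE, height = TRUE, agb = TRUE),
    error_toggles(dbh_assign = TRUE, wd = TRUE, height = TRUE, agb = TRUE,
                  n_exp = TRUE))
  cvs <- vapply(ladder, function(tg) {
    est <- batch_estimate(invs, toggles = tg, n_iter = 300, seed = 11)
    mean(est$cv_pct)
  }, numeric(1))
  expect_true(all(diff(cvs) > 0))
})

test_that("Monte Carlo means are stable in the iteration count", {
  p <- generate_plot(taxa = fixture_taxa, seed = 12)
  e1 <- estimate_plot_agb(p, toggles = classical_errors(), n_iter = 500,
                          seed = 13)
  e2 <- estimate_plot_agb(p, toggles = classical_errors(), n_iter = 2000,
                          seed = 14)
  se <- sqrt(e1$variance / 500 + e2$variance / 2000)
  expect_equal(e1$mean_agb, e2$mean_agb, tolerance = 3 * se / e1$mean_agb)
})

test_that("batch estimation is deterministic and order-independent", {
  plots <- generate_plots(6, taxa = fixture_taxa, seed = 15)
  a <- batch_estimate(plots, toggles = classical_errors(), n_iter = 60,
                      seed = 16)
  b <- batch_estimate(rev(plots), toggles = classical_errors(), n_iter = 60,
                      seed = 16)
  b <- b[match(a$plot_id, b$plot_id), ]
  rownames(b) <- NULL
  expect_equal(a, b)
  expect_identical(nrow(batch_estimate(list(), n_iter = 10, seed = 1)), 0L)
})

test_that("failures on single plots are isolated, not fatal", {
  p <- generate_plot(taxa = fixture_taxa, seed = 17)
  bad <- degrade_plot(p, degradation_scenario(drop_10_20 = TRUE), seed = 18)
  # bad needs a correction model that is not supplied
  out <- batch_estimate(list(p, bad), toggles = classical_errors(),
                        n_iter = 30, seed = 19)
  expect_identical(nrow(out), 1L)
  expect_match(attr(out, "errors")[[1]], "correction")
})

test_that("the corrected estimate adds the 10-20 cm prediction per iteration", {
  p <- generate_plot(taxa = fixture_taxa, seed = 20)
  cor <- calibrate_correction_model(n_plots = 120, taxa = fixture_taxa,
                                    seed = 21)
  inv <- degrade_plot(p, degradation_scenario(drop_10_20 = TRUE), seed = 22)
  est <- estimate_plot_agb(inv, correction = cor, n_iter = 100, seed = 23)
  expect_true(est$corrected)
  expect_equal(est$dbh_floor, 20)
  expect_equal(est$mean_agb, est$agb_ge20_mean + est$agb_10_20_mean)
  expect_gt(est$agb_10_20_mean, 0)
  # correction residual adds variance
  est2 <- estimate_plot_agb(inv, correction = cor,
                            toggles = error_toggles(agb_cor = TRUE),
                            n_iter = 100, seed = 24)
  expect_gt(est2$variance, est$variance)
  # without a correction model the corrected path refuses to run
  expect_error(estimate_plot_agb(inv, n_iter = 10, seed = 25), "correction")
})
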