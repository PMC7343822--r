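test_that("taxon table normalizes abundances and honours its bounds", {
  one <- generate_taxon_table(1, seed = 1)
  expect_equal(one$rel_abundance, 1)
  tab <- generate_taxon_table(200, seed = 2)
  expect_equal(sum(tab$rel_abundance), 1, tolerance = 1e-12)
  expect_true(all(diff(tab$rel_abundance) < 0))  # geometric decay
  expect_true(all(tab$wd_mean >= 0.2 & tab$wd_mean <= 1.0))
  expect_true(all(tab$wd_sd >= 0))
  # determinism under seed
  expect_identical(generate_taxon_table(50, seed = 7),
                   generate_taxon_table(50, seed = 7))
  expect_error(generate_taxon_table(0), ">= 1")
})

test_that("taxon wood density means match a rejection-sampling oracle", {
  n <- 1e4
  tab <- generate_taxon_table(n, seed = 3)
  set.seed(4)
  z <- rnorm(1e6, 0.62, 0.12)
  z <- z[z >= 0.2 & z <= 1.0]
  expect_equal(mean(tab$wd_mean), mean(z),
               tolerance = 3 * sd(z) / sqrt(n) / mean(z))
})

test_that("plot generator reproduces the truncated-Weibull class shares", {
  expect_identical(nrow(generate_plot(stem_density = 0, seed = 1)$trees), 0L)
  big <- generate_plot(area = 100, stem_density = 1000,
                       taxa = fixture_taxa, seed = 5)
  n <- nrow(big$trees)
  expect_equal(n, 1e5, tolerance = 0.02)
  # closed-form truncated CDF probability of the 10-20 cm class
  m <- dbh_model()
  p_class <- pdbh_trunc(20, m) - pdbh_trunc(10, m)
  frac <- mean(big$trees$dbh < 20)
  expect_equal(frac, p_class,
               tolerance = 3 * sqrt(p_class * (1 - p_class) / n) / p_class)
  expect_true(all(big$trees$dbh >= 10 & big$trees$dbh <= 400))
  # deterministic under seed
  expect_identical(generate_plot(seed = 6)$trees, generate_plot(seed = 6)$trees)
})

test_that("degradation with full sampling is lossless binning", {
  p <- generate_plot(area = 1, stem_density = 400, taxa = fixture_taxa,
                     seed = 8)
  p$trees <- p$trees[p$trees$dbh < 200, , drop = FALSE]  # keep all below open
  inv <- degrade_plot(p, degradation_scenario(open_class = 200), seed = 1)
  got <- tapply(inv$classes$count, inv$classes$class_lo, sum)
  want <- table(floor(p$trees$dbh / 10) * 10)
  expect_equal(as.vector(got), as.vector(want))
  expect_identical(names(got), names(want))
  expect_true(all(inv$classes$p == 1))
  # taxon composition preserved within a class
  cl0 <- floor(p$trees$dbh / 10) * 10
  comp_ref <- table(p$trees$taxon_id[cl0 == 20])
  sub <- inv$classes[inv$classes$class_lo == 20, ]
  expect_equal(sub$count[match(names(comp_ref), sub$taxon_id)],
               as.vector(comp_ref))
})

test_that("binomial thinning retains n * p trees on average", {
  p <- generate_plot(area = 0.5, stem_density = 400, taxa = fixture_taxa,
                     seed = 9)
  n_class <- sum(floor(p$trees$dbh / 10) * 10 == 10)
  sc <- degradation_scenario(sampling_fractions = c("10" = 0.3))
  kept <- vapply(1:3000, function(s) {
    inv <- degrade_plot(p, sc, seed = s)
    sum(inv$classes$count[inv$classes$class_lo == 10])
  }, numeric(1))
  se <- sqrt(n_class * 0.3 * 0.7)
  expect_equal(mean(kept), n_class * 0.3, tolerance = 3 * se / sqrt(3000) /
                 (n_class * 0.3))
  # recorded fractions mirror the scenario (heaviest subsampling preset)
  heavy <- scenario_preset("nexp_heavy")$scenario
  inv <- degrade_plot(p, heavy, seed = 1)
  expect_equal(unique(inv$classes$p[inv$classes$class_lo == 10]), 0.125)
  expect_equal(unique(inv$classes$p[inv$classes$class_lo == 20]), 0.125)
  expect_equal(unique(inv$classes$p[inv$classes$class_lo == 30]), 0.25)
  expect_true(all(inv$classes$p[inv$classes$class_lo >= 40] == 1))
})

test_that("scenario constructor enforces its invariants", {
  expect_error(degradation_scenario(open_class = 115), "120")
  expect_error(degradation_scenario(sampling_fractions = c("10" = 0)),
               "\\(0, 1\\]")
  expect_error(degradation_scenario(sampling_fractions = c(0.5)), "named")
  sc <- degradation_scenario(drop_10_20 = TRUE)
  expect_equal(sc$census_threshold, 20)
})

test_that("plot splitting conserves area and partitions the tree list", {
  p <- generate_plot(area = 1, stem_density = 10000, taxa = fixture_taxa,
                     seed = 10)
  halves <- split_plot(p)
  expect_equal(halves[[1]]$area + halves[[2]]$area, 1)
  expect_equal(sort(c(halves[[1]]$trees$dbh, halves[[2]]$trees$dbh)),
               sort(p$trees$dbh))
  # uniform positions: each half holds ~half the stems
  n <- nrow(p$trees)
  expect_equal(nrow(halves[[1]]$trees), n / 2,
               tolerance = 3 * sqrt(n * 0.25) / (n / 2))
  # quadrat snapping shifts the areas away from exact halves
  q <- split_plot(p, quadrat = 48)
  expect_equal(q[[1]]$area + q[[2]]$area, 1)
  expect_equal(q[[1]]$area, 0.48)
  expect_error(split_plot(p, n_parts = 3), "2 parts")
})

test_that("inventory CSV round trips preserve both dialects", {
  plots <- generate_plots(3, area = 0.5, stem_density = 100,
                          taxa = fixture_taxa, seed = 11)
  td <- tempfile("io"); dir.create(td); on.exit(unlink(td, recursive = TRUE))
  write_reference_csv(plots, file.path(td, "t.csv"), file.path(td, "m.csv"))
  back <- read_reference_csv(file.path(td, "t.csv"), file.path(td, "m.csv"))
  expect_equal(length(back), 3)
  expect_equal(back[[2]]$trees$dbh, plots[[2]]$trees$dbh)
  expect_equal(back[[2]]$area, plots[[2]]$area)
  invs <- lapply(plots, degrade_plot,
                 scenario = scenario_preset("best")$scenario, seed = 12)
  write_management_csv(invs, file.path(td, "inv.csv"), file.path(td, "im.csv"))
  taxa_tab <- fixture_taxa
  back2 <- read_management_csv(file.path(td, "inv.csv"),
                               file.path(td, "im.csv"), taxa_tab)
  expect_equal(back2[[1]]$classes$count, invs[[1]]$classes$count)
  expect_equal(back2[[1]]$classes$class_hi, invs[[1]]$classes$class_hi)
  expect_equal(back2[[1]]$classes$wd_mean, invs[[1]]$classes$wd_mean)
  expect_true(back2[[1]]$has_10_20)
})
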