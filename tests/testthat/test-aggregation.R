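test_that("pixel assignment uses half-open floor indexing", {
  g <- grid_spec(pixel_size = 1000, origin = c(0, 0))
  df <- data.frame(x = c(0, 999.9, 1000, 2500, -1),
                   y = c(0, 0, 0, 1500, -1))
  out <- assign_to_pixels(df, g)
  expect_equal(out$ix, c(0L, 0L, 1L, 2L, -1L))
  expect_equal(out$iy, c(0L, 0L, 0L, 1L, -1L))
  # two plots 1 m apart straddling a boundary land in different pixels
  s <- assign_to_pixels(data.frame(x = c(999.5, 1000.5), y = c(5, 5)), g)
  expect_false(s$ix[1] == s$ix[2])
  # non-finite coordinates are skipped with a warning
  expect_warning(
    bad <- assign_to_pixels(data.frame(x = c(1, NA), y = c(1, 2)), g),
    "skipped")
  expect_identical(nrow(bad), 1L)
})

test_that("pixel occupancy matches an independent histogram oracle", {
  set.seed(1)
  g <- grid_spec(pixel_size = 1, origin = c(0, 0))
  df <- data.frame(x = runif(1000, 0, 10), y = runif(1000, 0, 10),
                   mean_agb = 1, variance = 0, area = 1, date = 2000)
  px <- aggregate_pixels(df, g)
  oracle <- table(paste(floor(df$x), floor(df$y)))
  got <- setNames(px$n_plots, paste(px$ix, px$iy))
  expect_equal(sum(px$n_plots), 1000)
  expect_equal(as.vector(got[names(oracle)]), as.vector(oracle))
})

test_that("pixel aggregation matches direct weighted formulas", {
  # single plot: mean passes through, inter-plot variance is zero
  one <- aggregate_pixel(mean_agb = 321, variance = 900, area = 0.5,
                         date = 2004)
  expect_equal(one$mean_agb, 321)
  expect_equal(one$inter_var, 0)
  expect_equal(one$intra_var, 900)
  expect_equal(one$total_cv_pct, 100 * sqrt(900) / 321)
  # identical plots: no sampling spread
  same <- aggregate_pixel(rep(200, 4), rep(400, 4), rep(0.5, 4), rep(2005, 4))
  expect_equal(same$inter_var, 0)
  expect_equal(same$intra_var, 400)
  # five unequal-area plots against hand-coded sums
  m <- c(310, 450, 280, 520, 390)
  v <- c(900, 1600, 700, 2500, 1200)
  w <- c(0.3, 0.5, 0.5, 0.4, 1.0)
  dt <- c(2001, 2003, 2004, 2008, 2010)
  px <- aggregate_pixel(m, v, w, dt)
  mbar <- sum(w * m) / sum(w)
  expect_equal(px$mean_agb, mbar)
  expect_equal(px$intra_var, sum(w * v) / sum(w))
  expect_equal(px$inter_var,
               sum(w * (m - mbar)^2) * sum(w) / (sum(w)^2 - sum(w^2)))
  expect_equal(px$mean_date, sum(w * dt) / sum(w))
  expect_equal(px$total_cv_pct,
               100 * sqrt(px$inter_var + px$intra_var) / px$mean_agb)
  expect_equal(px$n_plots, 5)
  expect_error(aggregate_pixel(numeric(0), numeric(0), numeric(0),
                               numeric(0)), "at least one")
})

test_that("intra + inter variance matches a pooled Monte Carlo draw", {
  # equal-area plots: the population-form decomposition equals the variance
  # of drawing one plot uniformly, then one of its Monte Carlo iterations
  plots <- generate_plots(5, taxa = fixture_taxa, seed = 2)
  ests <- lapply(seq_along(plots), function(i)
    estimate_plot_agb(plots[[i]], toggles = classical_errors(), n_iter = 400,
                      seed = 30 + i, keep_draws = TRUE))
  m <- vapply(ests, `[[`, numeric(1), "mean_agb")
  v <- vapply(ests, `[[`, numeric(1), "variance")
  px <- aggregate_pixel(m, v, rep(0.5, 5), rep(2005, 5), unbiased = FALSE)
  set.seed(3)
  pooled <- replicate(1000, {
    j <- sample.int(5, 1)
    sample(ests[[j]]$draws, 1)
  })
  want <- px$intra_var + px$inter_var
  x2 <- (pooled - mean(pooled))^2
  se <- sd(x2) / sqrt(length(pooled))
  expect_equal(var(pooled) * (999 / 1000), want,
               tolerance = 3 * se / want)
})

test_that("sampling uncertainty shrinks roughly as 1/sqrt(n)", {
  # equal plots per pixel, n in {3, 6, 10}: the CI half-width on the pixel
  # mean scales as sd/sqrt(n); check the log-log slope is near -0.5
  set.seed(4)
  ns <- c(3, 6, 10)
  ci <- vapply(ns, function(n) {
    widths <- replicate(300, {
      m <- rnorm(n, 400, 60)
      px <- aggregate_pixel(m, rep(0, n), rep(0.5, n), rep(2005, n))
      sqrt(px$inter_var / n)  # CI half-width ~ se of the pixel mean
    })
    mean(widths)
  }, numeric(1))
  slope <- coef(lm(log(ci) ~ log(ns)))[2]
  expect_lt(slope, -0.35)
  expect_gt(slope, -0.65)
  expect_true(all(diff(ci) < 0))
})

test_that("the five-layer GeoTIFF round trip is bit-exact", {
  plots <- generate_plots(15, taxa = fixture_taxa, seed = 5,
                          extent = c(0, 4000, 0, 3000))
  est <- batch_estimate(plots, toggles = classical_errors(), n_iter = 40,
                        seed = 6)
  g <- grid_spec()
  px <- aggregate_pixels(est, g)
  tf <- tempfile(fileext = ".tif")
  on.exit(unlink(tf))
  write_agb_raster(px, g, tf)
  r <- read_agb_raster(tf)
  expect_identical(length(r$bands), 5L)
  expect_identical(names(r$bands),
                   c("mean_agb", "n_plots", "mean_date", "inter_var",
                     "intra_var"))
  expect_identical(r$epsg, 3395L)
  expect_identical(r$nodata, -9999)
  expect_identical(r$pixel_size, 1000)
  # occupied cells: every band value identical to the pixel table
  for (nm in names(r$bands)) {
    b <- r$bands[[nm]]
    rrow <- (max(px$iy) - px$iy) + 1L
    ccol <- px$ix - min(px$ix) + 1L
    expect_identical(unname(b[cbind(rrow, ccol)]), as.numeric(px[[nm]]))
  }
  # empty pixels carry nodata in all five bands
  occupied <- matrix(FALSE, r$height, r$width)
  occupied[cbind((max(px$iy) - px$iy) + 1L, px$ix - min(px$ix) + 1L)] <- TRUE
  for (nm in names(r$bands))
    expect_true(all(r$bands[[nm]][!occupied] == -9999))
  # conservation: total plot count is preserved
  expect_equal(sum(px$n_plots), nrow(est))
})

test_that("a single-plot pixel maps to the documented band order", {
  est <- data.frame(mean_agb = 250, variance = 500, area = 0.5, date = 2007,
                    x = 100, y = 100)
  g <- grid_spec()
  px <- aggregate_pixels(est, g)
  tf <- tempfile(fileext = ".tif")
  on.exit(unlink(tf))
  write_agb_raster(px, g, tf)
  r <- read_agb_raster(tf)
  expect_equal(r$bands$mean_agb[1, 1], 250)   # band 1: mean AGB
  expect_equal(r$bands$n_plots[1, 1], 1)      # band 2: plot count
  expect_equal(r$bands$mean_date[1, 1], 2007) # band 3: mean date
  expect_equal(r$bands$inter_var[1, 1], 0)    # band 4: inter-plot variance
  expect_equal(r$bands$intra_var[1, 1], 500)  # band 5: intra-plot variance
})

test_that("an independent TIFF reader agrees with the written raster", {
  px <- data.frame(ix = c(0, 1, 1), iy = c(0, 0, 1),
                   mean_agb = c(123.25, 456.5, 789.75), n_plots = c(1, 2, 3),
                   mean_date = c(2001, 2002, 2003), inter_var = c(0, 1, 2),
                   intra_var = c(3, 4, 5), total_cv_pct = c(1, 1, 1))
  tf <- tempfile(fileext = ".tif")
  on.exit(unlink(tf))
  write_agb_raster(px, grid_spec(), tf)
  script <- paste(
    "import tifffile, json, sys",
    "a = tifffile.imread(sys.argv[1])",
    "print(json.dumps({'shape': list(a.shape),",
    "                  'vals': a.reshape(-1).tolist()}))", sep = "\n")
  out <- system2("python", c("-c", shQuote(script), shQuote(tf)),
                 stdout = TRUE)
  parsed <- jsonlite::fromJSON(paste(out, collapse = ""))
  expect_equal(parsed$shape, c(5, 2, 2))
  r <- read_agb_raster(tf)
  ours <- as.vector(sapply(r$bands, function(b) as.vector(t(b))))
  expect_equal(parsed$vals, ours)
})
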