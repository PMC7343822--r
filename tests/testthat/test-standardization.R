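test_that("negative-binomial expansion honours its boundary cases and mean", {
  expect_identical(expand_small_trees(7, 1), 7L)
  expect_identical(expand_small_trees(0, 0.3), 0L)
  set.seed(1)
  tot <- expand_small_trees(rep(10, 1e5), 0.5)
  # E[r + X] = r / p; Var(X) = r (1 - p) / p^2
  se <- sqrt(10 * 0.5 / 0.5^2 / 1e5)
  expect_equal(mean(tot), 20, tolerance = 3 * se / 20)
  expect_error(expand_small_trees(5, 0), "\\(0, 1\\]")
  expect_error(expand_small_trees(5, 1.2), "\\(0, 1\\]")
  expect_error(expand_small_trees(-1, 0.5), ">= 0")
})

test_that("expansion is unbiased for the pre-thinning count", {
  # paired with binomial thinning at the same p: E[expanded | thinned] = n
  set.seed(2)
  n_true <- 40; p <- 0.25
  reps <- 1e4
  r <- rbinom(reps, n_true, p)
  tot <- expand_small_trees(r, p)
  expect_equal(mean(tot), n_true, tolerance = 3 * sd(tot) / sqrt(reps) / n_true)
})

test_that("pro-rata taxon assignment matches the multinomial oracle", {
  expect_identical(assign_species_pro_rata(0, c(A = 3)), character(0))
  expect_true(all(assign_species_pro_rata(50, c(A = 3)) == "A"))
  set.seed(3)
  lab <- assign_species_pro_rata(1e5, c(A = 3, B = 1))
  expect_equal(mean(lab == "A"), 0.75,
               tolerance = 3 * sqrt(0.75 * 0.25 / 1e5) / 0.75)
  expect_error(assign_species_pro_rata(5, numeric(0)), "non-empty")
})

test_that("shape metrics reproduce exact algebra on collinear classes", {
  # equal class AGB A: cumulated y = (A/10) x - 2A on x = 30..70
  A <- 7.3
  si <- compute_shape_metrics(setNames(rep(A, 5), seq(20, 60, 10)))
  expect_equal(si[["S"]], A / 10)
  expect_equal(si[["I"]], -2 * A)
  z <- compute_shape_metrics(setNames(rep(0, 5), seq(20, 60, 10)))
  expect_equal(unname(z), c(0, 0))
  # arbitrary input vs an independent normal-equations solve
  set.seed(4)
  v <- runif(5, 0, 20)
  si2 <- compute_shape_metrics(setNames(v, seq(20, 60, 10)))
  X <- cbind(1, seq(30, 70, 10))
  beta <- solve(t(X) %*% X, t(X) %*% cumsum(v))
  expect_equal(si2[["S"]], beta[2], tolerance = 1e-12)
  expect_equal(si2[["I"]], beta[1], tolerance = 1e-12)
  expect_error(compute_shape_metrics(c("20" = 1)), "named")
})

test_that("correction model recovers known coefficients from clean data", {
  set.seed(5)
  n <- 500
  dat <- data.frame(agb_ge20 = runif(n, 100, 600), S = runif(n, 0, 5),
                    I = runif(n, -100, 0))
  truth <- c(a = 12.5, b = 0.031, c = 4.2, d = -0.37)
  dat$agb_10_20 <- truth["a"] + truth["b"] * dat$agb_ge20 +
    truth["c"] * dat$S + truth["d"] * dat$I
  fit <- fit_correction_model(dat)
  expect_equal(unname(coef(fit)), unname(truth), tolerance = 1e-7)
  expect_lt(sigma(fit), 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
})

test_that("correction model recovers the residual sd under noise", {
  set.seed(6)
  n <- 1e4
  dat <- data.frame(agb_ge20 = runif(n, 100, 600), S = runif(n, 0, 5),
                    I = runif(n, -100, 0))
  dat$agb_10_20 <- 10 + 0.05 * dat$agb_ge20 + 3 * dat$S - 0.2 * dat$I +
    rnorm(n, 0, 4.5)
  fit <- fit_correction_model(dat)
  expect_equal(sigma(fit), 4.5, tolerance = 0.03)
  # unbiased predictor: mean residual of the fitted family is ~0
  pred <- predict(fit, dat$agb_ge20, dat$S, dat$I)
  expect_equal(mean(dat$agb_10_20 - pred), 0,
               tolerance = 3 * 4.5 / sqrt(n))
})

test_that("correction prediction floors at zero and draws its residual", {
  fit <- structure(list(a = 50, b = 0, c = 0, d = 0, sigma = 2, r2 = 0.5,
                        n = 100), class = "agb_correction")
  expect_equal(predict(fit, 300, 1, -10), 50)
  set.seed(7)
  draws <- predict(fit, rep(300, 1e5), 1, -10, with_error = TRUE)
  expect_equal(sd(draws), 2, tolerance = 3 / sqrt(2 * 1e5))
  neg <- structure(list(a = -500, b = 0, c = 0, d = 0, sigma = 0, r2 = 0,
                        n = 100), class = "agb_correction")
  expect_equal(predict(neg, 300, 1, -10), 0)
})

test_that("degenerate calibration designs are rejected", {
  dat <- data.frame(agb_10_20 = 1:20, agb_ge20 = 1:20, S = 2 * (1:20),
                    I = 1:20)  # S collinear with agb_ge20
  expect_error(fit_correction_model(dat), "rank-deficient")
  expect_error(fit_correction_model(dat[1:5, ]), "10 calibration")
})

test_that("synthetic calibration produces a usable correction model", {
  fit <- calibrate_correction_model(n_plots = 150, taxa = fixture_taxa,
                                    seed = 8)
  expect_s3_class(fit, "agb_correction")
  expect_gt(fit$sigma, 0)
  expect_true(is.finite(fit$r2))
  # prediction at typical synthetic stand structure is positive
  expect_gt(predict(fit, 450, 3, -60), 0)
})
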