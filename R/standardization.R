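#' Expand a partially sampled diameter-class count
#'
#' A diameter class sampled on a spatial fraction `p` of the plot records `r`
#' trees. The number of unrecorded trees `X` is simulated from a negative
#' binomial distribution, `X ~ NegBin(r, p)`, parameterized as the number of
#' failures before the r-th success with success probability `p`
#' (`E[X] = r (1 - p) / p`, so the expanded total `r + X` has expectation
#' `r / p`, the Horvitz-Thompson expansion). This is the exact Bayesian
#' inverse of binomial thinning with retention probability `p` under an
#' improper uniform prior on the true count. `r = 0` or `p = 1` return `r`
#' unchanged.
#'
#' @param r observed counts (vectorized, >= 0).
#' @param p sampling fractions in (0, 1\] (recycled).
#' @return integer vector of expanded totals `r + X`.
#' @examples
#' set.seed(1)
#' mean(expand_small_trees(rep(10, 1000), 0.5)) # ~ 20
#' @export
expand_small_trees <- function(r, p) {
  if (any(p <= 0 | p > 1)) stop("sampling fractions must lie in (0, 1]")
  if (any(r < 0)) stop("observed counts must be >= 0")
  n <- max(length(r), length(p))
  r <- rep_len(r, n); p <- rep_len(p, n)
  x <- integer(n)
  draw <- r > 0 & p < 1
  if (any(draw)) x[draw] <- stats::rnbinom(sum(draw), size = r[draw], prob = p[draw])
  as.integer(r + x)
}

#' Assign taxa to simulated trees pro rata of observed abundance
#'
#' Trees simulated by [expand_small_trees()] receive taxon labels drawn
#' multinomially with probabilities proportional to the taxon counts observed
#' in the sampled fraction of the class.
#'
#' @param n_new number of simulated trees (>= 0).
#' @param composition named numeric vector of observed counts per taxon.
#' @return character vector of `n_new` taxon labels.
#' @export
assign_species_pro_rata <- function(n_new, composition) {
  if (n_new < 0) stop("n_new must be >= 0")
  if (n_new == 0) return(character(0))
  if (length(composition) == 0 || sum(composition) <= 0)
    stop("n_new > 0 requires a non-empty observed composition")
  if (is.null(names(composition))) stop("composition must be named by taxon")
  names(composition)[sample.int(length(composition), n_new, replace = TRUE,
                                prob = composition)]
}

#' Shape metrics of the cumulated biomass distribution
#'
#' Computes the slope `S` and intercept `I` of an ordinary least squares fit
#' to a plot's cumulated AGB across 10-cm diameter classes from 20 cm up to
#' 70 cm: the response at class upper bound `x` in \{30, 40, 50, 60, 70\} cm
#' is the total AGB of trees with 20 <= DBH < x. These two stand-structure
#' metrics summarize how biomass accumulates with tree size and are the
#' covariates of the 10-20 cm AGB correction model.
#'
#' @param class_agb named numeric vector of per-class AGB (Mg/ha) for the five
#'   classes with lower bounds 20, 30, 40, 50, 60 (names `"20"` ... `"60"`;
#'   zero values allowed).
#' @return named numeric vector `c(S = slope, I = intercept)`, in
#'   Mg/ha/cm and Mg/ha.
#' @examples
#' compute_shape_metrics(c("20" = 5, "30" = 5, "40" = 5, "50" = 5, "60" = 5))
#' @export
compute_shape_metrics <- function(class_agb) {
  need <- as.character(seq(20, 60, by = 10))
  if (!all(need %in% names(class_agb)))
    stop("class_agb must contain entries named ", paste(need, collapse = ", "))
  y <- cumsum(as.numeric(class_agb[need]))
  x <- seq(30, 70, by = 10)
  s <- sum((x - mean(x)) * y) / sum((x - mean(x))^2)
  c(S = s, I = mean(y) - s * mean(x))
}

#' Fit the 10-20 cm AGB correction model
#'
#' Management inventories with a 20-cm census threshold carry no information
#' on trees in the 10-20 cm DBH class. Their AGB contribution is predicted by
#' the linear model
#' `AGB_10-20 = a + b AGB_>=20 + c S + d I + eps`, `eps ~ N(0, sigma^2)`,
#' fitted by ordinary least squares on calibration plots where the class was
#' (at least partially) sampled. `S` and `I` are the [compute_shape_metrics()]
#' of the calibration plots.
#'
#' @param calibration data frame with columns `agb_10_20`, `agb_ge20`, `S`,
#'   `I` (all Mg/ha except `S`, Mg/ha/cm), one row per calibration plot
#'   (>= 10 rows).
#' @return an object of class `agb_correction` wrapping the `lm` fit, with
#'   coefficients `a`, `b`, `c`, `d`, residual standard error `sigma` and
#'   calibration `r2`.
#' @seealso [calibrate_correction_model()] to build a synthetic calibration
#'   set, [predict.agb_correction()].
#' @export
fit_correction_model <- function(calibration) {
  stopifnot(is.data.frame(calibration),
            all(c("agb_10_20", "agb_ge20", "S", "I") %in% names(calibration)))
  if (nrow(calibration) < 10)
    stop("at least 10 calibration plots are required")
  fit <- stats::lm(agb_10_20 ~ agb_ge20 + S + I, data = calibration)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient calibration design: coefficients not identifiable")
  sm <- suppressWarnings(summary(fit))  # noise-free calibration is legitimate
  cf <- unname(stats::coef(fit))
  structure(list(a = cf[1], b = cf[2], c = cf[3], d = cf[4],
                 sigma = sm$sigma, r2 = sm$r.squared,
                 n = nrow(calibration), fit = fit),
            class = "agb_correction")
}

#' @export
print.agb_correction <- function(x, ...) {
  cat("AGB correction model for the 10-20 cm class\n")
  cat(sprintf(
    "  AGB_10-20 = %.4g + %.4g AGB_>=20 + %.4g S + %.4g I   (Mg/ha)\n",
    x$a, x$b, x$c, x$d))
  cat(sprintf("  residual sd = %.4g Mg/ha, R2 = %.3f, n = %d plots\n",
              x$sigma, x$r2, x$n))
  invisible(x)
}

#' @export
coef.agb_correction <- function(object, ...) {
  c(a = object$a, b = object$b, c = object$c, d = object$d)
}

#' @export
sigma.agb_correction <- function(object, ...) object$sigma

#' Predict the AGB of the 10-20 cm class
#'
#' Evaluates the fitted correction model, optionally adding a draw of the
#' normal residual term (one draw per prediction); predictions are floored at
#' zero.
#'
#' @param object an [fit_correction_model()] result.
#' @param agb_ge20 plot AGB of trees >= 20 cm DBH, Mg/ha.
#' @param S,I shape metrics from [compute_shape_metrics()].
#' @param with_error add the `N(0, sigma^2)` residual draw.
#' @param ... unused.
#' @return predicted AGB of the 10-20 cm class, Mg/ha (>= 0).
#' @export
predict.agb_correction <- function(object, agb_ge20, S, I,
                                   with_error = FALSE, ...) {
  mu <- object$a + object$b * agb_ge20 + object$c * S + object$d * I
  if (with_error) mu <- mu + stats::rnorm(length(mu), 0, object$sigma)
  pmax(mu, 0)
}

# per-ha AGB of the 10-20 class, >= 20, and the 20..60 class sums of a tree set
.structure_summary <- function(dbh, agb, area) {
  k <- floor(dbh / 10)
  cls <- vapply(2:6, function(kk) sum(agb[k == kk]), numeric(1)) / area
  names(cls) <- as.character(seq(20, 60, by = 10))
  list(agb_10_20 = sum(agb[dbh < 20]) / area,
       agb_ge20 = sum(agb[dbh >= 20]) / area,
       class_agb = cls)
}

#' Build a synthetic calibration set and fit the correction model
#'
#' Generates reference plots with the synthetic forest generator, computes
#' per-plot `AGB_10-20`, `AGB_>=20` and the shape metrics `S`, `I` with
#' deterministic allometry, and fits the correction model on them. This is the
#' in-package analogue of calibrating the model on management plots where the
#' 10-20 cm class is partially sampled.
#'
#' @param n_plots number of calibration plots (>= 10).
#' @param seed master seed.
#' @inheritParams generate_plots
#' @param hmod a [height_model()].
#' @param amod an [agb_model()].
#' @return an `agb_correction` object.
#' @export
calibrate_correction_model <- function(n_plots = 1000, area = 0.5,
                                       stem_density = 500,
                                       model = dbh_model(),
                                       taxa = generate_taxon_table(50, seed = 1),
                                       hmod = height_model(),
                                       amod = agb_model(), seed = 1) {
  plots <- generate_plots(n_plots, area = area, stem_density = stem_density,
                          model = model, taxa = taxa, seed = seed)
  rows <- lapply(plots, function(p) {
    tr <- p$trees
    if (nrow(tr) == 0) return(NULL)
    agb <- tree_agb(tr$wd_mean, tr$dbh, predict_height(tr$dbh, hmod), amod)
    st <- .structure_summary(tr$dbh, agb, p$area)
    si <- compute_shape_metrics(st$class_agb)
    data.frame(agb_10_20 = st$agb_10_20, agb_ge20 = st$agb_ge20,
               S = si[["S"]], I = si[["I"]])
  })
  fit_correction_model(do.call(rbind, rows))
}
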