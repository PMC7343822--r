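#' Monte Carlo plot AGB estimation
#'
#' Estimates plot aboveground biomass and its uncertainty by Monte Carlo
#' simulation. Each iteration (i) expands partially sampled diameter-class
#' counts by negative-binomial simulation and assigns taxa pro rata
#' (management dialect), (ii) assigns a continuous diameter to every
#' class-recorded tree by inverse-transform sampling from the diameter
#' distribution model (measured diameters are used as-is in the scientific
#' dialect), (iii) draws wood-density, height-model and AGB-model errors per
#' the toggles, (iv) sums tree AGB and divides by plot area, and (v) when the
#' 10-20 cm class is absent, computes the shape metrics `S` and `I` on the
#' iteration's tree set and adds the correction-model prediction (with its
#' residual drawn when the `agb_cor` source is on). The plot estimate is the
#' mean of the iterations; the variance and the coefficient of variation
#' quantify estimation uncertainty.
#'
#' With an error source toggled off, the corresponding step becomes
#' deterministic: class-recorded trees take the class-conditional median
#' diameter, partially sampled counts are expanded to their expectation
#' `round(r / p)` with simulated trees receiving the count-weighted mean wood
#' density of their class, and the correction residual is omitted. With all
#' sources off the estimate has exactly zero Monte Carlo variance.
#'
#' @param inv a `reference_plot` (scientific dialect) or
#'   `management_inventory` (management dialect).
#' @param dbh_mod a [dbh_model()] used for diameter assignment.
#' @param hmod a [height_model()].
#' @param amod an [agb_model()].
#' @param correction an `agb_correction` model; required when the inventory
#'   lacks the 10-20 cm class.
#' @param toggles an [error_toggles()].
#' @param n_iter number of Monte Carlo iterations (>= 1; 1000 by default).
#' @param seed optional integer seed; estimates are deterministic under
#'   `(seed, n_iter)`.
#' @param keep_draws store the vector of per-iteration AGB values.
#' @return an object of class `plot_agb_estimate` with elements `plot_id`,
#'   `mean_agb` (Mg/ha), `variance` (Mg^2/ha^2), `cv_pct`, `n_iter`,
#'   `dbh_floor` (10 or 20, pre-correction), `corrected`, `agb_ge20_mean`,
#'   `agb_10_20_mean` (Mg/ha), `n_rejected` (non-finite iterations redrawn),
#'   `empty`, and plot coordinates/area/date.
#' @examples
#' p <- generate_plot(seed = 1)
#' est <- estimate_plot_agb(p, toggles = classical_errors(), n_iter = 100,
#'                          seed = 1)
#' est
#' @export
estimate_plot_agb <- function(inv, dbh_mod = dbh_model(),
                              hmod = height_model(), amod = agb_model(),
                              correction = NULL,
                              toggles = error_toggles(), n_iter = 1000,
                              seed = NULL, keep_draws = FALSE) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (inherits(inv, "reference_plot")) {
    res <- .mc_scientific(inv, hmod, amod, toggles, n_iter)
    dbh_floor <- 10; corrected <- FALSE
  } else if (inherits(inv, "management_inventory")) {
    if (!inv$has_10_20 && is.null(correction))
      stop("inventory lacks the 10-20 cm class: a correction model is required")
    res <- .mc_management(inv, dbh_mod, hmod, amod, correction, toggles, n_iter)
    dbh_floor <- if (inv$has_10_20) 10 else 20
    corrected <- !inv$has_10_20
  } else stop("unknown inventory dialect: expected reference_plot or management_inventory")
  tot <- res$tot
  v <- if (n_iter > 1) stats::var(tot) else 0
  m <- mean(tot)
  structure(list(plot_id = inv$plot_id, mean_agb = m, variance = v,
                 cv_pct = if (m > 0) 100 * sqrt(v) / m else NA_real_,
                 n_iter = n_iter, dbh_floor = dbh_floor,
                 corrected = corrected,
                 agb_ge20_mean = mean(res$ge20),
                 agb_10_20_mean = mean(res$a1020),
                 n_rejected = res$n_rejected,
                 empty = res$empty,
                 area = inv$area, x = inv$x, y = inv$y, date = inv$date,
                 draws = if (keep_draws) tot else NULL),
            class = "plot_agb_estimate")
}

#' @export
print.plot_agb_estimate <- function(x, ...) {
  cat(sprintf("Plot AGB estimate '%s' (%d Monte Carlo iterations)\n",
              x$plot_id, x$n_iter))
  cat(sprintf("  AGB = %.1f Mg/ha, variance = %.2f, CV = %s%%\n",
              x$mean_agb, x$variance,
              if (is.na(x$cv_pct)) "NA" else sprintf("%.2f", x$cv_pct)))
  cat(sprintf("  AGB >= 20 cm: %.1f Mg/ha, AGB 10-20 cm: %.1f Mg/ha%s\n",
              x$agb_ge20_mean, x$agb_10_20_mean,
              if (x$corrected) " (correction model)" else ""))
  if (x$empty) cat("  [empty inventory]\n")
  invisible(x)
}

#' @export
as.data.frame.plot_agb_estimate <- function(x, ...) {
  data.frame(plot_id = x$plot_id, mean_agb = x$mean_agb,
             variance = x$variance, cv_pct = x$cv_pct, n_iter = x$n_iter,
             dbh_floor = x$dbh_floor, corrected = x$corrected,
             agb_ge20_mean = x$agb_ge20_mean,
             agb_10_20_mean = x$agb_10_20_mean, area = x$area,
             x = x$x, y = x$y, date = x$date, empty = x$empty,
             stringsAsFactors = FALSE)
}

# one Monte Carlo pass over a prepared tree set; returns per-iteration totals
.mc_core <- function(n_iter, gen_trees, area, hmod, amod, toggles,
                     correction = NULL, corrected = FALSE, max_redraw = 100) {
  tot <- ge20 <- a1020 <- numeric(n_iter)
  n_rejected <- 0L
  shared_cv <- toggles$agb && amod$coef_rel_sd > 0
  for (it in seq_len(n_iter)) {
    for (attempt in seq_len(max_redraw)) {
      tl <- gen_trees()
      dbh <- tl$dbh; n <- length(dbh)
      wd <- if (toggles$wd && n > 0)
        .rtruncnorm(n, tl$wd_mean, tl$wd_sd, .WD_BOUNDS[1], .WD_BOUNDS[2])
      else tl$wd_mean
      h <- hmod$a * (1 - exp(-hmod$b * dbh^hmod$c))
      if (toggles$height && n > 0)
        h <- pmax(h + stats::rnorm(n, 0, hmod$sigma), 1.3)
      alpha <- amod$alpha; beta <- amod$beta
      if (shared_cv) {
        alpha <- alpha * (1 + stats::rnorm(1, 0, amod$coef_rel_sd))
        beta <- beta * (1 + stats::rnorm(1, 0, amod$coef_rel_sd))
      }
      agb <- alpha * (wd * dbh^2 * h)^beta / 1000
      if (toggles$agb && amod$sigma_ln > 0 && n > 0)
        agb <- agb * exp(stats::rnorm(n, -amod$sigma_ln^2 / 2, amod$sigma_ln))
      g20 <- sum(agb[dbh >= 20]) / area
      a12 <- sum(agb[dbh < 20]) / area
      if (corrected) {
        k <- floor(dbh / 10)
        cls <- vapply(2:6, function(kk) sum(agb[k == kk]), numeric(1)) / area
        names(cls) <- as.character(seq(20, 60, by = 10))
        si <- compute_shape_metrics(cls)
        a12 <- predict(correction, g20, si[["S"]], si[["I"]],
                       with_error = toggles$agb_cor)
      }
      t_i <- g20 + a12
      if (is.finite(t_i)) break
      n_rejected <- n_rejected + 1L
    }
    if (!is.finite(t_i))
      stop("Monte Carlo iteration produced non-finite AGB after ", max_redraw,
           " redraws")
    tot[it] <- t_i; ge20[it] <- g20; a1020[it] <- a12
  }
  list(tot = tot, ge20 = ge20, a1020 = a1020, n_rejected = n_rejected)
}

.mc_scientific <- function(plot, hmod, amod, toggles, n_iter) {
  tr <- plot$trees
  if (nrow(tr) == 0) {
    return(list(tot = numeric(n_iter), ge20 = numeric(n_iter),
                a1020 = numeric(n_iter), n_rejected = 0L, empty = TRUE))
  }
  fixed <- list(dbh = tr$dbh, wd_mean = tr$wd_mean, wd_sd = tr$wd_sd)
  res <- .mc_core(n_iter, function() fixed, plot$area, hmod, amod, toggles)
  res$empty <- FALSE
  res
}

.mc_management <- function(inv, dbh_mod, hmod, amod, correction, toggles,
                           n_iter) {
  cl <- inv$classes
  if (nrow(cl) == 0 || sum(cl$count) == 0) {
    return(list(tot = numeric(n_iter), ge20 = numeric(n_iter),
                a1020 = numeric(n_iter), n_rejected = 0L, empty = TRUE))
  }
  hi_all <- ifelse(is.na(cl$class_hi), dbh_mod$d_max, cl$class_hi)
  obs <- list(lo = rep(cl$class_lo, cl$count), hi = rep(hi_all, cl$count),
              wd_mean = rep(cl$wd_mean, cl$count),
              wd_sd = rep(cl$wd_sd, cl$count))
  obs$flo <- .dbh_cdf(obs$lo, dbh_mod); obs$fhi <- .dbh_cdf(obs$hi, dbh_mod)
  # per-class expansion setup for partially sampled classes
  exp_cls <- unique(cl$class_lo[cl$p < 1])
  expinfo <- lapply(exp_cls, function(lo) {
    rows <- which(cl$class_lo == lo)
    hi <- hi_all[rows[1]]
    list(r = sum(cl$count[rows]), p = cl$p[rows[1]], lo = lo, hi = hi,
         flo = .dbh_cdf(lo, dbh_mod), fhi = .dbh_cdf(hi, dbh_mod),
         w = cl$count[rows], wd_mean = cl$wd_mean[rows],
         wd_sd = cl$wd_sd[rows],
         wbar = sum(cl$wd_mean[rows] * cl$count[rows]) / sum(cl$count[rows]),
         sbar = sum(cl$wd_sd[rows] * cl$count[rows]) / sum(cl$count[rows]))
  })
  gen <- function() {
    lo <- obs$lo; hi <- obs$hi; flo <- obs$flo; fhi <- obs$fhi
    wdm <- obs$wd_mean; wds <- obs$wd_sd
    for (e in expinfo) {
      x <- if (toggles$n_exp) {
        if (e$r > 0) stats::rnbinom(1, size = e$r, prob = e$p) else 0L
      } else round(e$r / e$p) - e$r
      if (x > 0) {
        if (toggles$n_exp) {
          j <- sample.int(length(e$w), x, replace = TRUE, prob = e$w)
          nwdm <- e$wd_mean[j]; nwds <- e$wd_sd[j]
        } else {
          nwdm <- rep(e$wbar, x); nwds <- rep(e$sbar, x)
        }
        lo <- c(lo, rep(e$lo, x)); hi <- c(hi, rep(e$hi, x))
        flo <- c(flo, rep(e$flo, x)); fhi <- c(fhi, rep(e$fhi, x))
        wdm <- c(wdm, nwdm); wds <- c(wds, nwds)
      }
    }
    n <- length(lo)
    u <- if (toggles$dbh_assign) stats::runif(n) else rep(0.5, n)
    dbh <- pmin(pmax(.dbh_quantile(flo + u * (fhi - flo), dbh_mod), lo), hi)
    list(dbh = dbh, wd_mean = wdm, wd_sd = wds)
  }
  res <- .mc_core(n_iter, gen, inv$area, hmod, amod, toggles,
                  correction = correction, corrected = !inv$has_10_20)
  res$empty <- FALSE
  res
}

#' Estimate AGB for a batch of plots
#'
#' Runs [estimate_plot_agb()] over a list of inventories with per-plot seed
#' substreams derived from the master seed and the plot label, so results are
#' identical regardless of processing order or batch composition. Failures on
#' individual plots are collected, not fatal.
#'
#' @param inventories list of `reference_plot` / `management_inventory`
#'   objects.
#' @param seed master seed.
#' @inheritParams estimate_plot_agb
#' @return data frame with one row per successfully estimated plot (columns
#'   as [as.data.frame.plot_agb_estimate()]); failed plots are reported in
#'   `attr(, "errors")` as a named character vector.
#' @export
batch_estimate <- function(inventories, dbh_mod = dbh_model(),
                           hmod = height_model(), amod = agb_model(),
                           correction = NULL, toggles = error_toggles(),
                           n_iter = 1000, seed = 1) {
  out <- vector("list", length(inventories))
  errors <- character(0)
  for (i in seq_along(inventories)) {
    inv <- inventories[[i]]
    id <- tryCatch(inv$plot_id, error = function(e) sprintf("[%d]", i))
    res <- tryCatch(
      estimate_plot_agb(inv, dbh_mod = dbh_mod, hmod = hmod, amod = amod,
                        correction = correction, toggles = toggles,
                        n_iter = n_iter,
                        seed = .derive_seed(seed, paste0("plot:", id))),
      error = function(e) e)
    if (inherits(res, "error")) {
      errors[id] <- conditionMessage(res)
    } else {
      out[[i]] <- as.data.frame(res)
    }
  }
  df <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(df)) df <- as.data.frame(estimate_plot_agb(
    generate_plot(stem_density = 0, seed = 1), n_iter = 1))[0, ]
  rownames(df) <- NULL
  attr(df, "errors") <- errors
  df
}
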