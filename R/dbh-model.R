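#' Stem diameter distribution model
#'
#' Constructs a parametric model for the distribution of tree diameters at
#' breast height (DBH, cm) on a bounded support `[d_min, d_max]`. The model is
#' used both to generate synthetic stem diameters and to assign continuous
#' diameters to trees recorded in 10-cm diameter classes. All probability
#' statements made by the package condition on the support, i.e. work with the
#' truncated distribution.
#'
#' Supported families and their parameters:
#' \describe{
#'   \item{`weibull`}{`scale` (cm) and `shape` (dimensionless).}
#'   \item{`exponential`}{`rate` (1/cm).}
#'   \item{`gamma`}{`shape` (dimensionless) and `rate` (1/cm).}
#' }
#'
#' The default is the two-parameter Weibull with scale 8.593 cm and shape
#' 0.737, a heavy-tailed size distribution typical of central African moist
#' forest, defined on DBH in \[10, 400\] cm.
#'
#' @param family distribution family, one of `"weibull"`, `"exponential"`,
#'   `"gamma"`.
#' @param scale Weibull scale parameter, cm.
#' @param shape Weibull or gamma shape parameter.
#' @param rate exponential or gamma rate parameter, 1/cm.
#' @param d_min lower support bound, cm (census threshold of the data the
#'   model describes).
#' @param d_max maximum assignable diameter, cm (upper bound of the open
#'   diameter class).
#' @return an object of class `dbh_model`.
#' @seealso [fit_dbh_model()], [assign_diameter()], [pdbh_trunc()]
#' @examples
#' m <- dbh_model()
#' pdbh_trunc(c(20, 50, 100), m)
#' @export
dbh_model <- function(family = c("weibull", "exponential", "gamma"),
                      scale = 8.593, shape = 0.737, rate = NULL,
                      d_min = 10, d_max = 400) {
  family <- match.arg(family)
  pars <- switch(family,
    weibull = c(scale = scale, shape = shape),
    exponential = {
      if (is.null(rate)) stop("exponential family requires `rate`")
      c(rate = rate)
    },
    gamma = {
      if (is.null(rate)) stop("gamma family requires `rate`")
      c(shape = shape, rate = rate)
    })
  if (any(!is.finite(pars)) || any(pars <= 0))
    stop("distribution parameters must be positive and finite")
  if (!is.finite(d_min) || !is.finite(d_max) || d_min <= 0 || d_min >= d_max)
    stop("support must satisfy 0 < d_min < d_max")
  structure(list(family = family, pars = pars, d_min = d_min, d_max = d_max),
            class = "dbh_model")
}

#' @export
print.dbh_model <- function(x, ...) {
  cat(sprintf("DBH distribution model: %s(%s) on [%g, %g] cm\n",
              x$family,
              paste(sprintf("%s = %g", names(x$pars), x$pars), collapse = ", "),
              x$d_min, x$d_max))
  invisible(x)
}

# untruncated CDF / quantile of the underlying family
.dbh_cdf <- function(x, model) {
  p <- model$pars
  switch(model$family,
    weibull = stats::pweibull(x, shape = p[["shape"]], scale = p[["scale"]]),
    exponential = stats::pexp(x, rate = p[["rate"]]),
    gamma = stats::pgamma(x, shape = p[["shape"]], rate = p[["rate"]]))
}

.dbh_quantile <- function(q, model) {
  p <- model$pars
  switch(model$family,
    weibull = stats::qweibull(q, shape = p[["shape"]], scale = p[["scale"]]),
    exponential = stats::qexp(q, rate = p[["rate"]]),
    gamma = stats::qgamma(q, shape = p[["shape"]], rate = p[["rate"]]))
}

#' Truncated diameter distribution functions
#'
#' CDF and quantile function of a [dbh_model()] conditioned on an interval
#' `[lo, hi]`, defaulting to the model support. These are the primitives of
#' inverse-transform diameter assignment: a class-conditional draw is
#' `qdbh_trunc(u, model, lo, hi)` with `u ~ Uniform(0, 1)`.
#'
#' @param q,p vector of quantiles / probabilities.
#' @param model a [dbh_model()].
#' @param lo,hi truncation bounds, cm; `NULL` means the model support bound.
#' @return numeric vector.
#' @export
pdbh_trunc <- function(q, model, lo = NULL, hi = NULL) {
  stopifnot(inherits(model, "dbh_model"))
  if (is.null(lo)) lo <- model$d_min
  if (is.null(hi)) hi <- model$d_max
  flo <- .dbh_cdf(lo, model); fhi <- .dbh_cdf(hi, model)
  pmin(pmax((.dbh_cdf(q, model) - flo) / (fhi - flo), 0), 1)
}

#' @rdname pdbh_trunc
#' @export
qdbh_trunc <- function(p, model, lo = NULL, hi = NULL) {
  stopifnot(inherits(model, "dbh_model"))
  if (is.null(lo)) lo <- model$d_min
  if (is.null(hi)) hi <- model$d_max
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("probabilities must lie in [0, 1]")
  flo <- .dbh_cdf(lo, model); fhi <- .dbh_cdf(hi, model)
  d <- .dbh_quantile(flo + p * (fhi - flo), model)
  # guard against floating-point excursions outside the class
  pmin(pmax(d, lo), hi)
}

#' Simulate stem diameters from a diameter distribution model
#'
#' Draws diameters from the model truncated to its support by inverse-transform
#' sampling.
#'
#' @param object a [dbh_model()].
#' @param nsim number of diameters to draw.
#' @param seed optional integer seed applied locally.
#' @param lo,hi optional truncation bounds overriding the model support.
#' @param ... unused.
#' @return numeric vector of diameters, cm.
#' @export
simulate.dbh_model <- function(object, nsim = 1, seed = NULL,
                               lo = NULL, hi = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  qdbh_trunc(stats::runif(nsim), object, lo = lo, hi = hi)
}

#' Assign continuous diameters to trees recorded in diameter classes
#'
#' Management inventories record DBH by 10-cm classes with a right-censored
#' open class. This function draws, for each tree, a continuous diameter from
#' the fitted diameter distribution conditioned on its class bounds, by inverse
#' transform sampling: `D = F^-1(F(lo) + u (F(hi) - F(lo)))`.
#'
#' @param model a [dbh_model()].
#' @param class_lo vector of class lower bounds, cm (one per tree).
#' @param class_hi vector of class upper bounds, cm; `NA` marks the open class,
#'   whose upper bound is the model `d_max`.
#' @param u optional uniform variates (one per tree), mainly for testing;
#'   drawn from the current RNG stream when `NULL`. `u = 0` returns `class_lo`
#'   exactly.
#' @return numeric vector of diameters, cm, each within its class.
#' @examples
#' m <- dbh_model()
#' assign_diameter(m, class_lo = c(10, 30, 150), class_hi = c(20, 40, NA))
#' @export
assign_diameter <- function(model, class_lo, class_hi = class_lo + 10, u = NULL) {
  stopifnot(inherits(model, "dbh_model"))
  n <- length(class_lo)
  class_hi <- rep_len(class_hi, n)
  class_hi[is.na(class_hi)] <- model$d_max
  if (any(class_lo < model$d_min - 1e-9) || any(class_hi > model$d_max + 1e-9))
    stop("diameter class outside the model support [d_min, d_max]")
  if (any(class_hi <= class_lo)) stop("class upper bounds must exceed lower bounds")
  if (is.null(u)) u <- stats::runif(n)
  qdbh_trunc(u, model, lo = class_lo, hi = class_hi)
}

# ---- fitting -----------------------------------------------------------------

# multinomial log-likelihood of binned, right-censored counts under `model`,
# normalized to the support [d_min, d_max]
.binned_loglik <- function(model, class_lo, class_hi, count) {
  hi <- ifelse(is.na(class_hi), model$d_max, class_hi)
  pr <- pdbh_trunc(hi, model) - pdbh_trunc(class_lo, model)
  if (any(pr <= 0 & count > 0)) return(-Inf)
  sum(count[count > 0] * log(pr[count > 0]))
}

.fit_one_family <- function(family, class_lo, class_hi, count, d_min, d_max) {
  # moment-style initial values from class midpoints (open class at lo + 20)
  mid <- ifelse(is.na(class_hi), class_lo + 20, (class_lo + class_hi) / 2)
  mbar <- sum(mid * count) / sum(count)
  make <- switch(family,
    weibull = function(th) dbh_model("weibull", scale = exp(th[1]),
                                     shape = exp(th[2]),
                                     d_min = d_min, d_max = d_max),
    gamma = function(th) dbh_model("gamma", shape = exp(th[1]),
                                   rate = exp(th[2]),
                                   d_min = d_min, d_max = d_max),
    exponential = function(th) dbh_model("exponential", rate = exp(th[1]),
                                         d_min = d_min, d_max = d_max))
  init <- switch(family,
    weibull = log(c(mbar, 1)),
    gamma = log(c(1, 1 / mbar)),
    exponential = log(1 / mbar))
  nll <- function(th) {
    m <- tryCatch(make(th), error = function(e) NULL)
    if (is.null(m)) return(1e12)
    ll <- .binned_loglik(m, class_lo, class_hi, count)
    if (!is.finite(ll)) 1e12 else -ll
  }
  opt <- if (length(init) == 1L) {
    stats::optim(init, nll, method = "Brent", lower = init - 12, upper = init + 12)
  } else {
    stats::optim(init, nll, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-10))
  }
  model <- make(opt$par)
  list(model = model, logLik = -opt$value, npar = length(init),
       converged = opt$convergence == 0)
}

#' Fit diameter distribution models to binned, right-censored counts
#'
#' Fits candidate probability distribution functions (two-parameter Weibull,
#' exponential, two-parameter gamma) to diameter-class counts by maximizing the
#' multinomial log-likelihood of the binned, right-censored data, for each
#' candidate maximum diameter `d_max` in a grid. Candidates are ranked by AIC
#' and reported with Akaike weights; the minimum-AIC candidate is retained as
#' the fitted model.
#'
#' The likelihood of counts `n_b` in classes `[lo_b, hi_b)` (the open class
#' contributing `[open_lo, d_max]`) is
#' `sum_b n_b log[(F(hi_b) - F(lo_b)) / (F(d_max) - F(d_min))]`
#' with `F` the family CDF.
#'
#' @param counts data frame with columns `class_lo`, `class_hi` (`NA` for the
#'   open class) and `count`.
#' @param families character vector of candidate families.
#' @param d_max_grid candidate maximum diameters, cm.
#' @param d_min lower support bound, cm.
#' @return an object of class `dbh_fit`: a list with `results` (one row per
#'   candidate: family, d_max, parameters, logLik, aic, akaike_weight,
#'   converged), `models` (the fitted [dbh_model()] objects), `best` (index of
#'   the minimum-AIC candidate) and `counts`.
#' @examples
#' m <- dbh_model()
#' d <- simulate(m, 5000, seed = 1)
#' cl <- pmin(floor(d / 10) * 10, 150)
#' tab <- as.data.frame(table(cl), stringsAsFactors = FALSE)
#' counts <- data.frame(class_lo = as.numeric(tab$cl),
#'                      class_hi = ifelse(as.numeric(tab$cl) >= 150, NA,
#'                                        as.numeric(tab$cl) + 10),
#'                      count = tab$Freq)
#' fit <- fit_dbh_model(counts, d_max_grid = 400)
#' coef(fit)
#' @export
fit_dbh_model <- function(counts,
                          families = c("weibull", "exponential", "gamma"),
                          d_max_grid = seq(300, 500, by = 50),
                          d_min = 10) {
  stopifnot(is.data.frame(counts),
            all(c("class_lo", "class_hi", "count") %in% names(counts)))
  families <- match.arg(families, c("weibull", "exponential", "gamma"),
                        several.ok = TRUE)
  if (all(counts$count == 0)) stop("all class counts are zero: nothing to fit")
  if (sum(counts$count[!is.na(counts$class_hi)] > 0) < 1)
    stop("at least one closed class with a positive count is required")
  if (sum(counts$count > 0) < 2)
    stop("cannot fit a diameter distribution to a single occupied class")
  grid <- expand.grid(family = families, d_max = d_max_grid,
                      stringsAsFactors = FALSE)
  fits <- lapply(seq_len(nrow(grid)), function(i) {
    .fit_one_family(grid$family[i], counts$class_lo, counts$class_hi,
                    counts$count, d_min, grid$d_max[i])
  })
  ll <- vapply(fits, `[[`, numeric(1), "logLik")
  npar <- vapply(fits, `[[`, numeric(1), "npar")
  aic <- 2 * npar - 2 * ll
  delta <- aic - min(aic)
  w <- exp(-delta / 2); w <- w / sum(w)
  results <- data.frame(family = grid$family, d_max = grid$d_max,
                        logLik = ll, aic = aic, delta_aic = delta,
                        akaike_weight = w,
                        converged = vapply(fits, `[[`, logical(1), "converged"),
                        stringsAsFactors = FALSE)
  pars <- lapply(fits, function(f) f$model$pars)
  results$par1 <- vapply(pars, function(p) p[[1]], numeric(1))
  results$par2 <- vapply(pars, function(p) if (length(p) > 1) p[[2]] else NA_real_,
                         numeric(1))
  structure(list(results = results,
                 models = lapply(fits, `[[`, "model"),
                 best = which.min(aic),
                 counts = counts),
            class = "dbh_fit")
}

#' @export
print.dbh_fit <- function(x, ...) {
  b <- x$results[x$best, ]
  cat(sprintf("Binned/censored diameter distribution fit (%d candidates)\n",
              nrow(x$results)))
  cat(sprintf("Selected by AIC: %s, d_max = %g cm (Akaike weight %.3f)\n",
              b$family, b$d_max, b$akaike_weight))
  print(x$models[[x$best]])
  invisible(x)
}

#' @export
summary.dbh_fit <- function(object, ...) {
  res <- object$results[order(object$results$aic), ]
  rownames(res) <- NULL
  res
}

#' @export
coef.dbh_fit <- function(object, ...) object$models[[object$best]]$pars

#' @export
logLik.dbh_fit <- function(object, ...) {
  b <- object$results[object$best, ]
  structure(b$logLik, df = sum(!is.na(c(b$par1, b$par2))), class = "logLik")
}

#' @export
simulate.dbh_fit <- function(object, nsim = 1, seed = NULL, ...) {
  simulate(object$models[[object$best]], nsim = nsim, seed = seed, ...)
}
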