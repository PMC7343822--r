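#' Height-diameter allometric model
#'
#' Asymptotic (Weibull-form) height-diameter model
#' `H = a (1 - exp(-b D^c))` with additive residual standard deviation
#' `sigma` (m). Defaults are the central African regional parameterization of
#' Feldpausch-type pantropical height-diameter allometry; all four values are
#' configuration, not constants, and should be replaced when a locally fitted
#' model is available.
#'
#' @param a asymptotic height, m.
#' @param b rate coefficient.
#' @param c shape exponent.
#' @param sigma residual standard deviation, m.
#' @return an object of class `height_model`.
#' @export
height_model <- function(a = 50.453, b = 0.0471, c = 0.8120, sigma = 5.7) {
  if (a <= 0 || b <= 0 || c <= 0 || sigma < 0)
    stop("height model requires a, b, c > 0 and sigma >= 0")
  structure(list(a = a, b = b, c = c, sigma = sigma), class = "height_model")
}

#' @export
print.height_model <- function(x, ...) {
  cat(sprintf("Height-diameter model: H = %g (1 - exp(-%g D^%g)), sigma = %g m\n",
              x$a, x$b, x$c, x$sigma))
  invisible(x)
}

#' Predict tree height from diameter
#'
#' @param dbh diameter at breast height, cm (vectorized).
#' @param model a [height_model()].
#' @return predicted height, m; strictly increasing in `dbh` and bounded above
#'   by the asymptote `a`.
#' @examples
#' predict_height(c(10, 50, 150), height_model())
#' @export
predict_height <- function(dbh, model = height_model()) {
  stopifnot(inherits(model, "height_model"))
  if (any(dbh <= 0)) stop("dbh must be positive")
  model$a * (1 - exp(-model$b * dbh^model$c))
}

#' Pantropical aboveground biomass model
#'
#' Power-law tree AGB allometry `AGB_kg = alpha (rho D^2 H)^beta` with
#' log-scale residual standard deviation `sigma_ln`. Defaults are the
#' pantropical moist-forest coefficients (alpha = 0.0673, beta = 0.976,
#' RSE 0.357 on the log scale). `coef_rel_sd` is the relative standard
#' deviation of the per-Monte-Carlo-iteration draw of (alpha, beta), shared by
#' all trees of an iteration; it represents allometric-model coefficient
#' uncertainty and is the component of plot-level CV that does not average out
#' with tree count. Its default (0.004) is calibrated so that the
#' classical-error plot CV on default synthetic forests matches plot CVs
#' reported for research-grade inventories (see the methods vignette).
#'
#' @param alpha multiplier.
#' @param beta exponent.
#' @param sigma_ln residual standard deviation on the log scale.
#' @param coef_rel_sd relative standard deviation of the shared coefficient
#'   draw per Monte Carlo iteration.
#' @return an object of class `agb_model`.
#' @export
agb_model <- function(alpha = 0.0673, beta = 0.976, sigma_ln = 0.357,
                      coef_rel_sd = 0.004) {
  if (alpha <= 0 || beta <= 0 || sigma_ln < 0 || coef_rel_sd < 0)
    stop("agb model requires alpha, beta > 0 and sigma_ln, coef_rel_sd >= 0")
  structure(list(alpha = alpha, beta = beta, sigma_ln = sigma_ln,
                 coef_rel_sd = coef_rel_sd), class = "agb_model")
}

#' @export
print.agb_model <- function(x, ...) {
  cat(sprintf(
    "AGB model: AGB = %g (rho D^2 H)^%g kg, sigma_ln = %g, coef_rel_sd = %g\n",
    x$alpha, x$beta, x$sigma_ln, x$coef_rel_sd))
  invisible(x)
}

#' Tree aboveground biomass
#'
#' Evaluates the AGB allometry for one or more trees and converts to Mg.
#'
#' @param wd wood density, g/cm3.
#' @param dbh diameter at breast height, cm.
#' @param h tree height, m.
#' @param model an [agb_model()].
#' @return tree AGB, Mg; monotone increasing in each input.
#' @examples
#' tree_agb(0.6, 30, 25)
#' @export
tree_agb <- function(wd, dbh, h, model = agb_model()) {
  stopifnot(inherits(model, "agb_model"))
  if (any(wd <= 0) || any(dbh <= 0) || any(h <= 0))
    stop("wd, dbh and h must be positive")
  model$alpha * (wd * dbh^2 * h)^model$beta / 1000
}

#' Wood density lookup with taxonomic fallback
#'
#' Resolves wood density for trees against a reference table at the finest
#' available taxonomic level: exact species match first, then the genus mean,
#' then the family mean, then the dataset-wide mean. The reported standard
#' deviation is the standard deviation of values at the matched level (for a
#' species match, the table's `wd_sd`; for the dataset fallback, the standard
#' deviation of all table values).
#'
#' @param genus,species character vectors (one entry per tree); `NA` allowed.
#' @param table reference table with columns `family`, `genus`, `species`,
#'   `wd_mean`, `wd_sd`.
#' @param family optional character vector of tree families for the
#'   family-level fallback.
#' @return data frame with columns `wd_mean`, `wd_sd` (g/cm3) and
#'   `resolution_level` (one of `"species"`, `"genus"`, `"family"`,
#'   `"dataset"`).
#' @export
lookup_wood_density <- function(genus, species, table, family = NULL) {
  stopifnot(is.data.frame(table),
            all(c("genus", "species", "wd_mean", "wd_sd") %in% names(table)))
  if (nrow(table) == 0) stop("wood density table is empty")
  n <- max(length(genus), length(species))
  genus <- rep_len(as.character(genus), n)
  species <- rep_len(as.character(species), n)
  if (!is.null(family)) family <- rep_len(as.character(family), n)
  out <- data.frame(wd_mean = NA_real_, wd_sd = NA_real_,
                    resolution_level = NA_character_,
                    stringsAsFactors = FALSE)[rep(1, n), , drop = FALSE]
  rownames(out) <- NULL
  key_sp <- paste(table$genus, table$species)
  for (i in seq_len(n)) {
    j <- which(key_sp == paste(genus[i], species[i]))
    if (length(j) >= 1 && !is.na(genus[i]) && !is.na(species[i])) {
      out$wd_mean[i] <- mean(table$wd_mean[j])
      out$wd_sd[i] <- mean(table$wd_sd[j])
      out$resolution_level[i] <- "species"
      next
    }
    j <- which(table$genus == genus[i])
    if (length(j) >= 1 && !is.na(genus[i])) {
      out$wd_mean[i] <- mean(table$wd_mean[j])
      out$wd_sd[i] <- if (length(j) > 1) stats::sd(table$wd_mean[j]) else
        mean(table$wd_sd[j])
      out$resolution_level[i] <- "genus"
      next
    }
    if (!is.null(family) && "family" %in% names(table) && !is.na(family[i])) {
      j <- which(table$family == family[i])
      if (length(j) >= 1) {
        out$wd_mean[i] <- mean(table$wd_mean[j])
        out$wd_sd[i] <- if (length(j) > 1) stats::sd(table$wd_mean[j]) else
          mean(table$wd_sd[j])
        out$resolution_level[i] <- "family"
        next
      }
    }
    out$wd_mean[i] <- mean(table$wd_mean)
    out$wd_sd[i] <- if (nrow(table) > 1) stats::sd(table$wd_mean) else
      mean(table$wd_sd)
    out$resolution_level[i] <- "dataset"
  }
  out
}

#' Error-source toggles for Monte Carlo propagation
#'
#' Switches for the six error sources propagated by the Monte Carlo engine:
#' per-tree wood density (`wd`), per-tree height-model residual (`height`),
#' AGB allometric-model error (`agb`: a per-iteration coefficient draw shared
#' across trees plus a per-tree log-normal residual), continuous diameter
#' assignment from classes (`dbh_assign`), negative-binomial expansion of
#' partially sampled counts (`n_exp`), and the residual of the 10-20 cm AGB
#' correction model (`agb_cor`).
#'
#' @param wd,height,agb,dbh_assign,n_exp,agb_cor logical flags.
#' @return an object of class `error_toggles`.
#' @seealso [classical_errors()], [all_errors()]
#' @export
error_toggles <- function(wd = FALSE, height = FALSE, agb = FALSE,
                          dbh_assign = FALSE, n_exp = FALSE, agb_cor = FALSE) {
  structure(list(wd = isTRUE(wd), height = isTRUE(height), agb = isTRUE(agb),
                 dbh_assign = isTRUE(dbh_assign), n_exp = isTRUE(n_exp),
                 agb_cor = isTRUE(agb_cor)),
            class = "error_toggles")
}

#' @rdname error_toggles
#' @export
classical_errors <- function() error_toggles(wd = TRUE, height = TRUE, agb = TRUE)

#' @rdname error_toggles
#' @export
all_errors <- function() error_toggles(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE)

#' @export
print.error_toggles <- function(x, ...) {
  on <- names(x)[vapply(x, isTRUE, logical(1))]
  cat("Error sources:", if (length(on)) paste(on, collapse = ", ") else "none", "\n")
  invisible(x)
}

# physical bounds of wood density draws (extreme values of the global database)
.WD_BOUNDS <- c(0.08, 1.39)

# vectorized truncated-normal draw by inverse CDF; sd = 0 returns the mean
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  x <- mean
  pos <- sd > 0
  if (any(pos)) {
    plo <- stats::pnorm(lo, mean[pos], sd[pos])
    phi <- stats::pnorm(hi, mean[pos], sd[pos])
    x[pos] <- stats::qnorm(stats::runif(sum(pos), plo, phi), mean[pos], sd[pos])
  }
  pmin(pmax(x, lo), hi)
}

#' Draw one Monte Carlo error realization for a tree list
#'
#' Applies one iteration's worth of stochastic perturbations to a tree list:
#' wood density drawn per tree from a normal distribution truncated to the
#' physical range \[0.08, 1.39\] g/cm3; height predicted from diameter with an
#' additive normal residual (floored at breast height, 1.3 m); and AGB
#' computed with a per-iteration shared draw of (alpha, beta) plus a per-tree
#' mean-one log-normal residual. With all toggles off the transform is the
#' identity: `wd = wd_mean`, `h = predict_height(dbh)`, `agb` deterministic.
#'
#' @param trees data frame with columns `dbh`, `wd_mean`, `wd_sd`.
#' @param toggles an [error_toggles()]; `dbh_assign`, `n_exp` and `agb_cor`
#'   are handled upstream by the engine and ignored here.
#' @param hmod a [height_model()].
#' @param amod an [agb_model()].
#' @return the tree data frame with columns `wd`, `h` and `agb` (Mg) added.
#' @export
draw_error_realization <- function(trees, toggles = error_toggles(),
                                   hmod = height_model(), amod = agb_model()) {
  n <- nrow(trees)
  wd <- if (toggles$wd)
    .rtruncnorm(n, trees$wd_mean, trees$wd_sd, .WD_BOUNDS[1], .WD_BOUNDS[2])
  else trees$wd_mean
  h <- predict_height(trees$dbh, hmod)
  if (toggles$height) h <- pmax(h + stats::rnorm(n, 0, hmod$sigma), 1.3)
  alpha <- amod$alpha; beta <- amod$beta
  if (toggles$agb && amod$coef_rel_sd > 0) {
    alpha <- alpha * (1 + stats::rnorm(1, 0, amod$coef_rel_sd))
    beta <- beta * (1 + stats::rnorm(1, 0, amod$coef_rel_sd))
  }
  agb <- alpha * (wd * trees$dbh^2 * h)^beta / 1000
  if (toggles$agb && amod$sigma_ln > 0)
    agb <- agb * exp(stats::rnorm(n, -amod$sigma_ln^2 / 2, amod$sigma_ln))
  trees$wd <- wd; trees$h <- h; trees$agb <- agb
  trees
}
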