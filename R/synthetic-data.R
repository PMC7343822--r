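# deterministic integer seed substream derived from a master seed and a key
# (counter-based: results do not depend on execution order)
.derive_seed <- function(master, key) {
  h <- as.double(master %% 2147483647L)
  for (ch in utf8ToInt(as.character(key))) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Generate a synthetic taxon pool with wood densities
#'
#' Builds a stand-in for a taxon-level wood density reference table: taxon
#' wood density means drawn from Normal(0.62, 0.12) truncated to
#' \[0.2, 1.0\] g/cm3 (the bulk of tropical tree wood densities), a common
#' within-taxon standard deviation, and relative abundances following a
#' geometric (log-series-like) decay, which yields the strong dominance
#' structure typical of tropical tree communities.
#'
#' @param n_taxa number of taxa (>= 1).
#' @param seed optional integer seed applied locally.
#' @param wd_mu,wd_sigma mean and sd of the truncated normal generating taxon
#'   wood density means, g/cm3.
#' @param wd_bounds truncation bounds for taxon wood density means, g/cm3.
#' @param taxon_wd_sd within-taxon wood density standard deviation, g/cm3.
#' @param abundance_ratio geometric decay ratio of ranked relative abundances.
#' @return data frame with columns `taxon_id`, `genus`, `species`, `wd_mean`,
#'   `wd_sd`, `rel_abundance` (summing to 1).
#' @examples
#' generate_taxon_table(5, seed = 1)
#' @export
generate_taxon_table <- function(n_taxa, seed = NULL, wd_mu = 0.62,
                                 wd_sigma = 0.12, wd_bounds = c(0.2, 1.0),
                                 taxon_wd_sd = 0.07, abundance_ratio = 0.97) {
  if (!is.numeric(n_taxa) || n_taxa < 1) stop("n_taxa must be >= 1")
  n_taxa <- as.integer(n_taxa)
  if (!is.null(seed)) set.seed(seed)
  wd <- .rtruncnorm(n_taxa, wd_mu, wd_sigma, wd_bounds[1], wd_bounds[2])
  ab <- abundance_ratio^(seq_len(n_taxa) - 1)
  data.frame(taxon_id = sprintf("t%04d", seq_len(n_taxa)),
             genus = sprintf("genus%03d", 1 + (seq_len(n_taxa) - 1) %/% 3),
             species = sprintf("sp%d", 1 + (seq_len(n_taxa) - 1) %% 3),
             wd_mean = wd, wd_sd = taxon_wd_sd,
             rel_abundance = ab / sum(ab),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic reference (scientific-dialect) forest plot
#'
#' Simulates a research-grade inventory plot: the number of stems with
#' DBH >= 10 cm is Poisson with mean `area * stem_density`, diameters are
#' drawn from the diameter distribution model truncated to its support, taxa
#' are drawn from the pool proportionally to their relative abundances, and
#' stem positions are uniform within a square plot.
#'
#' @param plot_id plot label.
#' @param area plot area, ha.
#' @param stem_density expected stems per ha with DBH >= `model$d_min`.
#' @param model a [dbh_model()] used as generator.
#' @param taxa taxon pool from [generate_taxon_table()].
#' @param seed optional integer seed applied locally.
#' @param origin plot lower-left corner in projected meters, `c(x, y)`.
#' @param date inventory date, fractional year.
#' @return an object of class `reference_plot`: a list with `plot_id`, `area`
#'   (ha), `side` (m), `trees` (data frame: `dbh`, `taxon_id`, `wd_mean`,
#'   `wd_sd`, `x`, `y`), `x`, `y` (origin, m) and `date`.
#' @export
generate_plot <- function(plot_id = "plot1", area = 0.5, stem_density = 500,
                          model = dbh_model(), taxa = generate_taxon_table(50, seed = 1),
                          seed = NULL, origin = c(0, 0), date = 2005) {
  if (area <= 0) stop("area must be positive")
  if (stem_density < 0) stop("stem_density must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- stats::rpois(1, area * stem_density)
  side <- sqrt(area * 1e4)
  idx <- if (n > 0)
    sample.int(nrow(taxa), n, replace = TRUE, prob = taxa$rel_abundance)
  else integer(0)
  trees <- data.frame(dbh = if (n > 0) simulate(model, n) else numeric(0),
                      taxon_id = taxa$taxon_id[idx],
                      wd_mean = taxa$wd_mean[idx],
                      wd_sd = taxa$wd_sd[idx],
                      x = stats::runif(n, 0, side),
                      y = stats::runif(n, 0, side),
                      stringsAsFactors = FALSE)
  structure(list(plot_id = plot_id, area = area, side = side, trees = trees,
                 x = origin[1], y = origin[2], date = date),
            class = "reference_plot")
}

#' @export
print.reference_plot <- function(x, ...) {
  cat(sprintf("Reference plot '%s': %.2f ha, %d stems >= 10 cm, origin (%g, %g)\n",
              x$plot_id, x$area, nrow(x$trees), x$x, x$y))
  invisible(x)
}

#' Generate a set of synthetic reference plots
#'
#' Convenience wrapper around [generate_plot()]. Per-plot seeds are derived
#' from the master seed and the plot label, so any subset of plots is
#' reproducible independently of generation order.
#'
#' @param n_plots number of plots.
#' @param seed master seed.
#' @param extent `c(xmin, xmax, ymin, ymax)` in projected meters within which
#'   plot origins are placed uniformly.
#' @param dates inventory dates, recycled over plots.
#' @inheritParams generate_plot
#' @return list of `reference_plot` objects.
#' @export
generate_plots <- function(n_plots, area = 0.5, stem_density = 500,
                           model = dbh_model(),
                           taxa = generate_taxon_table(50, seed = 1),
                           seed = 1, extent = c(0, 10000, 0, 10000),
                           dates = 2005) {
  dates <- rep_len(dates, n_plots)
  set.seed(.derive_seed(seed, "plot-origins"))
  ox <- stats::runif(n_plots, extent[1], extent[2])
  oy <- stats::runif(n_plots, extent[3], extent[4])
  lapply(seq_len(n_plots), function(i) {
    id <- sprintf("plot%04d", i)
    generate_plot(id, area = area, stem_density = stem_density, model = model,
                  taxa = taxa, seed = .derive_seed(seed, id),
                  origin = c(ox[i], oy[i]), date = dates[i])
  })
}

#' Degradation scenario for management-inventory emulation
#'
#' Describes how a research-grade inventory is degraded to the information
#' level of a forest-management inventory: diameters binned into 10-cm
#' classes, classes at or above `open_class` pooled into a right-censored open
#' class, small-tree classes subsampled on a fraction of plot area, classes
#' below the census threshold removed, and optionally the 10-20 cm class
#' removed entirely (to be recovered downstream by the AGB correction model).
#'
#' @param open_class lower bound of the open (right-censored) class, cm; one
#'   of 120, 130, ..., 200.
#' @param census_threshold minimum censused DBH, cm (10 or 20).
#' @param sampling_fractions named numeric vector of per-class spatial
#'   sampling fractions in (0, 1\], names being class lower bounds (e.g.
#'   `c("10" = 0.25)`); classes not named are fully sampled.
#' @param drop_10_20 remove the 10-20 cm class entirely (implies
#'   `census_threshold = 20`).
#' @return an object of class `degradation_scenario`.
#' @seealso [scenario_preset()] for the named presets used in validation.
#' @export
degradation_scenario <- function(open_class = 200, census_threshold = 10,
                                 sampling_fractions = numeric(),
                                 drop_10_20 = FALSE) {
  if (!open_class %in% seq(120, 200, by = 10))
    stop("open_class must be one of 120, 130, ..., 200 cm")
  if (!census_threshold %in% c(10, 20))
    stop("census_threshold must be 10 or 20 cm")
  if (length(sampling_fractions)) {
    if (is.null(names(sampling_fractions)))
      stop("sampling_fractions must be named by class lower bound")
    if (any(sampling_fractions <= 0 | sampling_fractions > 1))
      stop("sampling fractions must lie in (0, 1]")
  }
  if (drop_10_20) census_threshold <- 20
  structure(list(open_class = open_class, census_threshold = census_threshold,
                 sampling_fractions = sampling_fractions,
                 drop_10_20 = isTRUE(drop_10_20)),
            class = "degradation_scenario")
}

#' @export
print.degradation_scenario <- function(x, ...) {
  cat(sprintf("Degradation scenario: open class at %g cm, census >= %g cm%s\n",
              x$open_class, x$census_threshold,
              if (x$drop_10_20) ", 10-20 cm class removed" else ""))
  if (length(x$sampling_fractions))
    cat("  sampling fractions:",
        paste(sprintf("[%s-%s): %g", names(x$sampling_fractions),
                      as.numeric(names(x$sampling_fractions)) + 10,
                      x$sampling_fractions), collapse = ", "), "\n")
  invisible(x)
}

#' Degrade a reference plot into a management inventory
#'
#' Applies a [degradation_scenario()] to a `reference_plot`: diameters are
#' binned into half-open `[lo, lo + 10)` classes by `floor(D / 10) * 10`,
#' classes at or above the open threshold are pooled, each tree of a
#' subsampled class is independently retained with probability equal to the
#' class sampling fraction (binomial thinning, emulating a spatial sampling
#' fraction), and classes below the census threshold (or the 10-20 cm class
#' under `drop_10_20`) are removed. Taxon composition of retained trees is
#' preserved class by class.
#'
#' @param plot a `reference_plot`.
#' @param scenario a [degradation_scenario()].
#' @param seed optional integer seed applied locally (drives the thinning).
#' @return an object of class `management_inventory`: a list with `plot_id`,
#'   `area`, `classes` (data frame: `class_lo`, `class_hi` with `NA` for the
#'   open class, `taxon_id`, `wd_mean`, `wd_sd`, `count`, `p`),
#'   `census_threshold`, `open_class`, `has_10_20`, `x`, `y`, `date`.
#' @export
degrade_plot <- function(plot, scenario = degradation_scenario(), seed = NULL) {
  stopifnot(inherits(plot, "reference_plot"),
            inherits(scenario, "degradation_scenario"))
  if (!is.null(seed)) set.seed(seed)
  tr <- plot$trees
  cls <- floor(tr$dbh / 10) * 10
  open <- cls >= scenario$open_class
  cls[open] <- scenario$open_class
  # censoring floor
  keep <- cls >= scenario$census_threshold
  if (scenario$drop_10_20) keep <- keep & cls >= 20
  tr <- tr[keep, , drop = FALSE]; cls <- cls[keep]; open <- open[keep]
  # binomial thinning per subsampled class
  p <- rep(1, nrow(tr))
  for (nm in names(scenario$sampling_fractions)) {
    in_cls <- cls == as.numeric(nm)
    p[in_cls] <- scenario$sampling_fractions[[nm]]
  }
  retained <- stats::runif(nrow(tr)) <= p
  tr <- tr[retained, , drop = FALSE]; cls <- cls[retained]; p <- p[retained]
  key <- paste(cls, tr$taxon_id, sep = "|")
  agg <- if (nrow(tr)) {
    u <- !duplicated(key)
    data.frame(class_lo = cls[u],
               class_hi = ifelse(cls[u] >= scenario$open_class, NA, cls[u] + 10),
               taxon_id = tr$taxon_id[u],
               wd_mean = tr$wd_mean[u], wd_sd = tr$wd_sd[u],
               count = as.vector(table(key)[key[u]]),
               p = p[u], stringsAsFactors = FALSE)
  } else {
    data.frame(class_lo = numeric(0), class_hi = numeric(0),
               taxon_id = character(0), wd_mean = numeric(0),
               wd_sd = numeric(0), count = integer(0), p = numeric(0),
               stringsAsFactors = FALSE)
  }
  agg <- agg[order(agg$class_lo, agg$taxon_id), , drop = FALSE]
  rownames(agg) <- NULL
  structure(list(plot_id = plot$plot_id, area = plot$area, classes = agg,
                 census_threshold = scenario$census_threshold,
                 open_class = scenario$open_class,
                 has_10_20 = scenario$census_threshold < 20 && !scenario$drop_10_20,
                 x = plot$x, y = plot$y, date = plot$date),
            class = "management_inventory")
}

#' @export
print.management_inventory <- function(x, ...) {
  cat(sprintf(
    "Management inventory '%s': %.2f ha, %d trees in %d class x taxon records\n",
    x$plot_id, x$area, sum(x$classes$count), nrow(x$classes)))
  cat(sprintf("  census >= %g cm, open class at %g cm%s\n", x$census_threshold,
              x$open_class,
              if (!x$has_10_20) ", 10-20 cm class absent" else ""))
  invisible(x)
}

#' Split a reference plot into two halves
#'
#' Partitions a plot into two sub-plots along the x axis, emulating the
#' splitting of 1-ha research plots into halves matching the dominant
#' management plot size (~0.5 ha). The split boundary is the plot midline,
#' optionally snapped to a quadrat grid so that sub-plot areas take values
#' such as 0.48/0.52 ha.
#'
#' @param plot a `reference_plot`.
#' @param n_parts number of parts; only 2 is supported.
#' @param quadrat optional quadrat width, m; when given, the boundary is the
#'   multiple of `quadrat` nearest to the midline.
#' @return list of two `reference_plot` objects whose areas sum to the
#'   original area and whose tree lists partition the original tree list.
#' @export
split_plot <- function(plot, n_parts = 2, quadrat = NULL) {
  stopifnot(inherits(plot, "reference_plot"))
  if (n_parts != 2) stop("only splitting into 2 parts is supported")
  side <- plot$side
  bound <- side / 2
  if (!is.null(quadrat)) bound <- round(bound / quadrat) * quadrat
  if (bound <= 0 || bound >= side) stop("quadrat too coarse to split this plot")
  left <- plot$trees$x < bound
  mk <- function(trees, frac, tag, xoff) {
    structure(list(plot_id = paste0(plot$plot_id, tag),
                   area = plot$area * frac, side = side, trees = trees,
                   x = plot$x + xoff, y = plot$y, date = plot$date),
              class = "reference_plot")
  }
  list(mk(plot$trees[left, , drop = FALSE], bound / side, "_1", 0),
       mk(plot$trees[!left, , drop = FALSE], 1 - bound / side, "_2", bound))
}

# ---- delimited-text interfaces ----------------------------------------------

#' Read and write plot inventories as delimited text
#'
#' Reference (scientific-dialect) plots are written one row per tree
#' (`plot_id, dbh_cm, taxon_id, wd_mean, wd_sd, x, y`); management-dialect
#' inventories one row per class x taxon
#' (`plot_id, class_lo, class_hi, taxon_id, count, sampling_fraction`, with
#' `class_hi = "OPEN"` for the open class). Both carry a plot metadata sidecar
#' (`plot_id, area_ha, x, y, date, census_threshold, open_threshold`).
#'
#' @param plots list of `reference_plot` objects.
#' @param invs list of `management_inventory` objects.
#' @param trees_path,path,meta_path file paths.
#' @param taxa taxon table with `taxon_id`, `wd_mean`, `wd_sd` used to resolve
#'   wood density when reading management inventories.
#' @return the read functions return lists of `reference_plot` /
#'   `management_inventory` objects; the write functions return the main path,
#'   invisibly.
#' @name inventory_io
NULL

#' @rdname inventory_io
#' @export
write_reference_csv <- function(plots, trees_path, meta_path) {
  rows <- do.call(rbind, lapply(plots, function(p) {
    if (nrow(p$trees) == 0) return(NULL)
    data.frame(plot_id = p$plot_id, dbh_cm = p$trees$dbh,
               taxon_id = p$trees$taxon_id, wd_mean = p$trees$wd_mean,
               wd_sd = p$trees$wd_sd, x = p$trees$x, y = p$trees$y,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, trees_path, row.names = FALSE)
  meta <- do.call(rbind, lapply(plots, function(p)
    data.frame(plot_id = p$plot_id, area_ha = p$area, x = p$x, y = p$y,
               date = p$date, census_threshold = 10, open_threshold = NA,
               stringsAsFactors = FALSE)))
  utils::write.csv(meta, meta_path, row.names = FALSE)
  invisible(trees_path)
}

#' @rdname inventory_io
#' @export
read_reference_csv <- function(trees_path, meta_path) {
  rows <- utils::read.csv(trees_path, stringsAsFactors = FALSE)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    tr <- rows[rows$plot_id == m$plot_id, , drop = FALSE]
    structure(list(plot_id = m$plot_id, area = m$area_ha,
                   side = sqrt(m$area_ha * 1e4),
                   trees = data.frame(dbh = tr$dbh_cm, taxon_id = tr$taxon_id,
                                      wd_mean = tr$wd_mean, wd_sd = tr$wd_sd,
                                      x = tr$x, y = tr$y,
                                      stringsAsFactors = FALSE),
                   x = m$x, y = m$y, date = m$date),
              class = "reference_plot")
  })
}

#' @rdname inventory_io
#' @export
write_management_csv <- function(invs, path, meta_path) {
  rows <- do.call(rbind, lapply(invs, function(v) {
    if (nrow(v$classes) == 0) return(NULL)
    data.frame(plot_id = v$plot_id, class_lo = v$classes$class_lo,
               class_hi = ifelse(is.na(v$classes$class_hi), "OPEN",
                                 v$classes$class_hi),
               taxon_id = v$classes$taxon_id, count = v$classes$count,
               sampling_fraction = v$classes$p, stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  meta <- do.call(rbind, lapply(invs, function(v)
    data.frame(plot_id = v$plot_id, area_ha = v$area, x = v$x, y = v$y,
               date = v$date, census_threshold = v$census_threshold,
               open_threshold = v$open_class, stringsAsFactors = FALSE)))
  utils::write.csv(meta, meta_path, row.names = FALSE)
  invisible(path)
}

#' @rdname inventory_io
#' @export
read_management_csv <- function(path, meta_path, taxa) {
  rows <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  wd <- taxa[match(rows$taxon_id, taxa$taxon_id), c("wd_mean", "wd_sd")]
  if (anyNA(wd$wd_mean)) stop("unknown taxon_id in management inventory")
  lapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    sel <- rows$plot_id == m$plot_id
    cl <- data.frame(class_lo = rows$class_lo[sel],
                     class_hi = suppressWarnings(as.numeric(rows$class_hi[sel])),
                     taxon_id = rows$taxon_id[sel],
                     wd_mean = wd$wd_mean[sel], wd_sd = wd$wd_sd[sel],
                     count = rows$count[sel], p = rows$sampling_fraction[sel],
                     stringsAsFactors = FALSE)
    structure(list(plot_id = m$plot_id, area = m$area_ha, classes = cl,
                   census_threshold = m$census_threshold,
                   open_class = m$open_threshold,
                   has_10_20 = m$census_threshold < 20,
                   x = m$x, y = m$y, date = m$date),
              class = "management_inventory")
  })
}
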