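# shared fixtures: small taxon pool and helpers to bin diameters into the
# management-dialect count table

fixture_taxa <- generate_taxon_table(20, seed = 99)

bin_counts <- function(d, open_class = 150) {
  cl <- pmin(floor(d / 10) * 10, open_class)
  tab <- table(cl)
  lo <- as.numeric(names(tab))
  data.frame(class_lo = lo,
             class_hi = ifelse(lo >= open_class, NA, lo + 10),
             count = as.vector(tab))
}

# deterministic plot AGB: the engine's value with every error source off
deterministic_plot_agb <- function(plot, hmod = height_model(),
                                   amod = agb_model()) {
  tr <- plot$trees
  sum(tree_agb(tr$wd_mean, tr$dbh, predict_height(tr$dbh, hmod), amod)) /
    plot$area
}
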