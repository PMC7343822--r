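Package: forestAGB
Title: Forest Aboveground Biomass and Uncertainty from Degraded Management Inventories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates plot-level tropical forest aboveground biomass (AGB) and its
    uncertainty from forest-management inventory data in which tree diameters are
    recorded in 10-cm classes, the largest diameters are pooled in a right-censored
    open class, and small-tree classes are sampled on a fraction of the plot area.
    Provides binned, right-censored maximum-likelihood fitting of stem diameter
    distributions with AIC selection; inverse-transform assignment of continuous
    diameters from diameter classes; negative-binomial expansion of partially
    sampled small-tree counts; a linear correction model predicting the AGB of the
    missing 10-20 cm class from stand structure metrics; Monte Carlo propagation of
    wood-density, height-model and allometric-model errors to plot AGB; aggregation
    of plot estimates to raster pixels with intra-/inter-plot variance
    decomposition written as a five-layer GeoTIFF; and a synthetic forest generator
    with degradation operators for end-to-end validation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
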