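Package: vignagap
Title: Ecogeographic Analysis and Conservation Gap Assessment for Vigna Wild Relatives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An audited pipeline for ecogeographic analysis of crop wild
    relatives, built around the Vigna genus. Cleans georeferenced presence
    records (country-mismatch, coastal, centroid, duplicate and climate-outlier
    filters), models climatic niches with a presence-background maximum-entropy
    model (spatially thinned presences, convex-hull background sampling,
    max-sensitivity-plus-specificity thresholding), classifies taxa into
    climate-harshness groups with rank-based ANOVA and Tukey HSD compact
    letters, integrates abiotic-tolerance screening scores and biotic-resistance
    review tables, and computes ex situ conservation gaps (taxonomic and
    geographic) with genebank accession categories, richness rasters and
    priority-country rankings. Includes a synthetic-world generator with an
    error ledger so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
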