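Package: surfzone
Title: Multi-Method Surf-Zone Fish Biomonitoring with eDNA Metabarcoding,
    Occupancy Modelling, and Community Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing fish surveys of sandy-beach surf zones
    conducted by beach seine, baited remote underwater video (BRUV), and
    environmental DNA (eDNA) metabarcoding. Provides replicate-consistency
    decontamination of ASV read tables, taxonomic aggregation, eDNA index
    normalization, a Bayesian site-occupancy model with false-positive
    detections yielding per-species probability of occurrence, sensitivity
    and specificity, presence/absence community comparison (Jaccard
    dissimilarity, sequential PERMANOVA, homogeneity of dispersions, Venn
    overlap, incidence-based sample coverage and rarefaction/extrapolation),
    cross-method abundance concordance regressions, and a synthetic-data
    generator with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
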