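Package: smprospect
Title: Projecting Fungal Secondary-Metabolite Diversity from Gene Cluster Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation pipeline for projecting the secondary-metabolite (SM)
    diversity encoded by fungal biosynthetic gene clusters (BGCs).  Reads
    BiG-SCAPE-style BGC-to-gene-cluster-family (GCF) clustering tables, builds
    species-by-GCF incidence matrices, and estimates GCF richness by
    incidence-based rarefaction, Chao2 undetected-richness estimation, and
    extrapolation with bootstrap confidence intervals.  Computes the effective
    number of SMs per BGC from BGC-SM link tables by down-weighting shared
    compounds, projects GCF and SM counts across larger species pools via
    discovery-ratio scenario grids, and quantifies structural diversity of
    compound sets as one minus the mean pairwise Tanimoto similarity of
    molecular fingerprints.  A calibrated synthetic-data generator emulates
    the statistical structure of genome-mining surveys so that every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    ChemmineR,
    optparse
Config/testthat/edition: 3
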