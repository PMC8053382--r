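Package: emoccur
Title: Community Ecology and Site-Fungus Occurrence Analysis for
    Ectomycorrhizal OTU Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for site-structured ectomycorrhizal (EM)
    fungal OTU tables: rarefaction, alpha diversity and OTU accumulation
    curves, abundance classification, Venn partitioning of shared and
    site-specific OTUs, and lineage-level aggregation; Hellinger/Bray-Curtis
    and Sorensen community dissimilarity with Mantel tests, PerMANOVA, PCNM
    spatial eigenvectors and environmental vector fitting; and a
    permutation-null site/fungus occurrence analysis producing standardized
    d-prime specialization scores and two-dimensional occurrence (2DO)
    scores with false-discovery-rate control. A synthetic OTU-table
    generator with planted site specialists supports calibration, power and
    type-I-error studies of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    geosphere,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
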