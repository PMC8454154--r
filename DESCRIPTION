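Package: trophoweb
Title: Trophic Structure of Soil-Invertebrate Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking the trophic level of soil
    invertebrates (from nitrogen stable isotopes) to the diversity,
    uniqueness, assembly and network structure of their microbiomes.
    Provides OTU-table input/output and filtering, a synthetic study
    generator with planted ground truth, Shannon diversity and additive
    hierarchical diversity partitioning, UniFrac/Jaccard distances with
    PCoA and PERMANOVA, enterotyping by Jensen-Shannon distance and
    k-medoids, Sloan neutral community model fitting, delta-15N trophic
    level assignment, host-unique taxon detection, and co-occurrence
    network analysis of unidentified ("dark matter") taxa with
    node-removal null models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    cluster,
    igraph,
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    biomformat,
    mclust,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
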