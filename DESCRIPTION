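Package: germtrace
Title: Pedigree and Genomic-Marker Analysis of Crop Germplasm Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for tracing the germplasm sources of released crop cultivar
    populations by integrating parental-pedigree analysis with genomic-marker
    diversity statistics. Provides pedigree graph input/output and validation,
    terminal-ancestor tracing, nuclear and cytoplasmic genetic-contribution
    accounting, coefficient-of-parentage (COP) matrices, core-terminal-ancestor
    nomination and ancestor-derived families; SNP quality control, assembly of
    multi-allelic SNP linkage-disequilibrium blocks (SNPLDBs), genetic richness,
    allele-frequency dispersion, population-specific alleles, coefficient of
    genetic similarity (CGS), Weir-Cockerham F_ST, Mantel tests and PCA;
    neighbor-joining clustering with reproducible group cutting; multi-environment
    randomized-complete-block ANOVA with variance components and the genetic
    coefficient of variation; and a gene-dropping simulator of multi-ecoregion
    breeding programs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    phangorn,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
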