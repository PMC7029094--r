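Package: lampreykin
Title: Sibship Reconstruction, Breeder Inference and RAD-Capture Panel
    Analysis for Larval Sea Lamprey
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing kinship and reproductive ecology of larval
    sea lamprey (Petromyzon marinus) from RAD-capture SNP panels. Implements
    a breeding-matrix power simulator for sibship reconstruction, a
    likelihood-based full-sib/half-sib/unrelated dyad classifier, pedigree
    summary statistics (contributing adults, reproductive success, group
    coancestry, effective number of breeders by sibship frequencies and by
    linkage disequilibrium), randomization tests for spatial clustering of
    related dyads, and population-genomic summaries (diversity, Nei
    differentiation, DAPC-style ordination, trimmed chi-square F_ST outlier
    scanning, HDplot paralog statistics, genotype filtering). All inputs can
    be simulated, so every analysis runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
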