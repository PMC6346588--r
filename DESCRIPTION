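Package: seqgwas
Title: Simulation and Mixed-Model GWAS with Imputed Sequence Genotype and
    Dosage Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how imputation uncertainty in whole-genome
    sequence data affects single-SNP mixed-model association studies.
    Provides a seeded generator of two-line, LD-structured SNP data with a
    heritable quantitative trait and a calibrated imputation-error process
    producing genotype-probability and allele-dosage tracks; variant quality
    control matching common sequence pipelines (depth, site quality,
    missingness, spacing, minor allele frequency, genotype-class frequency,
    imputation-accuracy filters); genomic relationship matrices (Yang
    estimator) with leave-one-chromosome-out support; REML variance
    components and generalized-least-squares single-SNP tests for hard-call
    and dosage scores; genomic-control inflation factors, significance
    thresholds based on the effective number of independent chromosome
    segments, and greedy 0.5-Mb QTL-region calling; and an end-to-end
    pipeline comparing chip, dense-chip, imputed-genotype and imputed-dosage
    tracks against simulated ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
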