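Package: ancestryscore
Title: Ancestry-Aware Polygenic Score Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Improves polygenic-score (PGS) phenotype prediction by adding an
    ancestry score (AS) derived from genetically inferred ancestry. Provides
    projection of cohorts into the principal-component space of a shared map
    cohort (mapped PCs), per-SNP association scans (GWAS) and
    principal-component association studies (PCAS), p-value-thresholded PGS
    construction with LD clumping, tagging-SNP substitution, calibration of
    joint PGS+AS predictive models, and evaluation by phenotypic variance
    explained. Includes a three-population genotype/phenotype simulator
    (Balding-Nichols allele frequencies, Hardy-Weinberg genotype sampling,
    heritability-controlled continuous phenotypes) for studying when ancestry
    information improves trans-ancestry prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    vcfR,
    ggplot2,
    optparse,
    yaml
Config/testthat/edition: 3
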