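Package: rvburden
Title: Rare-Variant Gene-Burden Phenome-Wide Association Studies with
    Firth Logistic Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for phenome-wide association studies
    (PheWAS) of rare coding variation in targeted gene panels. Implements
    genotype-, sample- and variant-level sequencing quality control
    (allelic-balance and quality masking, call-rate and ratio-outlier
    filters, exact Hardy-Weinberg tests, principal-component ancestry
    assignment), consequence-based qualifying-variant classification with
    a seven-predictor damaging-missense consensus, ICD-to-PheCode phenome
    construction with a two-date case rule, per-gene burden scores, and
    Firth bias-reduced logistic regression with penalized
    likelihood-ratio tests, alongside Fisher's exact carrier (dominance)
    tests, age/sex interaction scans, gene-set burden tests, Gene
    Ontology over-representation, and Bonferroni/FDR multiplicity
    control. A synthetic-cohort generator with planted per-gene effects
    makes the whole pipeline testable without access to protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
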