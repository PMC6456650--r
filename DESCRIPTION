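Package: predxpop
Title: Cross-Population Accuracy of Genotype-Based Gene Expression Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating how well genotype-based gene expression
    prediction models transfer across populations. Reads PredictDB-format
    SQLite weight databases, extracts and harmonizes effect-allele dosages
    from VCF genotypes, predicts expression as a weighted linear combination
    of dosages, scores per-gene per-population Pearson correlations between
    observed and predicted expression, filters poorly predicted genes, and
    compares populations with paired t-tests, a random-intercept linear
    mixed model fit by restricted maximum likelihood, and repeated-measures
    ANOVA. Includes a synthetic multi-population study generator (Balding-
    Nichols allele-frequency drift, Markov-chain linkage disequilibrium,
    controlled cis-heritability) so the whole pipeline can be exercised and
    calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    DBI,
    RSQLite,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
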