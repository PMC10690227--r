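Package: f2eqtl
Title: Quantitative Genetics of Gene Expression in Replicated F2 Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for expression QTL mapping in
    multiparental replicated F2 designs, where one reference inbred line is
    crossed to several alternative lines and each F1 is selfed. Provides a
    hidden Markov model genotyper for allele-specific RNA-seq counts with
    marker-specific error rates, genetic map extraction and a line-of-origin
    relatedness matrix; maximum-likelihood animal-model variance partitioning
    of expression into cis and trans components with likelihood-ratio tests
    for additive and dominance cis effects; allelic-series inference over
    founder haplotypes; beta-binomial tests of allele-specific expression in
    heterozygotes; genetic covariance estimation for gene pairs via the
    variance-of-sums identity; per-family marker-regression scans with
    permutation thresholds, trans-eQTL clustering and hotspot calling; and
    principal-component QTL scans. A synthetic-data generator with known
    cis/trans architecture supports estimator benchmarking and end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
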