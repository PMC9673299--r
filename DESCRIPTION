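Package: namgwas
Title: Full Genetic Model GWAS and Breeding Prediction for NAM Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, quality control, association mapping and breeding
    prediction for nested association mapping (NAM) populations under a full
    genetic model with additive, dominance, digenic epistasis and
    gene-by-environment interaction effects.  Provides GMDR-style
    prescreening of loci and locus pairs, Henderson method III F-tests with
    permutation-based experiment-wise thresholds, Gibbs-sampling effect
    estimation, heritability partitioning into twelve components with
    dominance-related and environment-interaction aggregates, and prediction
    of superior lines and superior hybrids by exact enumeration or stepwise
    tuning of multi-locus genotype combinations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
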