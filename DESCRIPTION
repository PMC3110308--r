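Package: distortgwas
Title: Disease Model Distortion, Power, and Simulation for GWAS Under
    Linkage Disequilibrium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how imperfect linkage disequilibrium (LD)
    between causal and marker SNPs distorts case-control disease models in
    genome-wide association studies. Provides a two-locus LD engine
    parameterized by allele frequencies and the allelic correlation r,
    log-risk disease models with additive, dominance, and interaction
    parameters, exact and approximate computation of the disease model
    observed at a marker SNP, noncentrality-parameter power theory for the
    trend, deviation, and interaction tests (including the N/r^2, N/r^4,
    and N/(rr')^2 equivalent-sample-size rules), finite-sample association
    tests on genotype count tables, and a seedable GWAS simulation engine
    with synthetic haplotype panels, chip thinning, and a
    scan-replication-deviation outcome pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
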