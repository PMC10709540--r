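Package: breedsim
Title: Stochastic Simulation of Breeding Programs with Genomic Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the core operations of a modern breeding program:
    stochastic meiotic recombination under the Poisson crossover model
    (Haldane mapping function), biparental and diallel crossing plans,
    doubled-haploid induction, genomic estimated breeding values by tensor
    contraction of marker effects with phased genomes, phenotypes with
    heritability-calibrated genotype-by-environment interaction, and
    truncation selection with pluggable score functions (breeding value,
    optimal haploid value, phenotype). Includes a differentiable continuous
    relaxation of biparental crossing over parent-weight simplices, a
    configurable multi-stage inbred breeding-schema runner, phased-VCF and
    native population I/O, and seeded synthetic fixture generators.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    withr,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
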