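Package: ibdtrace
Title: IBD-Network Characterization of Rare Dominant Alleles in Genotype
    Databases
Version: 0.1.0
Authors@R:
    person("Maintainer", "ibdtrace", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to characterize a rare autosomal-dominant risk allele in a
    large genotype database: unphased identity-by-descent (IBD) segment
    detection by seeded haplotype matching with extension to homozygous
    mismatch, IBD-network-based carrier imputation from sharing with known
    carriers at a focal locus, population-ancestry and genealogical
    birth-record enrichment mapping, and allele age estimation from joint
    recombination and mutation clocks with a coalescent prior. Includes a
    fully synthetic study generator (pedigree gene dropping on a genetic map
    with Poisson recombination, background cohorts, ancestry annotations and
    migration-structured birth records) with complete truth labels, so every
    stage of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    graphics,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
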