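Package: lofmate
Title: Mate Selection and Genotyping Economics for Recessive Lethal Alleles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-generation simulation and optimization toolkit for managing
    recessive loss-of-function (LOF) alleles in a beef herd. Provides pedigree
    kinship and coancestry computation, a synthetic-herd generator (pedigree,
    EPDs with a published genetic-parameter structure, LOF locus panels),
    gene dropping with lethal-homozygote rejection, segregation analysis for
    genotype probabilities of ungenotyped animals (exact elimination on small
    pedigrees, iterative peeling on large ones), a maternal economic selection
    index, an evolutionary mate-selection optimizer balancing progeny index,
    parental coancestry and expected embryonic mortality, and the economic
    accounting (profit per mating, genotyping savings, net profit, breakeven
    test cost) for partial-herd genotyping strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
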