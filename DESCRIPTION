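Package: ptmapr
Title: Pseudo-Testcross Linkage Maps for Heterozygous F1 Families from
    Genotyping-by-Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction, phasing and curation of dense parent-separated
    genetic linkage maps for F1 families of highly heterozygous outcrossing
    species, from shallow-coverage genotyping-by-sequencing (GBS) genotype
    calls and without requiring parental genotypes.  Pseudo-testcross markers
    are identified from progeny segregation patterns with genotype-quality
    driven masking and correction of heterozygote under-calling; linkage
    groups are formed either by reference synteny or de novo through
    topological-overlap clustering of binary minor-allele signals; markers
    are phased, ordered with a minimum-spanning-tree method and mapped with
    the Kosambi function; maps are curated with missing-data and crossover
    filters, hidden-Markov genotyping-error estimation, drop-one-marker
    scans and rippling.  A synthetic F1 GBS simulator with known truth
    (parental phases, crossovers, contaminants, collapsed tandem duplicates)
    makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
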