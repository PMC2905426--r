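Package: karyophy
Title: Chromosomal Phylogenies from Cross-Species Chromosome Painting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building chromosomal phylogenies from comparative
    chromosome painting (ZOO-FISH) homology maps. Reads probe-to-target
    homology tables, counts hybridization signals, classifies conserved
    syntenies, detects syntenic associations and matches them against an
    ancestral-karyotype catalogue, codes presence/absence of discrete
    chromosomal characters into binary matrices, and infers most
    parsimonious trees by exhaustive enumeration of unrooted topologies
    with Fitch optimization, consistency/retention/homoplasy indices,
    outgroup rooting, character bootstrap and majority-rule consensus.
    Includes a karyotype rearrangement simulator (fusions, fissions,
    inversions, tandem fusions, sex-autosome translocations) and a
    two-state character simulator for end-to-end recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
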