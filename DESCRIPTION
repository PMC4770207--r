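Package: hammerhead
Title: Automated Design of Trans-Cleaving Hammerhead Ribozymes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enumerates, scores and ranks trans-cleaving hammerhead ribozyme
    candidates against a target RNA. Cleavage sites are NUH triplets; for each
    site all arm-length combinations in a user range are assembled around a
    conserved catalytic core. Candidates are filtered on nearest-neighbor
    annealing temperature of both arms, scored on ribozyme secondary-structure
    openness over a Boltzmann-style ensemble, on target cut-site accessibility
    (annealing-temperature and disruption-energy terms), and, for in vivo use,
    on off-target specificity against a reference transcriptome. Surviving
    candidates are min-max normalized and ranked by successive Pareto fronts,
    yielding a sortable design table. A deterministic mock folding backend
    makes every stage reproducible offline; ViennaRNA can be plugged in as an
    external ensemble provider.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
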