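Package: orthofix
Title: Orthology-Guided Correction of Reconciled Gene Trees
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Corrects reconciled gene trees so that externally supported
    orthology relations hold, while changing the tree as little as possible
    under the rooted Robinson-Foulds distance.  Two polynomial-time
    corrections are provided: pair constraints (required orthologous gene
    pairs, solved by recursive maximum-orthology-tree construction) and
    clade constraints (clades required to be rooted by speciation nodes,
    solved by pushing duplications via tree duplication, which is also
    triplet-maximal among the optima).  Includes LCA reconciliation and
    duplication/speciation labelling, rooted clade-based Robinson-Foulds
    and shared-triplet comparison, non-apparent duplication flagging,
    synteny-based inference of orthology constraints from gene orders,
    exhaustive brute-force oracles for small instances, seeded
    duplication-loss simulators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
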