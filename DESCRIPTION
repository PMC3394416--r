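Package: barrelfold
Title: Graph-Theoretic Recognition and Folding of Transmembrane Beta-Barrels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recognizes and folds transmembrane beta-barrel (TMB) proteins from
    sequence alone. Candidate membrane-spanning beta-strands are screened with
    Kyte-Doolittle amphipathicity constraints and a block-frequency information
    filter, assembled into a weighted directed acyclic graph whose vertices are
    oriented strand candidates, and folded by constrained longest-path dynamic
    programming: open beta-sheets, closed barrels at a prescribed strand count n
    and shear number S, and permuted barrels containing Greek key motifs. Ships
    a pluggable simplified pseudo-energy potential, TMB/non-TMB classification,
    permutation landscape scans, per-residue and per-strand prediction metrics,
    loop-mutation experiments via PAM250, and deterministic synthetic fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
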