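Package: rnacov
Title: Evidence for Conserved RNA Structure from Alignment Covariation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decides whether a multiple sequence alignment shows evidence of
    an evolutionarily conserved RNA secondary structure. Column-pair
    covariation (G-test, mutual information) is scored against phylogenetic
    null alignments that preserve the per-branch substitution history of the
    input while randomizing substitution sites, yielding empirical E-values.
    Covariation power is estimated from per-pair substitution counts, and
    alignments are classified into a four-way evidence scheme (structural,
    negative, cannot-tell, inconsistent-power). Includes a codon-evolution
    model explaining within-codon covariation in protein-coding alignments,
    and synthetic-data generators reproducing known covariation artifacts
    (occupancy bias, conserved-column traps, pseudogene dilution, shifted
    helices).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Matrix,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
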