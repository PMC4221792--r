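Package: distilseq
Title: Adaptive Compressed Sequencing Strategies for Single-Cell Genome Censuses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to plan and analyse adaptive compressed ("distilled
    sensing") sequencing strategies that recover every distinct genome in a
    sparse microbial community of single cells while sequencing far fewer
    nucleotides than cell-by-cell deep sequencing.  The package provides an
    idealized error-free sequencing-and-assembly oracle, per-permutation
    simulators of the depth-first and breadth-first adaptive pooling
    searches, and a dynamic-programming ensemble analyzer that computes the
    expected total sequenced nucleotides and the exact joint probability of
    capturing every distinct genome over all orderings of the input cells.
    A brute-force enumerator over small communities serves as an independent
    validation oracle for the dynamic program.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
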