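Package: imogfold
Title: Protein Folding in the 2D Triangular-Lattice HP Model via Ions
    Motion Optimization with Greedy Local Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for hydrophobic-polar (HP) lattice protein folding on the
    two-dimensional triangular lattice. Provides parsing of HP sequences in
    letter or binary repeat notation, the 28 classic benchmark instances,
    contact-energy evaluation, an ions motion optimization metaheuristic
    hybridized with a greedy single-direction local search (IMOG), an
    exhaustive self-avoiding-walk enumeration oracle for short chains, batch
    statistics over independent runs, and rendering of folds to ggplot2,
    ASCII and SVG.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
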