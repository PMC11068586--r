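Package: tcc
Title: Turing-Chomsky Compression for Minimalist Syntactic Derivations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for scoring stages of minimalist syntactic derivations by
    algorithmic compressibility. Bare-phrase-structure trees are read and
    written in labeled bracket notation; a MERGE engine derives workspaces
    under the economy conditions of current syntactic theory (No Tampering,
    Resource Restriction, Relativised Minimality, minimal search); four
    serializers turn structures, search paths, movement paths and label
    sequences into finite-alphabet symbol strings; and a Lempel-Ziv (1976)
    phrase-counting estimator of Kolmogorov complexity, with a calibrated
    normalization, ranks competing derivational options. The Turing-Chomsky
    Compression comparator predicts the grammatically licensed option as the
    one whose encoding attains the lowest normalized complexity, and ships
    worked examples (polar interrogatives, wh-islands, Bulgarian multiple
    wh-fronting, raising/labeling contrasts) as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: jsonlite, stats, utils
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
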