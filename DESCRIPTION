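Package: orfclass
Title: Coding-Sequence Classification with Interpolated Markov Models and
    Canonical Powered Partial Least Squares
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds reliable training sets for prokaryotic coding-sequence
    modeling from multi-strain pangenomes (highly conserved ORFs as Positives,
    their out-of-frame interiors as Negatives), and trains and compares two
    classifiers on frame-aware DNA, codon and protein representations: an
    interpolated Markov model with EM-estimated interpolation weights and
    m/4 pseudo-counts, and a Canonical Powered Partial Least Squares (CPPLS)
    discriminant on word-frequency matrices. Includes 10-fold cross-validated
    performance metrics, arcsine-transformed balanced mixed-effect ANOVA with
    Tukey comparisons and variance F-tests, and a synthetic pangenome
    generator with planted gene families for fully self-contained analyses.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
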