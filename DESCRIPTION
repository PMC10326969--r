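Package: cas9repair
Title: Cas9 Double-Strand-Break Repair Outcome Profiling Across DNA Repair
    Knockouts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing CRISPR/Cas9 editing-outcome screens across
    DNA-repair-gene knockout cell lines. Provides a canonical indel
    representation with microhomology calculus, templated-insertion calls and
    a ten-category outcome classification; readers and writers for target
    libraries and long-format outcome count tables; a synthetic screen
    generator with exported ground truth; filtering, pooling, log2
    fold-change and divergence profiling; low-dimensional embedding and
    clustering of knockout response profiles; exponential modelling of
    microhomology-deletion frequency against inter-homology distance; and a
    per-cell-line softmax outcome-frequency predictor trained by minimising
    Kullback-Leibler divergence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
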