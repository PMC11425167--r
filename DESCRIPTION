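Package: qwalkmer
Title: Coined Quantum Walk Search on the DNA 2-Mer Hypercube
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact statevector simulation of the coined quantum walk search
    on a four-dimensional hypercube whose vertices are 2-bit-encoded DNA
    2-mers. Provides the 2-bit nucleotide encoding (T=00, C=01, A=10, G=11),
    assembly and parsing of 11-qubit register initialization strings, the
    walk circuit (Grover coin, hypercube shift, phase oracle, phase
    estimation with a reflection about the zero-phase subspace), a
    transfer-matrix fast path that makes the exhaustive input-by-mark sweep
    a desk-scale job, and the downstream analysis: per-run accuracy,
    hit-distribution standard deviation, sigma-based outcome categories,
    census over all 2048 initialization strings, and the auxiliary-qubit
    effect comparison. No quantum SDK is required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    readr,
    rlang,
    ggplot2,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
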