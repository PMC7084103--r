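Package: frameshiftr
Title: Frameshift Robustness of Protein Physicochemical Properties
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how well physicochemical properties of proteins
    survive +1 and -1 translational frameshifts. Provides the universal
    genetic code with frameshift pair enumeration and randomized control
    codes, amino-acid property scale handling (AAindex flat files and
    tabular custom scales), genetic-code-level Pearson correlation
    statistics with random-scale Gaussian nulls and category enrichment,
    computational derivation of optimally frameshift-stable scales and
    their principal-component geometry, windowed property profiles of
    protein and mRNA sequences with a stop-exclusion rule, proteome-scale
    wild-type versus frameshift profile comparison, and a synthetic
    proteome and scale-library generator so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
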