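Package: fitr
Title: Frequency Increment Tests for Selection from Time-Series Allele Frequencies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects natural selection at a diallelic locus from time-series
    allele-frequency data. Implements the frequency increment test (FIT),
    which compares standardized per-interval frequency increments against a
    Student-t null, and its extension with independent neutral reference loci
    (FITR), which cancels the unknown, possibly fluctuating population size
    by standardizing the focal increment with the empirical drift magnitude
    at R reference loci. Includes Wright-Fisher forward simulators (exact
    binomial, fast pseudo-sampling, and an individual-based linked-loci
    scheme), step/exponential demographic models, binomial individual
    sampling, and replicate-level drivers that estimate type-I error rates
    and power with Monte-Carlo standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
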