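Package: kmermix
Title: Alignment-Free Taxonomic Profiling of Metagenomes by k-mer Mixture
    Deconvolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the relative abundances of reference organisms in a
    shotgun metagenome without aligning individual reads. A single canonical
    k-mer frequency vector is computed over all reads jointly and matched
    against a column-normalized reference k-mer matrix by non-negative least
    squares (Lawson-Hanson active set) with optional Tikhonov regularization.
    Abundances are aggregated across taxonomic ranks, and uncertainty is
    quantified by jackknife half-sampling of the reads. Includes a read
    simulator with known mixing proportions, a reference-database builder and
    serializer, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
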