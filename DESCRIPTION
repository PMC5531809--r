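Package: dudeseq
Title: Two-Pass Universal Denoising of Targeted Amplicon Sequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Error correction for targeted amplicon sequencing reads using
    the discrete universal denoiser (DUDE). Substitution errors are corrected
    by a two-pass sliding-window rule that aggregates double-sided context
    statistics across all reads and inverts an estimated discrete memoryless
    channel (a 4x4 confusion matrix). Homopolymer insertion/deletion errors
    are corrected on pyrosequencing flowgrams by quantizing intensities to
    integer run lengths and applying the same rule under a virtual channel
    derived from conditional intensity densities. Includes confusion-matrix
    estimation from aligned read/reference pairs, a ground-truthed read and
    flowgram simulator, per-base error-rate and clustering-concordance
    evaluation metrics, sequence-complexity scores, plain-text readers and
    writers for the supported formats, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
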