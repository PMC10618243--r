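Package: fionidx
Title: Fragment-Ion Index Search Engine for Tandem Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale peptide database search engine for tandem mass
    spectrometry built around a sorted fragment-ion index. Provides in-silico
    tryptic digestion with variable post-translational modifications,
    theoretical b/y-ion spectrum generation, a mass-sorted peptide index with
    an m/z-sorted fragment-ion index supporting tolerance-window queries,
    MS2 reading/writing with top-K peak extraction, hyperscore-based
    open and closed database search with per-spectrum null score
    distributions, and expectation values from a linear fit to the log
    survival of the null distribution. Includes a seeded synthetic-data
    generator (proteins, modified peptides, spectra with ground truth) so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
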