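Package: leaderscout
Title: Discovery and Validation Analytics for Structured mRNA Leaders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale comparative-genomics toolkit for discovering
    structured RNA elements in the 5' leaders of bacterial genes and for
    the quantitative analytics used to validate them. Provides harvesting
    of putative 5' untranslated regions upstream of a target gene (with
    redundancy removal and taxonomic clustering), progressive alignment
    with Gerstein-Sonnhammer-Chothia sequence weighting, covariation
    scoring and Nussinov-style nested-pairing structure inference,
    profile-based homology search with empirical Gumbel E-value
    calibration, transcription start site calling from read-depth
    change-points, annotated-Stockholm consensus reporting, equilibrium
    filter-binding isotherm fitting with censoring, and GFP reporter
    fold-change statistics. A synthetic-data generator with planted
    covarying helices, step-shaped coverage, and hyperbolic binding
    curves makes the whole pipeline testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    ape,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
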