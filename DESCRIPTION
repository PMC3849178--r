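Package: coopnet
Title: Cooperative Transcription-Factor Partner and Target Inference from
    ChIP-Seq and Time-Course Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated pipeline for inferring a transcription factor's
    cooperative partners and functionally active target genes from ChIP-seq
    peaks and short time-course expression data, and for assembling the
    resulting TF-centred regulatory network.  Provides spaced-motif
    co-occurrence enrichment inside peaks, a hypergeometric cooperativity
    test on expression correlations of shared-target gene pairs, Gaussian
    process latent-force ODE ranking of candidate targets, preranked gene
    set enrichment with permutation family-wise error control, SAM-style
    permutation differential expression, direction-separated Fisher
    over-representation, and a synthetic-data generator that emulates the
    assumed statistical structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr,
    jsonlite
Config/testthat/edition: 3
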