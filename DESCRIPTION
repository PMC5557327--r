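Package: crpevol
Title: Duplication, Selection and Expression Divergence of Cysteine-Rich
    Peptide Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-evolution toolkit for large plant gene families such
    as the cysteine-rich peptides (CRPs). Detects chromosomal gene clusters
    under an intergenic-distance rule, chains homologous anchors into
    collinear blocks and classifies duplicate genes (WGD/segmental, tandem,
    proximal, dispersed, singleton), estimates Ka/Ks by the Nei-Gojobori
    (1986) counting method with Jukes-Cantor correction and Fisher-exact
    significance, dates duplication bursts from Ks kernel-density peaks,
    performs likelihood-ratio tests over site-model log-likelihoods and
    Bartlett rate-group comparisons, and measures expression divergence and
    within-cluster expression coordination of duplicate pairs. Ships a
    synthetic-genome generator with a ground-truth ledger so every stage is
    testable without external genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
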