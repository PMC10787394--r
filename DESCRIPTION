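Package: ripnet
Title: RIP-Aware Subfamily Classification of Transposable Elements with
    Sequence Similarity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Consensus-free classification of long-terminal-repeat (LTR)
    retrotransposon copies into subfamilies using thresholded sequence
    similarity networks and unweighted greedy modularity community
    detection, designed for fungal genomes shaped by repeat-induced point
    mutation (RIP). Includes cleaning and per-pair merging of fragmented
    and overlapping all-vs-all BLAST hits with identity recalculation over
    the non-overlapping union of HSPs, centroid (exemplar) extraction,
    user-directed community merging into named subfamilies, comparison of
    classifications, rogue-copy detection against a phylogeny, LTR
    copy-context annotation (full copy, solo-LTR, fragment, nested),
    RepeatMasker output post-processing into per-species subfamily counts,
    and a forward simulator of LTR-retrotransposon families under RIP that
    emits FASTA, truth tables and exact hit tables for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    igraph,
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
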