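Package: isocoupler
Title: Coupling Between Transcription Start Sites and Polyadenylation
    Sites from Full-Length Long Reads
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies the coupling between transcription start sites
    (TSSs) and polyadenylation sites (PASs) in full-length long-read
    transcriptomes. Builds a confident poly(A)-site database from
    tail-anchored reads, filters and corrects transcript 3' ends,
    quantifies 5'-3' isoforms and tests per-gene TSS bias by
    Monte-Carlo chi-squared contingency testing with promoter-dominance
    calls (LATER), detects TSS-exon and exon-PAS splicing links
    (LASER), computes downstream alternative-polyadenylation statistics
    (diversity indices, proximal/distal PAS classification,
    poly(A)-signal skipping), and scores promoter-3'UTR co-evolution by
    mutual information with average product correction. Includes a
    synthetic-data generator emulating multi-TSS/multi-PAS gene models,
    read artifacts (5' truncation, internal priming), and species
    alignments with planted covariation, so the whole pipeline is
    testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    optparse,
    jsonlite,
    vegan,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
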