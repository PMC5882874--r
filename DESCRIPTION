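Package: riboreg
Title: Detection and Regulatory Classification of TPP Riboswitches in
    Fungal-Style Genomes
Version: 0.1.0
Authors@R:
    person("Riboreg", "Developers", email = "riboreg@example.org",
           role = c("aut", "cre"))
Description: Detects candidate thiamin-pyrophosphate (TPP) riboswitch
    aptamers in genomic sequence with a position-specific log-odds profile
    scanner, annotates the conserved aptamer motifs (GAGAU, J4/5 GCG,
    L5 UAAU and the non-canonical G-G pair), maps candidate hits onto gene
    models to derive their genomic context, classifies the implied
    regulatory mechanism into four location-defined types (5'UTR-intron
    uORF splicing, long-intron long-range alpha/alpha' pairing, short
    internal intron with in-frame stop codon, splice-site-free single-exon
    5'UTR), and applies tabular homology-filter rules for transporter
    annotation and single-copy marker selection.  Ships a synthetic-genome
    generator that plants each architecture with ground truth so the whole
    chain is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    rtracklayer,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
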