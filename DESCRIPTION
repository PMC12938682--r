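Package: codonbias
Title: Codon Usage Bias Analysis for Nuclear and Mitochondrial Coding Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the complete codon-usage-bias workflow on coding
    sequence (CDS) sets: sequence screening (start/stop structure, length,
    internal stops, redundancy removal by global-alignment identity),
    per-gene composition indices (positional GC content, silent-site base
    composition, RSCU, Wright's effective number of codons, CAI, Gravy,
    Aromo), diagnostic analyses (neutrality regression of GC12 on GC3,
    ENC-GC3 plots with the expected-ENC curve and ENC-ratio histograms,
    PR2 parity plots), correspondence analysis of gene-by-codon RSCU
    matrices, optimal-codon identification by maximum RSCU and by the
    delta-RSCU high/low-expression contrast, and a synthetic CDS generator
    with controllable mutational GC3 bias and translational selection for
    ground-truth validation. Reads CDS from FASTA or GenBank flat files and
    supports alternative genetic codes, including mold and invertebrate
    mitochondrial codes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    seqinr,
    rlang,
    stats,
    utils,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite
Config/testthat/edition: 3
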