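Package: codonbias
Title: Codon Usage Bias Analysis for Transcriptome Coding Sequences
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the standard codon-usage-bias index suite for a set of
    nucleotide coding sequences: nucleotide and dinucleotide composition by
    codon position, relative synonymous codon usage (RSCU) with
    preferred/avoided codon classification, Wright's effective number of
    codons (ENC) with the GC3-expected curve and deviation ratios, Parity
    Rule 2 bias coordinates, the neutrality (GC12 on GC3) regression with its
    mutation/selection decomposition, expression stratification of ENC and GC
    content, focal gene-set comparison, and principal component decompositions
    of RSCU and amino-acid composition matrices. A synthetic coding-sequence
    generator with explicit mutational GC3 bias and translational-selection
    parameters provides ground truth for every analysis stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
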