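Package: phagekit
Title: Quantitative Analyses for Bacteriophage Characterization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative side of lytic bacteriophage
    characterization against a bacterial host: strand-aware extraction of
    coding sequences from FASTA/GFF3, relative codon frequencies and
    phage-to-host codon usage ratios with threshold binning, cross-referencing
    of over-represented codons against a tRNA anticodon complement, latent
    period / rise period / burst size estimation from one-step growth curves,
    titers and efficiency of plating from spot dilution series, and
    normality-gated two-group comparisons (paired t-test or Mann-Whitney U)
    for biofilm assays. A synthetic-data generator produces coding genomes
    with controlled codon bias, growth curves, dilution-series plaque counts
    and two-group biofilm datasets with known ground truth, so the whole
    pipeline runs and is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
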