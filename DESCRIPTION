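Package: ecstress
Title: Exon and MicroRNA Screens for Acute Endothelial Stress Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens for RNA biomarkers of acute cellular stress responses in
    endothelial cells from two-condition RNA-seq and qPCR data. Implements a
    staged funnel that detects treatment-exclusive novel exons and classifies
    them as nonsense-mediated decay (NMD) targets by the 50-nt premature
    termination codon rule; pre-miRNA stem-loop quantification with
    library-size and length normalization, a 20 percent differential rule, and
    5p/3p mature-arm strand-bias classification from unique exact matches;
    absolute qPCR quantification against a spiked calibrator standard curve;
    and nonparametric comparison of miRNA-family target versus non-target mRNA
    fold changes (Mann-Whitney, Kruskal-Wallis and Friedman with Dunn's
    post-hoc tests). A seeded synthetic-data generator produces genomes,
    annotations, count tables, small-RNA reads and qPCR plates with known
    ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
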