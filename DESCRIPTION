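Package: CpGscape
Title: Landscape of C:G>T:A Polymorphism at CpG Dinucleotides and CpG Islands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide analysis of C:G>T:A transitions at CpG
    dinucleotides driven by 5-methylcytosine deamination. Enumerates CpG
    sites from a reference sequence, calls CpG islands by the
    Gardiner-Garden criteria and classifies them by functional context
    (TSS-coding, TSS-noncoding, intragenic-coding, intragenic-noncoding,
    intergenic), attaches population variant catalogues (VCF) to CpG sites,
    computes per-class, allele-frequency-binned, allele-frequency-weighted
    and distance-resolved mutation rates with binomial confidence
    intervals, summarises bisulfite methylation tracks per island and
    around island borders, enumerates silent-, missense- and
    nonsense-primed coding CpG positions, and decomposes rare-variant
    trinucleotide spectra against a signature matrix by non-negative least
    squares. A fully specified synthetic-data generator produces
    closed-loop test bundles (FASTA, genePred, BED, bedGraph, VCF) with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    VariantAnnotation,
    rtracklayer,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
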