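Package: SpliceSieve
Title: Stringent Discovery and Classification of Non-Canonical Splice Sites
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts splice junctions from gapped RNA-seq alignments and applies a
    set of stringent filters (anchor length, distinct-sequence support, multi-source
    reproducibility, SNP/indel overlap, DUST low-complexity, diploid concordance)
    to obtain high-confidence junction calls. Non-canonical junctions (terminal
    dinucleotides other than GT-AG, GC-AG or AT-AC) are disambiguated across
    direct-repeat-induced equivalent placements and classified as U2/U12-like or
    non-U2/U12 by position-weight-matrix scoring against a scrambled-sequence null.
    Additional components quantify alternative splice site usage (psi with Wilson
    confidence intervals), detect reverse-transcriptase template-switching and
    homopolymer artifact signatures, recode splice dinucleotides supported by A-to-I
    editing evidence, profile splicing-regulatory-element hexamer density around
    splice sites, test cross-species conservation, and write genome-browser junction
    tracks. A self-consistent simulator generates genomes with implanted junction
    classes and matching alignment, variant and pileup evidence for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    SummarizedExperiment,
    GenomicAlignments,
    VariantAnnotation,
    rtracklayer,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
biocViews: RNASeq, AlternativeSplicing, Transcriptomics, Sequencing
Config/testthat/edition: 3
RoxygenNote: 7.3.3
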