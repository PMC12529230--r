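Package: napbind
Title: Genome-Wide Binding Characterization of Nucleoid-Associated Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to characterize genome-wide occupancy of non-sequence-specific
    nucleoid-associated proteins from ChIP-seq peak tables: summit-window
    extraction, intergenic/coding context classification, AT-content enrichment
    statistics against genomic backgrounds, fold-enrichment category reports,
    subpeak merging, gene annotation of enriched regions, and peak-width versus
    enrichment correlation. Also quantifies two in vitro readouts of nonspecific
    DNA binding: apparent dissociation constants from EMSA saturation titrations
    and complex heights and foci counts from AFM topographs. A seeded synthetic
    data module generates genomes with contrasting intergenic/coding AT
    composition, AT-biased occupancy tracks with replicated Poisson coverage,
    toy peak calls, binding isotherms and topographs, so every analysis is
    exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    minpack.lm,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
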