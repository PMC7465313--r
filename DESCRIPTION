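Package: capxcise
Title: Design, Simulation and QC of CRISPR-Cas9 Targeted-Excision Nanopore Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for planning and benchmarking Cas9 in-vitro excision
    enrichment experiments read out by nanopore long-read sequencing. Generates
    seeded synthetic diploid genomes carrying a minisatellite target locus,
    designs and scores NGG guides, predicts cut sites and digestion fragment
    sizes with full end-state bookkeeping (phosphorylation, Cas9 blockage,
    dA-tailing, adapter ligation), simulates enrichment libraries and nanopore
    reads with truth tracking, computes run and on/off-target enrichment
    statistics from alignments, and phases tandem-repeat copy-number alleles
    from on-target reads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    seqinr,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
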