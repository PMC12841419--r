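Package: panelkit
Title: Targeted SNP Genotyping Panel Design and Cultivar Identification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for designing targeted (in-solution capture) SNP
    genotyping panels and applying them to cultivar identification.
    Implements the variant quality-control cascade (hard site filters and
    population-level call-rate/MAF/biallelic filters), capture-probe
    feasibility screening of candidate SNPs from flanking genomic context
    (single-copy uniqueness, GC content, repeat/N and nearby-InDel
    screens), functional-impact annotation against gene models, and
    windowed integration of trait-associated and resequencing-derived
    loci into a genome-spanning panel. Includes an identification layer
    (pairwise genetic similarity, individual heterozygosity, p-distance
    neighbor-joining trees with bootstrap, genotype PCA) and a simulator
    for genomes, gene models, inbred founder populations and
    backcross-selfing pedigrees used to validate every component.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
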