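Package: mhctyper
Title: MHC Genotyping from Mapped NGS Reads via Phased Haplotype Contigs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Types major histocompatibility complex (MHC) genes of non-human
    species from mapped next-generation sequencing reads. The pipeline removes
    reads that align better to paralogous genes than to the target gene
    (bit-score comparison against allele references), calls diploid variants
    over the target region, phases heterozygous calls into haplotype blocks by
    minimum error correction, builds per-block haplotype consensus contigs, and
    determines the allele pair whose summed local-alignment bit scores across
    blocks are maximal, reporting ambiguity groups of exon-identical alleles.
    Includes a seeded simulator of paralogous MHC-like gene families with
    planted diploid genotypes, and a genotype concordance evaluator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    vcfR,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
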