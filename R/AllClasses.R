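#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom Biostrings DNAStringSet DNAString reverseComplement
#' @useDynLib mhctyper, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Scoring parameters for local alignment and bit scores
#'
#' Holds the nucleotide scoring scheme (match/mismatch, affine gap costs) and
#' the Karlin-Altschul constants used to convert raw Smith-Waterman scores to
#' bit scores: \eqn{B = (\lambda S - \ln K)/\ln 2}. Defaults follow the stock
#' megablast-style nucleotide task (match +2, mismatch -3, gap open 5,
#' gap extend 2, lambda 0.625, K 0.41). \code{min_report_bits} is the floor
#' below which local hits are not reported (default 50 bits).
#'
#' @slot match positive integer match reward
#' @slot mismatch negative integer mismatch penalty
#' @slot gap_open non-negative integer gap opening cost
#' @slot gap_extend positive integer per-base gap extension cost
#' @slot lambda positive Karlin-Altschul lambda
#' @slot k_param positive Karlin-Altschul K
#' @slot min_report_bits non-negative reporting floor in bits
#' @exportClass ScoringParams
setClass("ScoringParams", representation(
  match = "integer", mismatch = "integer",
  gap_open = "integer", gap_extend = "integer",
  lambda = "numeric", k_param = "numeric", min_report_bits = "numeric"
))

setValidity("ScoringParams", function(object) {
  msg <- character()
  if (object@match <= 0L) msg <- c(msg, "match must be > 0")
  if (object@mismatch >= 0L) msg <- c(msg, "mismatch must be < 0")
  if (object@gap_extend < 1L) msg <- c(msg, "gap_extend must be >= 1")
  if (object@gap_open < object@gap_extend)
    msg <- c(msg, "gap_open must be >= gap_extend")
  if (object@lambda <= 0) msg <- c(msg, "lambda must be > 0")
  if (object@k_param <= 0) msg <- c(msg, "k_param must be > 0")
  if (object@min_report_bits < 0) msg <- c(msg, "min_report_bits must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param match,mismatch,gap_open,gap_extend integer scoring scheme
#' @param lambda,k_param Karlin-Altschul constants
#' @param min_report_bits reporting floor in bits
#' @return A \code{ScoringParams} object.
#' @rdname ScoringParams-class
#' @export
scoringParams <- function(match = 2L, mismatch = -3L, gap_open = 5L,
                          gap_extend = 2L, lambda = 0.625, k_param = 0.41,
                          min_report_bits = 50) {
  new("ScoringParams", match = as.integer(match), mismatch = as.integer(mismatch),
      gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
      lambda = lambda, k_param = k_param, min_report_bits = min_report_bits)
}

#' Target-region and paralog configuration
#'
#' One exon interval per row of \code{regions} (a \code{GRanges} with metadata
#' columns \code{gene} and \code{exon}); \code{paralogs} maps each gene to the
#' genes whose alleles serve as off-target references during read filtering;
#' \code{exonLabels} gives the ordered expected exon labels per gene.
#'
#' @slot regions GRanges of exon intervals (mcols: gene, exon)
#' @slot paralogs named list, gene -> character vector of other genes
#' @slot exonLabels named list, gene -> ordered exon labels
#' @exportClass MhcTargets
setClass("MhcTargets", representation(
  regions = "GRanges", paralogs = "list", exonLabels = "list"
))

setValidity("MhcTargets", function(object) {
  msg <- character()
  genes <- unique(mcols(object@regions)$gene)
  if (is.null(mcols(object@regions)$gene) || is.null(mcols(object@regions)$exon))
    return("regions must carry mcols 'gene' and 'exon'")
  for (g in genes) {
    r <- object@regions[mcols(object@regions)$gene == g]
    s <- start(r)[order(start(r))]
    e <- end(r)[order(start(r))]
    if (any(e < s)) msg <- c(msg, sprintf("gene %s: empty exon interval", g))
    if (length(s) > 1 && any(s[-1] <= e[-length(e)]))
      msg <- c(msg, sprintf("gene %s: overlapping exon intervals", g))
    if (length(unique(as.character(seqnames(r)))) != 1)
      msg <- c(msg, sprintf("gene %s: exons on multiple chromosomes", g))
  }
  for (g in names(object@paralogs)) {
    if (g %in% object@paralogs[[g]])
      msg <- c(msg, sprintf("gene %s is in its own paralog group", g))
  }
  if (length(msg)) msg else TRUE
})

#' Allele reference database
#'
#' Named, gene-grouped collection of MHC allele sequences. Sequences are the
#' exon-only (concatenated) allele references; \code{exons} records the span of
#' each exon within every sequence (1-based closed, tiling the sequence).
#'
#' @slot sequences DNAStringSet named by full allele names (GENE*fields)
#' @slot gene character, gene of each allele
#' @slot exons list of per-allele data.frames (exon, start, end)
#' @slot isComplete logical, TRUE when all expected exons came from the source
#' @slot donor character, donor allele used to patch missing exons (NA if none)
#' @slot paralogs named list, gene -> off-target gene set
#' @exportClass AlleleDb
setClass("AlleleDb", representation(
  sequences = "DNAStringSet", gene = "character", exons = "list",
  isComplete = "logical", donor = "character", paralogs = "list"
))

setValidity("AlleleDb", function(object) {
  msg <- character()
  nms <- names(object@sequences)
  n <- length(object@sequences)
  if (anyDuplicated(nms)) msg <- c(msg, "allele names must be globally unique")
  if (length(object@gene) != n || length(object@exons) != n ||
      length(object@isComplete) != n || length(object@donor) != n)
    msg <- c(msg, "per-allele slots must match the number of sequences")
  if (n && any(Biostrings::width(object@sequences) < 1L))
    msg <- c(msg, "allele sequences must be non-empty")
  pre <- sub("\\*.*$", "", nms)
  if (n && !all(pre == object@gene))
    msg <- c(msg, "gene must equal the allele-name prefix before '*'")
  for (i in seq_len(n)) {
    ex <- object@exons[[i]]
    if (nrow(ex)) {
      o <- order(ex$start)
      if (ex$start[o][1] != 1L ||
          ex$end[o][nrow(ex)] != Biostrings::width(object@sequences)[i] ||
          (nrow(ex) > 1 && any(ex$start[o][-1] != ex$end[o][-nrow(ex)] + 1L)))
        msg <- c(msg, sprintf("allele %s: exon spans must tile the sequence", nms[i]))
    }
  }
  for (g in names(object@paralogs)) {
    if (g %in% object@paralogs[[g]])
      msg <- c(msg, sprintf("gene %s is in its own paralog group", g))
    absent <- setdiff(object@paralogs[[g]], object@gene)
    if (length(absent))
      msg <- c(msg, sprintf("paralog group of %s names genes with no alleles: %s",
                            g, paste(absent, collapse = ",")))
  }
  if (length(msg)) msg else TRUE
})

#' Haplotype contigs for one gene
#'
#' Per-block phased consensus sequences. Block 0 with hap 0 is the
#' homozygous-consensus contig (reference plus homozygous-alt calls only);
#' blocks n >= 1 are phase sets (PS tag = leftmost variant position) with
#' haplotype contigs C_n^1 and C_n^2.
#'
#' @slot gene character(1)
#' @slot meta data.frame with columns block, hap, chrom, start, end, n_variants
#' @slot sequences DNAStringSet, one per row of meta
#' @slot applied list of per-contig data.frames (pos, ref_len, alt_len) of the
#'   variants substituted into each contig, for coordinate mapping
#' @exportClass HaplotypeContigs
setClass("HaplotypeContigs", representation(
  gene = "character", meta = "data.frame", sequences = "DNAStringSet",
  applied = "list"
))

setValidity("HaplotypeContigs", function(object) {
  if (nrow(object@meta) != length(object@sequences))
    return("meta and sequences must have equal length")
  if (length(object@applied) != length(object@sequences))
    return("applied must have one element per contig")
  need <- c("block", "hap", "chrom", "start", "end", "n_variants")
  if (!all(need %in% names(object@meta)))
    return(paste("meta must have columns", paste(need, collapse = ", ")))
  TRUE
})

#' A two-allele genotype call with ambiguity groups
#'
#' Allele 1 and Allele 2 of the typed gene, each as an ambiguity group
#' (reference alleles tied on rounded total bit score, typically because they
#' are identical over the typed exons), with the total bit scores and
#' alignment-length-weighted average percent identities of the winning
#' assignments.
#'
#' @slot gene character(1)
#' @slot allele1Group,allele2Group sorted character vectors of allele names
#' @slot totalBits1,totalBits2 numeric totals over haplotype blocks
#' @slot avgPident1,avgPident2 weighted mean percent identity
#' @slot blocksUsed integer vector of block ids contributing to the call
#' @slot homozygousByConsensus logical, TRUE when both rounds used only block 0
#' @slot contigList data.frame, the per-(allele, block) Contig List
#' @exportClass GenotypeCall
setClass("GenotypeCall", representation(
  gene = "character", allele1Group = "character", totalBits1 = "numeric",
  avgPident1 = "numeric", allele2Group = "character", totalBits2 = "numeric",
  avgPident2 = "numeric", blocksUsed = "integer",
  homozygousByConsensus = "logical", contigList = "data.frame"
))

setValidity("GenotypeCall", function(object) {
  msg <- character()
  if (!length(object@allele1Group) || !length(object@allele2Group))
    msg <- c(msg, "allele groups must be non-empty")
  if (is.unsorted(object@allele1Group) || is.unsorted(object@allele2Group))
    msg <- c(msg, "allele groups must be sorted by name")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated MHC-like gene family
#'
#' Everything the simulator planted: the reference genome holding the
#' paralogous loci, the target/paralog configuration, the allele reference
#' database, the planted diploid genotype, the two haplotype genome sequences,
#' and the table of true variant positions.
#'
#' @slot genome DNAStringSet of one chromosome
#' @slot targets MhcTargets
#' @slot db AlleleDb
#' @slot genotype named list, gene -> character(2) planted allele pair
#' @slot haplotypes DNAStringSet of the two haplotype genomes
#' @slot truthVariants data.frame (chrom, pos, ref, hap1, hap2, gene)
#' @slot spec list, the simulation parameters as realized
#' @exportClass SimTruth
setClass("SimTruth", representation(
  genome = "DNAStringSet", targets = "MhcTargets", db = "AlleleDb",
  genotype = "list", haplotypes = "DNAStringSet",
  truthVariants = "data.frame", spec = "list"
))

setMethod("show", "ScoringParams", function(object) {
  cat(sprintf(
    "ScoringParams: match %+d mismatch %+d gap %d/%d lambda %.3f K %.3f floor %.1f bits\n",
    object@match, object@mismatch, object@gap_open, object@gap_extend,
    object@lambda, object@k_param, object@min_report_bits))
})

setMethod("show", "MhcTargets", function(object) {
  genes <- unique(mcols(object@regions)$gene)
  cat(sprintf("MhcTargets: %d gene(s) [%s], %d exon interval(s)\n",
              length(genes), paste(genes, collapse = ", "),
              length(object@regions)))
})

setMethod("show", "AlleleDb", function(object) {
  tab <- table(object@gene)
  cat(sprintf("AlleleDb: %d allele(s) across %d gene(s)\n",
              length(object@sequences), length(tab)))
  for (g in names(tab)) cat(sprintf("  %s: %d\n", g, tab[[g]]))
})

setMethod("show", "HaplotypeContigs", function(object) {
  cat(sprintf("HaplotypeContigs for %s: %d contig(s), %d het block(s)\n",
              object@gene, nrow(object@meta),
              length(unique(object@meta$block[object@meta$block > 0]))))
})

setMethod("show", "GenotypeCall", function(object) {
  cat(sprintf("GenotypeCall %s\n  Allele 1: %s (%.1f bits, %.2f%% id)\n  Allele 2: %s (%.1f bits, %.2f%% id)\n",
              object@gene,
              paste(object@allele1Group, collapse = " or "), object@totalBits1,
              object@avgPident1,
              paste(object@allele2Group, collapse = " or "), object@totalBits2,
              object@avgPident2))
  if (object@homozygousByConsensus)
    cat("  homozygous call via consensus contig\n")
})

setMethod("show", "SimTruth", function(object) {
  cat(sprintf("SimTruth: %d paralog(s), genome %d bp, %d allele(s), %d true variant(s)\n",
              length(targetGenes(object@targets)),
              sum(Biostrings::width(object@genome)),
              length(object@db@sequences), nrow(object@truthVariants)))
})
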