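# Mapped reads travel through the pipeline as a plain data.frame with columns
#   read_id, flag, chrom, pos (1-based leftmost), mapq, cigar, seq, qual
# plus optional rnext/pnext/tlen and simulation provenance columns
# (origin_gene, origin_hap). Helper predicates decode the FLAG field.

#' @importFrom GenomicAlignments cigarWidthAlongReferenceSpace
#'   cigarRangesAlongReferenceSpace cigarRangesAlongQuerySpace
#'   explodeCigarOps explodeCigarOpLengths
NULL

flagPaired <- function(flag) bitwAnd(flag, 1L) != 0L
flagReverse <- function(flag) bitwAnd(flag, 16L) != 0L
flagFirstOfPair <- function(flag) bitwAnd(flag, 64L) != 0L
flagSecondary <- function(flag) bitwAnd(flag, 256L) != 0L
flagDuplicate <- function(flag) bitwAnd(flag, 1024L) != 0L
flagSupplementary <- function(flag) bitwAnd(flag, 2048L) != 0L

#' Is an alignment record a primary, non-duplicate alignment?
#' @param flag integer SAM FLAG value(s)
#' @return logical
#' @export
isPrimaryRecord <- function(flag) {
  !flagSecondary(flag) & !flagSupplementary(flag) & !flagDuplicate(flag)
}

# unique fragment-end key: qname alone collides for mates
.read_uid <- function(reads) {
  mate <- ifelse(flagPaired(reads$flag) & !flagFirstOfPair(reads$flag), "/2", "/1")
  paste0(reads$read_id, mate)
}

#' Reference span end of each alignment record
#' @param reads read data.frame
#' @return integer vector of rightmost aligned reference positions
#' @export
readRefEnd <- function(reads) {
  if (!nrow(reads)) return(integer(0))
  reads$pos + cigarWidthAlongReferenceSpace(reads$cigar) - 1L
}

#' Read mapped reads from a SAM or BAM file
#'
#' SAM text is converted through \code{Rsamtools::asBam} first; the whole file
#' is loaded (target regions in this pipeline are small) and can be subset
#' with \code{\link{subsetReads}}.
#'
#' @param path .sam or .bam file
#' @return read data.frame (see package overview)
#' @export
readAlignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
  }
  b <- Rsamtools::scanBam(Rsamtools::BamFile(path), param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual")))[[1]]
  keep <- !is.na(b$pos)
  data.frame(read_id = b$qname[keep], flag = b$flag[keep],
             chrom = as.character(b$rname)[keep], pos = b$pos[keep],
             mapq = b$mapq[keep], cigar = b$cigar[keep],
             seq = as.character(b$seq)[keep], qual = as.character(b$qual)[keep],
             stringsAsFactors = FALSE)
}

#' Subset reads overlapping an interval
#' @param reads read data.frame
#' @param chrom chromosome
#' @param start,end 1-based closed interval
#' @return read data.frame
#' @export
subsetReads <- function(reads, chrom, start, end) {
  if (!nrow(reads)) return(reads)
  keep <- reads$chrom == chrom & reads$pos <= end & readRefEnd(reads) >= start
  reads[keep, , drop = FALSE]
}

#' Write reads as SAM text (optionally converting to BAM)
#'
#' @param reads read data.frame
#' @param chrom_lengths named integer vector for the \code{@SQ} header lines
#' @param path output path; \code{.bam} suffix triggers conversion through
#'   \code{Rsamtools::asBam}
#' @param sort_reads coordinate-sort before writing
#' @return invisibly, the path written
#' @export
writeSam <- function(reads, chrom_lengths, path, sort_reads = TRUE) {
  if (sort_reads && nrow(reads))
    reads <- reads[order(reads$chrom, reads$pos), , drop = FALSE]
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  rnext <- if ("rnext" %in% names(reads)) reads$rnext else rep("*", nrow(reads))
  pnext <- if ("pnext" %in% names(reads)) reads$pnext else rep(0L, nrow(reads))
  tlen <- if ("tlen" %in% names(reads)) reads$tlen else rep(0L, nrow(reads))
  body <- if (nrow(reads)) {
    paste(reads$read_id, reads$flag, reads$chrom, reads$pos, reads$mapq,
          reads$cigar, rnext, pnext, tlen, reads$seq, reads$qual, sep = "\t")
  } else character(0)
  to_bam <- grepl("\\.bam$", path, ignore.case = TRUE)
  sam_path <- if (to_bam) tempfile(fileext = ".sam") else path
  writeLines(c(hdr, body), sam_path)
  if (to_bam) {
    Rsamtools::asBam(sam_path, sub("\\.bam$", "", path), overwrite = TRUE,
                     indexDestination = TRUE)
  }
  invisible(path)
}

# Per-record aligned blocks in reference and query space (M/=/X ops only),
# as parallel IRanges lists. Used by pileup, fragments and QC.
.aligned_blocks <- function(reads) {
  ops <- c("M", "=", "X")
  rr <- cigarRangesAlongReferenceSpace(reads$cigar, pos = reads$pos, ops = ops)
  qq <- cigarRangesAlongQuerySpace(reads$cigar, ops = ops)
  list(ref = rr, query = qq)
}
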