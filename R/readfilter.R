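#' Remove reads that score better against paralog alleles than target alleles
#'
#' For every primary, non-duplicate alignment record overlapping the target
#' gene's exon intervals, the read sequence (soft-clipped bases included) is
#' aligned against all target-gene alleles and all paralog-group alleles; the
#' read is removed when its best off-target bit score strictly exceeds its
#' best target bit score, or when it has no target hit at or above
#' \code{min_report_bits} while an off-target hit exists. Ties are kept.
#' Secondary/supplementary/duplicate records follow their primary's fate.
#' Reads with no hit to either side are kept and flagged. Reads that do not
#' overlap any target exon interval (within \code{screen_margin} bp) are not
#' aligned at all: the allele references are exon-only, so such reads cannot
#' reach the reporting floor; they are kept and flagged as unscored.
#'
#' @param reads read data.frame (see \code{\link{readAlignments}})
#' @param db \code{\link{AlleleDb}}
#' @param target_gene gene being typed
#' @param targets optional \code{\link{MhcTargets}}; enables exon-overlap
#'   screening
#' @param params \code{\link{ScoringParams}}
#' @param drop_pairs also remove the kept mate of a removed read
#' @param screen_margin bp of slack around exon intervals for screening
#' @return list with \code{kept} (read data.frame, input order preserved) and
#'   \code{decisions} (one row per primary record: read_id, mate, kept,
#'   best_target_bits, best_offtarget_bits, best_offtarget_gene, reason, note)
#' @export
filterReads <- function(reads, db, target_gene, targets = NULL,
                        params = scoringParams(), drop_pairs = FALSE,
                        screen_margin = 30L) {
  if (!target_gene %in% names(db@paralogs) && !target_gene %in% db@gene)
    stop("unknown target gene: ", target_gene)
  tseq <- as.character(db@sequences[db@gene == target_gene])
  if (!length(tseq)) stop("no reference alleles for target gene ", target_gene)
  pgenes <- db@paralogs[[target_gene]]
  if (is.null(pgenes)) pgenes <- character(0)
  oseq <- as.character(db@sequences[db@gene %in% pgenes])
  ogene <- db@gene[db@gene %in% pgenes]
  subjects <- c(tseq, oseq)
  is_target <- c(rep(TRUE, length(tseq)), rep(FALSE, length(oseq)))

  in_scope <- rep(TRUE, nrow(reads))
  if (!is.null(targets)) {
    ex <- exonRegions(targets, target_gene)
    ends <- readRefEnd(reads)
    in_scope <- rep(FALSE, nrow(reads))
    for (k in seq_along(ex)) {
      in_scope <- in_scope |
        (reads$chrom == as.character(seqnames(ex))[k] &
           reads$pos <= end(ex)[k] + screen_margin &
           ends >= start(ex)[k] - screen_margin)
    }
  }

  uid <- .read_uid(reads)
  primary <- isPrimaryRecord(reads$flag)
  pidx <- which(primary & !duplicated(uid))
  dec <- data.frame(
    read_id = reads$read_id[pidx],
    mate = ifelse(flagPaired(reads$flag[pidx]) &
                    !flagFirstOfPair(reads$flag[pidx]), 2L, 1L),
    kept = TRUE, best_target_bits = 0, best_offtarget_bits = 0,
    best_offtarget_gene = NA_character_, reason = "kept", note = "",
    stringsAsFactors = FALSE)

  for (k in seq_along(pidx)) {
    i <- pidx[k]
    if (!in_scope[i]) { dec$note[k] <- "not_scored_no_exon_overlap"; next }
    bits <- bestHitBits(reads$seq[i], subjects, params)
    bt <- if (any(is_target)) max(bits[is_target]) else 0
    bo <- if (any(!is_target)) max(bits[!is_target]) else 0
    dec$best_target_bits[k] <- bt
    dec$best_offtarget_bits[k] <- bo
    if (bo > 0)
      dec$best_offtarget_gene[k] <- ogene[which.max(bits[!is_target])]
    if (bo > bt && bt > 0) {
      dec$kept[k] <- FALSE; dec$reason[k] <- "offtarget_better"
    } else if (bt == 0 && bo > 0) {
      dec$kept[k] <- FALSE; dec$reason[k] <- "no_target_hit"
    } else if (bt == 0 && bo == 0) {
      dec$note[k] <- "no_hit_either_side"
    }
  }

  fate <- stats::setNames(dec$kept, uid[pidx])
  keep_record <- fate[uid]
  keep_record[is.na(keep_record)] <- TRUE  # records with no primary: keep
  if (drop_pairs) {
    dropped_q <- unique(reads$read_id[!keep_record])
    keep_record <- keep_record & !(reads$read_id %in% dropped_q)
  }
  list(kept = reads[keep_record, , drop = FALSE], decisions = dec)
}

#' Write a read-filter decision log as TSV
#' @param decisions decision data.frame from \code{\link{filterReads}}
#' @param path output file
#' @return invisibly, the path
#' @export
writeFilterLog <- function(decisions, path) {
  utils::write.table(decisions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Mapping-quality metrics over target intervals
#'
#' Per interval: number of primary non-duplicate reads overlapping by at
#' least one base, mean per-base depth of aligned bases over the interval
#' length, breadth of coverage (percent of positions with depth >= 1), mean
#' MAPQ of the counted reads, and mean Phred base quality of the aligned
#' bases falling inside the interval.
#'
#' @param reads read data.frame
#' @param intervals GRanges of target intervals (one chromosome)
#' @return data.frame: chrom, start, end, exon (if present in mcols),
#'   n_reads, mean_depth, breadth, mean_mapq, mean_baseq
#' @export
regionQC <- function(reads, intervals) {
  if (any(width(intervals) < 1L)) stop("empty interval in QC request")
  if (length(unique(as.character(seqnames(intervals)))) > 1L)
    stop("QC intervals must be on one chromosome")
  chrom <- as.character(seqnames(intervals))[1]
  rs <- reads[isPrimaryRecord(reads$flag) & reads$chrom == chrom, , drop = FALSE]
  ends <- readRefEnd(rs)
  blocks <- if (nrow(rs)) .aligned_blocks(rs) else NULL
  out <- lapply(seq_along(intervals), function(k) {
    s <- start(intervals)[k]; e <- end(intervals)[k]
    ov <- which(rs$pos <= e & ends >= s)
    cov <- integer(e - s + 1L)
    qsum <- 0; qn <- 0L
    for (i in ov) {
      rr <- blocks$ref[[i]]; qq <- blocks$query[[i]]
      for (j in seq_along(rr)) {
        is <- max(start(rr)[j], s); ie <- min(end(rr)[j], e)
        if (is > ie) next
        cov[(is - s + 1L):(ie - s + 1L)] <- cov[(is - s + 1L):(ie - s + 1L)] + 1L
        q0 <- start(qq)[j] + (is - start(rr)[j])
        quals <- utf8ToInt(substr(rs$qual[i], q0, q0 + (ie - is))) - 33L
        qsum <- qsum + sum(quals); qn <- qn + length(quals)
      }
    }
    data.frame(
      chrom = chrom, start = s, end = e,
      exon = if (!is.null(mcols(intervals)$exon)) mcols(intervals)$exon[k]
             else NA_character_,
      n_reads = length(ov), mean_depth = sum(cov) / length(cov),
      breadth = 100 * mean(cov >= 1L),
      mean_mapq = if (length(ov)) mean(rs$mapq[ov]) else NA_real_,
      mean_baseq = if (qn) qsum / qn else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
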