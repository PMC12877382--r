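#' Build haplotype contigs from phased calls
#'
#' For each phased block overlapping the target gene's exon envelope, two
#' contigs C_n^1 and C_n^2 are built over the span
#' \code{[block_start - flank, block_end + flank]} (clipped to the envelope
#' +/- flank and to the chromosome): the reference substring with the block's
#' haplotype-specific alleles and every homozygous-alt call in the span
#' substituted left-to-right, later coordinates shifted by earlier indels.
#' One homozygous-consensus contig (block 0, hap 0) spanning the full
#' envelope +/- flank carries only the homozygous-alt calls; it types fully
#' homozygous samples and exons no het block reaches. If a block's two
#' haplotype sequences come out identical a single contig is emitted with a
#' warning.
#'
#' @param phased_calls variant call data.frame with phasing columns
#'   (\code{\link{phaseVariants}} or \code{\link{readVcfCalls}})
#' @param genome DNAStringSet reference
#' @param targets \code{\link{MhcTargets}}
#' @param gene target gene
#' @param flank flank length in bp (default 200)
#' @return \code{\link{HaplotypeContigs}}
#' @export
buildContigs <- function(phased_calls, genome, targets, gene, flank = 200L) {
  env <- geneEnvelope(targets, gene)
  chrom <- as.character(seqnames(env))
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  chrseq <- as.character(genome[[chrom]])
  chrlen <- nchar(chrseq)
  lo_lim <- max(1L, start(env) - flank)
  hi_lim <- min(chrlen, end(env) + flank)

  calls <- phased_calls[phased_calls$chrom == chrom, , drop = FALSE]
  # verify REF matches the genome
  for (i in seq_len(nrow(calls))) {
    obs <- substr(chrseq, calls$pos[i], calls$pos[i] + nchar(calls$ref[i]) - 1L)
    if (obs != calls$ref[i])
      stop(sprintf("variant REF mismatch at %s:%d (VCF %s, genome %s)",
                   chrom, calls$pos[i], calls$ref[i], obs))
  }
  alt_list <- strsplit(calls$alt, ",")
  allele_seq <- function(i, idx) {
    if (idx == 0L) calls$ref[i] else alt_list[[i]][idx]
  }
  hom_alt <- !calls$phased &
    vapply(strsplit(calls$gt, "/"), function(g)
      g[1] == g[2] && g[1] != "0", logical(1))

  apply_variants <- function(span_lo, span_hi, rows, allele_of) {
    idx <- rows[calls$pos[rows] >= span_lo &
                  calls$pos[rows] + nchar(calls$ref[rows]) - 1L <= span_hi]
    idx <- idx[order(calls$pos[idx])]
    if (length(idx) > 1) {
      ref_end <- calls$pos[idx] + nchar(calls$ref[idx]) - 1L
      if (any(calls$pos[idx][-1] <= ref_end[-length(idx)]))
        stop("overlapping variants within one haplotype in span ",
             span_lo, "-", span_hi)
    }
    seqs <- character(0); cursor <- span_lo
    n_app <- 0L
    for (i in idx) {
      a <- allele_of(i)
      if (is.na(a)) next
      s <- allele_seq(i, a)
      if (s == calls$ref[i]) next
      seqs <- c(seqs, substr(chrseq, cursor, calls$pos[i] - 1L), s)
      cursor <- calls$pos[i] + nchar(calls$ref[i])
      n_app <- n_app + 1L
    }
    seqs <- c(seqs, substr(chrseq, cursor, span_hi))
    app <- data.frame(pos = calls$pos[idx], ref_len = nchar(calls$ref[idx]),
                      alt_len = nchar(calls$ref[idx]), stringsAsFactors = FALSE)
    used <- logical(length(idx)); k <- 0L
    for (i in idx) {  # record realized alt lengths for coordinate mapping
      k <- k + 1L
      a <- allele_of(i)
      if (is.na(a)) next
      s <- allele_seq(i, a)
      if (s == calls$ref[i]) next
      app$alt_len[k] <- nchar(s); used[k] <- TRUE
    }
    list(seq = paste(seqs, collapse = ""), n = n_app,
         applied = app[used, , drop = FALSE])
  }

  meta <- list(); seqs <- character(0); applied <- list()
  add <- function(block, hap, s, e, built) {
    meta[[length(meta) + 1L]] <<- data.frame(
      block = block, hap = hap, chrom = chrom, start = s, end = e,
      n_variants = built$n, stringsAsFactors = FALSE)
    seqs <<- c(seqs, built$seq)
    applied[[length(applied) + 1L]] <<- built$applied
  }

  # consensus contig: envelope +/- flank, homozygous-alt calls only
  add(0L, 0L, lo_lim, hi_lim,
      apply_variants(lo_lim, hi_lim, which(hom_alt),
                     function(i) as.integer(strsplit(calls$gt[i], "/")[[1]][1])))

  ph <- which(calls$phased)
  for (ps in sort(unique(calls$ps[ph]))) {
    rows <- ph[calls$ps[ph] == ps]
    b_lo <- min(calls$pos[rows]); b_hi <- max(calls$pos[rows] +
                                                nchar(calls$ref[rows]) - 1L)
    if (b_hi < start(env) - flank || b_lo > end(env) + flank) next
    span_lo <- max(b_lo - flank, lo_lim, 1L)
    span_hi <- min(b_hi + flank, hi_lim, chrlen)
    rows_all <- c(rows, which(hom_alt))
    b1 <- apply_variants(span_lo, span_hi, rows_all, function(i)
      if (calls$phased[i]) calls$hap1[i] else
        as.integer(strsplit(calls$gt[i], "/")[[1]][1]))
    b2 <- apply_variants(span_lo, span_hi, rows_all, function(i)
      if (calls$phased[i]) calls$hap2[i] else
        as.integer(strsplit(calls$gt[i], "/")[[1]][1]))
    if (b1$seq == b2$seq) {
      warning("block ", ps, ": haplotype sequences identical; emitting one contig")
      add(as.integer(ps), 1L, span_lo, span_hi, b1)
    } else {
      add(as.integer(ps), 1L, span_lo, span_hi, b1)
      add(as.integer(ps), 2L, span_lo, span_hi, b2)
    }
  }

  meta <- do.call(rbind, meta)
  ss <- DNAStringSet(seqs)
  names(ss) <- sprintf("%s|block=%d|hap=%d|%s:%d-%d", gene, meta$block,
                       meta$hap, meta$chrom, meta$start, meta$end)
  new("HaplotypeContigs", gene = gene, meta = meta, sequences = ss,
      applied = applied)
}

#' Write haplotype contigs to FASTA
#'
#' Headers follow \code{>gene|block=PS|hap=h|chrom:start-end} with 1-based
#' inclusive coordinates.
#'
#' @param contigs \code{\link{HaplotypeContigs}}
#' @param path output FASTA (default \code{output.contig.fa})
#' @return invisibly, the path
#' @export
writeContigFasta <- function(contigs, path = "output.contig.fa") {
  if (!length(contigs@sequences)) stop("no contigs to write")
  Biostrings::writeXStringSet(contigs@sequences, path)
  invisible(path)
}
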