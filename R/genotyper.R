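# Allele determination: score haplotype contigs against the target gene's
# allele references, build the Contig List, and call Allele 1 / Allele 2 by
# total bit score across blocks in two rounds.

# map a genomic position to an offset within a contig, accounting for the
# net indel shift of variants applied before it
.genomic_to_contig <- function(contig_start, applied, g) {
  shift <- 0L
  if (nrow(applied)) {
    before <- applied$pos + applied$ref_len - 1L < g
    shift <- sum(applied$alt_len[before] - applied$ref_len[before])
  }
  g - contig_start + 1L + shift
}

.score_one <- function(qseq, sseq, params, score_mode) {
  if (score_mode == "chained") {
    ch <- hspChain(qseq, sseq, params)
    list(bits = ch$total_bits, pident = ch$weighted_pident,
         n_ident = ch$n_ident, aln_len = ch$aln_len)
  } else {
    a <- alignLocal(qseq, sseq, params)
    bits <- if (a$bit_score >= params@min_report_bits) a$bit_score else 0
    list(bits = bits, pident = if (bits > 0) a$pident else 0,
         n_ident = if (bits > 0) a$n_ident else 0L,
         aln_len = if (bits > 0) a$aln_len else 0L)
  }
}

# consensus sub-sequences for the exon intervals not reached by any het block
.consensus_pieces <- function(contigs, targets, gene, flank) {
  meta <- contigs@meta
  ci <- which(meta$block == 0L)
  if (!length(ci)) return(character(0))
  het <- meta[meta$block > 0L, , drop = FALSE]
  ex <- exonRegions(targets, gene)
  covered <- vapply(seq_along(ex), function(k) {
    any(het$start <= end(ex)[k] & het$end >= start(ex)[k])
  }, logical(1))
  if (all(covered)) return(character(0))
  cs <- as.character(contigs@sequences[[ci]])
  c_start <- meta$start[ci]; c_end <- meta$end[ci]
  app <- contigs@applied[[ci]]
  vapply(which(!covered), function(k) {
    g_lo <- max(start(ex)[k] - flank, c_start)
    g_hi <- min(end(ex)[k] + flank, c_end)
    substr(cs, .genomic_to_contig(c_start, app, g_lo),
           .genomic_to_contig(c_start, app, g_hi))
  }, character(1))
}

#' Score contigs against allele references and build the Contig List
#'
#' For every reference allele of the target gene and every het haplotype
#' block, the block's contig with the higher score (summed co-linear HSP bit
#' score by default) is recorded with its bit score and percent identity;
#' ties between the two haplotype contigs go to haplotype 1 and are flagged.
#' The block-0 consensus contributes one entry per allele covering only the
#' exon intervals that no het block reaches (the homozygous remainder), so a
#' fully homozygous sample is typed entirely from block 0.
#'
#' @param contigs \code{\link{HaplotypeContigs}}
#' @param db \code{\link{AlleleDb}}
#' @param gene target gene
#' @param params \code{\link{ScoringParams}}
#' @param score_mode "chained" (summed co-linear HSPs) or "best_hsp"
#' @param targets \code{\link{MhcTargets}} (exon intervals for the consensus
#'   remainder)
#' @param flank flank used when trimming the consensus (match the contig
#'   builder's)
#' @return data.frame (allele, block, hap, bits, pident, n_ident, aln_len,
#'   tie) with attribute \code{scores}: the full per-haplotype score table
#'   consumed by \code{\link{callGenotype}}
#' @export
buildContigList <- function(contigs, db, gene, params = scoringParams(),
                            score_mode = c("chained", "best_hsp"),
                            targets = NULL, flank = 200L) {
  score_mode <- match.arg(score_mode)
  if (!gene %in% db@gene) stop("gene absent from allele database: ", gene)
  alleles <- sort(names(db@sequences)[db@gene == gene])
  aseq <- as.character(db@sequences[alleles])
  meta <- contigs@meta
  het_blocks <- sort(unique(meta$block[meta$block > 0L]))

  scores <- list()
  for (b in het_blocks) {
    rows <- which(meta$block == b)
    for (ri in rows) {
      qseq <- as.character(contigs@sequences[[ri]])
      for (a in alleles) {
        sc <- .score_one(qseq, aseq[[a]], params, score_mode)
        scores[[length(scores) + 1L]] <- data.frame(
          allele = a, block = b, hap = meta$hap[ri], bits = sc$bits,
          pident = sc$pident, n_ident = sc$n_ident, aln_len = sc$aln_len,
          stringsAsFactors = FALSE)
      }
    }
  }

  pieces <- if (!is.null(targets)) .consensus_pieces(contigs, targets, gene, flank)
            else if (length(het_blocks) == 0L && any(meta$block == 0L))
              as.character(contigs@sequences[meta$block == 0L])
            else character(0)
  if (length(pieces)) {
    for (a in alleles) {
      parts <- lapply(pieces, .score_one, sseq = aseq[[a]], params = params,
                      score_mode = score_mode)
      ni <- sum(vapply(parts, `[[`, integer(1), "n_ident"))
      al <- sum(vapply(parts, `[[`, integer(1), "aln_len"))
      scores[[length(scores) + 1L]] <- data.frame(
        allele = a, block = 0L, hap = 0L,
        bits = sum(vapply(parts, `[[`, numeric(1), "bits")),
        pident = if (al > 0) 100 * ni / al else 0,
        n_ident = ni, aln_len = al, stringsAsFactors = FALSE)
    }
  }
  scores <- if (length(scores)) do.call(rbind, scores) else
    data.frame(allele = character(), block = integer(), hap = integer(),
               bits = numeric(), pident = numeric(), n_ident = integer(),
               aln_len = integer(), stringsAsFactors = FALSE)

  # Contig List: per (allele, block) the best contig, ties toward hap 1
  entries <- list()
  for (a in alleles) {
    for (b in unique(scores$block)) {
      sub <- scores[scores$allele == a & scores$block == b, , drop = FALSE]
      if (!nrow(sub)) next
      sub <- sub[order(sub$hap), , drop = FALSE]
      best <- which.max(round(sub$bits, 2))  # first max = lowest hap
      tie <- sum(abs(round(sub$bits, 2) - round(sub$bits[best], 2)) < 1e-9) > 1
      e <- sub[best, , drop = FALSE]
      e$tie <- tie
      entries[[length(entries) + 1L]] <- e
    }
  }
  entries <- if (length(entries)) do.call(rbind, entries) else
    cbind(scores, tie = logical(0))
  rownames(entries) <- NULL
  attr(entries, "scores") <- scores
  attr(entries, "block_haps") <- {
    hb <- meta[meta$block > 0L, c("block", "hap")]
    split(hb$hap, hb$block)
  }
  entries
}

#' Two-round allele-pair determination by total bit score
#'
#' Round 1 sums, per allele, the Contig List bit scores across blocks; the
#' argmax set (totals compared after rounding to 2 decimals) is the Allele 1
#' ambiguity group. Round 2 removes, per het block, the contig consumed by
#' the group's lexicographically smallest member and repeats the sum over the
#' remaining contigs; single-contig blocks and the block-0 consensus remain
#' available to both rounds, which is what makes homozygous samples typable.
#' Average percent identity is the alignment-length-weighted identity of the
#' representative's scoring entries.
#'
#' @param entries Contig List from \code{\link{buildContigList}}
#' @param db \code{\link{AlleleDb}}
#' @param gene target gene
#' @return \code{\link{GenotypeCall}}
#' @export
callGenotype <- function(entries, db, gene) {
  scores <- attr(entries, "scores")
  if (is.null(scores)) stop("entries must come from buildContigList()")
  if (!nrow(scores)) stop("no typable sequence in target region")
  alleles <- sort(unique(scores$allele))
  blocks <- sort(unique(scores$block))
  het_blocks <- blocks[blocks > 0L]

  tot1 <- vapply(alleles, function(a)
    sum(entries$bits[entries$allele == a]), numeric(1))
  r1 <- round(tot1, 2)
  g1 <- sort(alleles[r1 == max(r1)])
  rep1 <- g1[1]
  # Tied alleles that explain DIFFERENT haplotype contigs are alternative
  # genotype components (the other haplotype's allele), not ambiguous
  # identities: keep only the representative's contig-choice cohort in the
  # ambiguity group. Exon-identical alleles always choose the same contigs.
  if (length(g1) > 1L && length(het_blocks)) {
    chosen_of <- function(a) {
      rows <- entries[entries$allele == a & entries$block > 0L, , drop = FALSE]
      rows$hap[match(het_blocks, rows$block)]
    }
    ref_choice <- chosen_of(rep1)
    g1 <- g1[vapply(g1, function(a) identical(chosen_of(a), ref_choice),
                    logical(1))]
  }
  rep1_rows <- entries[entries$allele == rep1, , drop = FALSE]
  wp <- function(rows) {
    al <- sum(rows$aln_len)
    if (al > 0) 100 * sum(rows$n_ident) / al else 0
  }

  consumed <- stats::setNames(rep1_rows$hap[match(het_blocks, rep1_rows$block)],
                              het_blocks)
  tot2 <- vapply(alleles, function(a) {
    s <- 0
    for (b in het_blocks) {
      haps <- unique(scores$hap[scores$block == b])
      use_hap <- if (length(haps) > 1L) setdiff(haps, consumed[[as.character(b)]])
                 else haps
      row <- scores[scores$allele == a & scores$block == b &
                      scores$hap == use_hap[1], , drop = FALSE]
      if (nrow(row)) s <- s + row$bits
    }
    c0 <- scores[scores$allele == a & scores$block == 0L, , drop = FALSE]
    if (nrow(c0)) s <- s + c0$bits
    s
  }, numeric(1))
  r2 <- round(tot2, 2)
  g2 <- sort(alleles[r2 == max(r2)])
  rep2 <- g2[1]
  rep2_rows <- do.call(rbind, c(
    lapply(het_blocks, function(b) {
      haps <- unique(scores$hap[scores$block == b])
      use_hap <- if (length(haps) > 1L) setdiff(haps, consumed[[as.character(b)]])
                 else haps
      scores[scores$allele == rep2 & scores$block == b &
               scores$hap == use_hap[1], , drop = FALSE]
    }),
    list(scores[scores$allele == rep2 & scores$block == 0L, , drop = FALSE])))

  new("GenotypeCall", gene = gene,
      allele1Group = g1, totalBits1 = unname(tot1[rep1]),
      avgPident1 = wp(rep1_rows),
      allele2Group = g2, totalBits2 = unname(tot2[rep2]),
      avgPident2 = wp(rep2_rows),
      blocksUsed = as.integer(blocks),
      homozygousByConsensus = length(het_blocks) == 0L,
      contigList = entries)
}

#' Score contigs and call the genotype in one step
#' @inheritParams buildContigList
#' @return \code{\link{GenotypeCall}}
#' @export
genotypeGene <- function(contigs, db, gene, params = scoringParams(),
                         score_mode = c("chained", "best_hsp"),
                         targets = NULL, flank = 200L) {
  if (!length(contigs@sequences)) stop("no typable sequence in target region")
  entries <- buildContigList(contigs, db, gene, params, score_mode, targets,
                             flank)
  callGenotype(entries, db, gene)
}

#' The set of alleles sharing an identical typed-exon sequence
#'
#' The expected ambiguity group of an allele: all alleles of the same gene
#' whose exon-concatenated reference sequences are identical to it.
#'
#' @param db \code{\link{AlleleDb}}
#' @param allele full allele name
#' @return sorted character vector (always contains \code{allele})
#' @export
ambiguityGroupOf <- function(db, allele) {
  i <- match(allele, names(db@sequences))
  if (is.na(i)) stop("unknown allele: ", allele)
  same_gene <- db@gene == db@gene[i]
  sort(names(db@sequences)[same_gene &
                             as.character(db@sequences) ==
                               as.character(db@sequences)[i]])
}

#' Write genotype calls as a TSV report
#'
#' One row per gene; ambiguity groups are joined with \code{" or "} exactly
#' as typing tables print them.
#'
#' @param calls list of \code{\link{GenotypeCall}}
#' @param path output file
#' @return invisibly, the path
#' @export
writeReport <- function(calls, path) {
  df <- data.frame(gene = character(), allele1 = character(),
                   total_bits_1 = numeric(), avg_pident_1 = numeric(),
                   allele2 = character(), total_bits_2 = numeric(),
                   avg_pident_2 = numeric(), n_blocks = integer(),
                   flags = character(), stringsAsFactors = FALSE)
  for (gc in calls) {
    df <- rbind(df, data.frame(
      gene = gc@gene,
      allele1 = paste(gc@allele1Group, collapse = " or "),
      total_bits_1 = round(gc@totalBits1, 2),
      avg_pident_1 = round(gc@avgPident1, 3),
      allele2 = paste(gc@allele2Group, collapse = " or "),
      total_bits_2 = round(gc@totalBits2, 2),
      avg_pident_2 = round(gc@avgPident2, 3),
      n_blocks = sum(gc@blocksUsed > 0L),
      flags = if (gc@homozygousByConsensus) "homozygous_by_consensus" else "",
      stringsAsFactors = FALSE))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
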