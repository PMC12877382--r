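#' Default variant-calling thresholds per mode
#'
#' Short-read mode uses base qualities and calls SNVs and CIGAR-derived
#' indels; long-read mode calls SNVs only, with no base-quality floor (noisy
#' long-read quality strings) and a slightly higher allele-fraction gate.
#'
#' @param mode "short" or "long"
#' @return list of thresholds (min_mapq, min_baseq, min_ad, min_af, het_af,
#'   call_indels)
#' @export
callerThresholds <- function(mode = c("short", "long")) {
  mode <- match.arg(mode)
  if (mode == "short") {
    list(min_mapq = 20L, min_baseq = 13L, min_ad = 2L, min_af = 0.2,
         het_af = 0.2, call_indels = TRUE)
  } else {
    list(min_mapq = 20L, min_baseq = 0L, min_ad = 2L, min_af = 0.25,
         het_af = 0.2, call_indels = FALSE)
  }
}

.base_code <- c(A = 1L, C = 2L, G = 3L, T = 4L)

#' Pileup-based diploid variant calling over a target region
#'
#' Builds a per-position pileup from primary reads with MAPQ at or above
#' \code{min_mapq}, using bases with quality at or above \code{min_baseq}.
#' Candidate alternate alleles require depth >= \code{min_ad} and allele
#' fraction >= \code{min_af}. The genotype at a site takes the two
#' highest-count qualifying alleles: heterozygous when the minor fraction is
#' >= \code{het_af}, otherwise homozygous for the top allele. Positions where
#' the top allele is the reference and no alternate qualifies produce no
#' record (variant-only output). QUAL is \eqn{-10\log_{10}} of the binomial
#' tail probability of the minor allele count under a 1\% error rate
#' (informational only).
#'
#' @param reads read data.frame
#' @param genome DNAStringSet reference
#' @param region GRanges of the region to call (one range)
#' @param mode "short" (SNVs + indels) or "long" (SNVs only)
#' @param thresholds list from \code{\link{callerThresholds}}; any element can
#'   be overridden
#' @return data.frame: chrom, pos, ref, alt (comma-separated), gt (unphased
#'   "a/b"), ad (comma-separated per-allele depths), dp, qual
#' @export
callVariants <- function(reads, genome, region, mode = c("short", "long"),
                         thresholds = list()) {
  mode <- match.arg(mode)
  th <- utils::modifyList(callerThresholds(mode), thresholds)
  chrom <- as.character(seqnames(region))[1]
  if (!chrom %in% names(genome)) stop("region chromosome not in genome: ", chrom)
  rs <- start(region)[1]; re <- end(region)[1]
  chrlen <- Biostrings::width(genome)[match(chrom, names(genome))]
  if (rs < 1L || re > chrlen) stop("region outside chromosome bounds")
  refseq <- substr(as.character(genome[[chrom]]), rs, re)
  L <- re - rs + 1L
  ref_codes <- .base_code[strsplit(refseq, "")[[1]]]

  reads <- reads[isPrimaryRecord(reads$flag) & reads$mapq >= th$min_mapq &
                   reads$chrom == chrom, , drop = FALSE]
  reads <- subsetReads(reads, chrom, rs, re)

  counts <- matrix(0L, nrow = L, ncol = 4L)
  indel_counts <- new.env(parent = emptyenv())
  if (nrow(reads)) {
    ops_all <- explodeCigarOps(reads$cigar)
    lens_all <- explodeCigarOpLengths(reads$cigar)
    for (i in seq_len(nrow(reads))) {
      ops <- ops_all[[i]]; lens <- lens_all[[i]]
      rpos <- reads$pos[i]; qpos <- 1L
      bases <- strsplit(reads$seq[i], "")[[1]]
      quals <- utf8ToInt(reads$qual[i]) - 33L
      for (j in seq_along(ops)) {
        op <- ops[j]; ln <- lens[j]
        if (op %in% c("M", "=", "X")) {
          p <- rpos:(rpos + ln - 1L); q <- qpos:(qpos + ln - 1L)
          keep <- p >= rs & p <= re & quals[q] >= th$min_baseq
          if (any(keep)) {
            codes <- .base_code[bases[q[keep]]]
            okb <- !is.na(codes)
            if (any(okb)) {
              ij <- cbind(p[keep][okb] - rs + 1L, codes[okb])
              counts[ij] <- counts[ij] + 1L
            }
          }
          rpos <- rpos + ln; qpos <- qpos + ln
        } else if (op == "I") {
          if (th$call_indels && rpos - 1L >= rs && rpos - 1L <= re) {
            key <- sprintf("%d|I|%s", rpos - 1L,
                           paste(bases[qpos:(qpos + ln - 1L)], collapse = ""))
            indel_counts[[key]] <- (if (is.null(indel_counts[[key]])) 0L
                                    else indel_counts[[key]]) + 1L
          }
          qpos <- qpos + ln
        } else if (op == "D" || op == "N") {
          if (op == "D" && th$call_indels && rpos - 1L >= rs &&
              rpos + ln - 1L <= re) {
            key <- sprintf("%d|D|%d", rpos - 1L, ln)
            indel_counts[[key]] <- (if (is.null(indel_counts[[key]])) 0L
                                    else indel_counts[[key]]) + 1L
          }
          rpos <- rpos + ln
        } else if (op == "S") {
          qpos <- qpos + ln
        } else if (op == "H" || op == "P") {
          # consume nothing
        }
      }
    }
  }

  depth <- rowSums(counts)
  recs <- list()
  emit <- function(pos, ref, alts, cts, dp) {
    # cts: counts parallel to c(ref, alts); decide genotype on top two
    o <- order(-cts, c(ref, alts))
    top <- o[1]; second <- o[2]
    minor <- cts[second]
    gt_idx <- if (dp > 0 && minor / dp >= th$het_af) sort(c(top, second) - 1L)
              else c(top - 1L, top - 1L)
    if (all(gt_idx == 0L)) return(NULL)  # hom-ref
    used <- sort(unique(gt_idx[gt_idx > 0L]))
    # keep up to 2 alts by count for the record
    keep_alts <- o[o != 1L][seq_len(min(2L, length(alts)))] - 1L
    keep_alts <- sort(unique(c(keep_alts, used)))[seq_len(min(2L, length(alts)))]
    alt_str <- alts[keep_alts]
    remap <- function(ix) match(ix, c(0L, keep_alts)) - 1L
    gt <- paste(remap(gt_idx), collapse = "/")
    qual <- -10 * log10(max(stats::pbinom(minor - 1, dp, 0.01,
                                          lower.tail = FALSE), 1e-300))
    data.frame(chrom = chrom, pos = pos, ref = ref,
               alt = paste(alt_str, collapse = ","), gt = gt,
               ad = paste(cts[c(1L, keep_alts + 1L)], collapse = ","),
               dp = dp, qual = round(qual, 2), stringsAsFactors = FALSE)
  }

  for (k in which(depth > 0)) {
    rb <- ref_codes[k]
    if (is.na(rb)) next  # N in reference: do not call
    alt_codes <- setdiff(1:4, rb)
    qual_alt <- alt_codes[counts[k, alt_codes] >= th$min_ad &
                            counts[k, alt_codes] / depth[k] >= th$min_af]
    if (!length(qual_alt)) next
    bases <- names(.base_code)
    r <- emit(rs + k - 1L, bases[rb], bases[qual_alt],
              c(counts[k, rb], counts[k, qual_alt]), depth[k])
    if (!is.null(r)) recs[[length(recs) + 1L]] <- r
  }

  for (key in ls(indel_counts)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    anchor <- as.integer(parts[1]); type <- parts[2]
    cnt <- indel_counts[[key]]
    k <- anchor - rs + 1L
    if (k < 1L || k > L) next
    dp <- max(depth[k], cnt)
    if (cnt < th$min_ad || cnt / dp < th$min_af) next
    if (type == "I") {
      ref_a <- substr(refseq, k, k)
      alt_a <- paste0(ref_a, parts[3])
    } else {
      dl <- as.integer(parts[3])
      if (k + dl > L) next
      ref_a <- substr(refseq, k, k + dl)
      alt_a <- substr(refseq, k, k)
    }
    ref_cnt <- max(dp - cnt, 0L)
    r <- emit(anchor, ref_a, alt_a, c(ref_cnt, cnt), dp)
    if (!is.null(r)) recs[[length(recs) + 1L]] <- r
  }

  if (!length(recs))
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), gt = character(), ad = character(),
                      dp = integer(), qual = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, recs)
  out <- out[order(out$pos, out$ref), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write variant calls as a VCF 4.2 file
#'
#' FORMAT is GT:AD:DP, with a PS tag appended for phased records when the
#' calls carry phasing columns (\code{phased}, \code{ps}, \code{hap1},
#' \code{hap2} from \code{\link{phaseVariants}}); phased genotypes are
#' written as \code{hap1|hap2}. A \code{.gz} suffix gzips the output.
#'
#' @param calls variant call data.frame
#' @param path output path (\code{.vcf} or \code{.vcf.gz})
#' @param chrom_lengths named integer vector for contig header lines
#' @param sample sample name
#' @return invisibly, the path
#' @export
writeVcfFile <- function(calls, path, chrom_lengths, sample = "sample1") {
  phased_cols <- all(c("phased", "ps", "hap1", "hap2") %in% names(calls))
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
                   as.integer(chrom_lengths)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           if (phased_cols)
             "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  sample))
  body <- character(0)
  if (nrow(calls)) {
    gt <- calls$gt
    fmt <- rep("GT:AD:DP", nrow(calls))
    sdat <- paste(gt, calls$ad, calls$dp, sep = ":")
    if (phased_cols) {
      ph <- !is.na(calls$phased) & calls$phased
      gt[ph] <- paste0(calls$hap1[ph], "|", calls$hap2[ph])
      fmt[ph] <- "GT:AD:DP:PS"
      sdat <- paste(gt, calls$ad, calls$dp, sep = ":")
      sdat[ph] <- paste(sdat[ph], calls$ps[ph], sep = ":")
    }
    body <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt,
                  sprintf("%.2f", calls$qual), "PASS", ".", fmt, sdat,
                  sep = "\t")
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  writeLines(c(hdr, body), con)
  close(con)
  invisible(path)
}

#' Read variant calls (possibly phased) from a VCF file
#'
#' Accepts VCFs written by \code{\link{writeVcfFile}} as well as externally
#' phased VCFs (GT with \code{|} and a PS FORMAT tag).
#'
#' @param path VCF file (.vcf or .vcf.gz)
#' @return variant call data.frame with phasing columns (phased, ps, hap1,
#'   hap2; NA when unphased)
#' @export
readVcfCalls <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n <- nrow(fix)
  gt_raw <- if (n) vcfR::extract.gt(v, element = "GT")[, 1] else character(0)
  ad <- if (n) vcfR::extract.gt(v, element = "AD")[, 1] else character(0)
  dp <- if (n) suppressWarnings(as.integer(vcfR::extract.gt(v, element = "DP")[, 1]))
        else integer(0)
  ps <- rep(NA_integer_, n)
  has_ps <- n > 0 && any(grepl("PS", v@gt[, "FORMAT"]))
  if (has_ps)
    ps <- suppressWarnings(as.integer(vcfR::extract.gt(v, element = "PS")[, 1]))
  phased <- grepl("\\|", gt_raw)
  split_gt <- strsplit(gt_raw, "[/|]")
  a1 <- suppressWarnings(as.integer(vapply(split_gt, `[`, character(1), 1)))
  a2 <- suppressWarnings(as.integer(vapply(split_gt, function(x)
    if (length(x) > 1) x[2] else x[1], character(1))))
  data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
             alt = fix$ALT,
             gt = paste(pmin(a1, a2), pmax(a1, a2), sep = "/"),
             ad = unname(ad), dp = unname(dp),
             qual = suppressWarnings(as.numeric(fix$QUAL)),
             phased = phased, ps = unname(ps),
             hap1 = ifelse(phased, a1, NA_integer_),
             hap2 = ifelse(phased, a2, NA_integer_),
             stringsAsFactors = FALSE)
}
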