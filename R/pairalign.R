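#' Convert a raw local-alignment score to a bit score
#'
#' \eqn{B = (\lambda S - \ln K) / \ln 2} with the Karlin-Altschul constants of
#' \code{params}.
#'
#' @param raw_score integer raw Smith-Waterman score(s)
#' @param params a \code{\link{ScoringParams}} object
#' @return numeric bit score(s)
#' @export
bitScore <- function(raw_score, params = scoringParams()) {
  (params@lambda * raw_score - log(params@k_param)) / log(2)
}

.revcomp <- function(x) {
  as.character(reverseComplement(DNAString(x)))
}

.check_seq <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) < 1L)
    stop(what, " must be a single non-empty sequence")
  if (grepl("[^ACGTNacgtn]", x))
    stop(what, " contains characters outside {A,C,G,T,N}")
  invisible(x)
}

.aln_result <- function(a, params, strand) {
  bits <- if (a$score > 0) bitScore(a$score, params) else 0
  list(raw_score = a$score, bit_score = bits,
       pident = if (a$aln_len > 0) 100 * a$n_ident / a$aln_len else 0,
       n_ident = a$n_ident, aln_len = a$aln_len, n_gap_cols = a$n_gap_cols,
       q_start = a$q_start, q_end = a$q_end,
       s_start = a$s_start, s_end = a$s_end, strand = strand)
}

#' Optimal affine-gap local alignment
#'
#' Smith-Waterman with affine gaps (a gap of length L costs
#' \code{gap_open + L * gap_extend}). N is scored as a mismatch against every
#' base including N and never counts as an identity. Both strands are tried by
#' default; the better strand is returned (ties prefer \code{+}). For strand
#' \code{-} the query was reverse-complemented before alignment and reported
#' coordinates refer to the reverse-complemented query. Traceback is
#' deterministic: diagonal over up (gap in subject) over left, and the best
#' cell is the lowest \code{(q_end, s_end)} among equal maxima. Coordinates
#' are 1-based closed.
#'
#' @param query,subject nucleotide strings over A,C,G,T,N
#' @param params a \code{\link{ScoringParams}}
#' @param both_strands try the reverse complement of the query too
#' @return list with raw_score, bit_score, pident, n_ident, aln_len,
#'   n_gap_cols, q_start/q_end, s_start/s_end, strand
#' @export
alignLocal <- function(query, subject, params = scoringParams(),
                       both_strands = TRUE) {
  .check_seq(query, "query"); .check_seq(subject, "subject")
  fwd <- .sw_align_cpp(query, subject, params@match, params@mismatch,
                       params@gap_open, params@gap_extend, integer(0), integer(0))
  if (both_strands) {
    rev <- .sw_align_cpp(.revcomp(query), subject, params@match, params@mismatch,
                         params@gap_open, params@gap_extend, integer(0), integer(0))
    if (rev$score > fwd$score) return(.aln_result(rev, params, "-"))
  }
  .aln_result(fwd, params, "+")
}

# One strand of greedy HSP chaining: repeatedly take the best local alignment,
# mask its query/subject spans, realign; keep hits that are co-linear and
# non-overlapping with those already accepted.
.chain_strand <- function(q, s, params, strand, max_hsps = 32L) {
  qmask <- integer(nchar(q)); smask <- integer(nchar(s))
  accepted <- list()
  for (iter in seq_len(max_hsps)) {
    a <- .sw_align_cpp(q, s, params@match, params@mismatch,
                       params@gap_open, params@gap_extend, qmask, smask)
    if (a$score <= 0) break
    bits <- bitScore(a$score, params)
    if (bits < params@min_report_bits) break
    qmask[a$q_start:a$q_end] <- 1L
    smask[a$s_start:a$s_end] <- 1L
    ok <- all(vapply(accepted, function(b) {
      (a$q_end < b$q_start && a$s_end < b$s_start) ||
        (a$q_start > b$q_end && a$s_start > b$s_end)
    }, logical(1)))
    if (ok) accepted[[length(accepted) + 1L]] <- .aln_result(a, params, strand)
    if (all(qmask == 1L) || all(smask == 1L)) break
  }
  accepted
}

.chain_summary <- function(hsps) {
  if (!length(hsps))
    return(list(total_bits = 0, weighted_pident = 0, n_ident = 0L, aln_len = 0L))
  ni <- sum(vapply(hsps, `[[`, integer(1), "n_ident"))
  al <- sum(vapply(hsps, `[[`, integer(1), "aln_len"))
  list(total_bits = sum(vapply(hsps, `[[`, numeric(1), "bit_score")),
       weighted_pident = if (al > 0) 100 * ni / al else 0,
       n_ident = ni, aln_len = al)
}

#' Greedy co-linear HSP chain between two sequences
#'
#' Repeatedly extracts the best local alignment, masks its query and subject
#' spans, and realigns until the next hit would fall below
#' \code{min_report_bits}. Retained HSPs are mutually non-overlapping and
#' co-linear in both sequences; their bit scores are summed. This is how a
#' haplotype contig spanning an intron is scored against an exon-concatenated
#' allele reference: one HSP per exon.
#'
#' @inheritParams alignLocal
#' @return list with total_bits, weighted_pident (identity-weighted by
#'   alignment length), n_ident, aln_len, strand, and hsps (list of
#'   \code{\link{alignLocal}}-style records)
#' @export
hspChain <- function(query, subject, params = scoringParams(),
                     both_strands = TRUE) {
  .check_seq(query, "query"); .check_seq(subject, "subject")
  fwd <- .chain_strand(query, subject, params, "+")
  best <- fwd; strand <- "+"
  if (both_strands) {
    rev <- .chain_strand(.revcomp(query), subject, params, "-")
    if (.chain_summary(rev)$total_bits > .chain_summary(fwd)$total_bits) {
      best <- rev; strand <- "-"
    }
  }
  c(.chain_summary(best), list(strand = strand, hsps = best))
}

#' Best bit score of a query against a set of subjects
#'
#' Score-only Smith-Waterman of the query (both strands) against every subject
#' sequence; returns the per-subject bit score. Scores below
#' \code{min_report_bits} are floored to 0. Workhorse of the paralog read
#' filter.
#'
#' @param query nucleotide string
#' @param subjects character vector (or DNAStringSet) of subject sequences
#' @param params a \code{\link{ScoringParams}}
#' @param both_strands try the reverse-complemented query too
#' @return numeric vector of bit scores, one per subject
#' @export
bestHitBits <- function(query, subjects, params = scoringParams(),
                        both_strands = TRUE) {
  .check_seq(query, "query")
  subjects <- as.character(subjects)
  if (!length(subjects)) return(numeric(0))
  raw <- .sw_score_batch_cpp(query, subjects, params@match, params@mismatch,
                             params@gap_open, params@gap_extend)
  if (both_strands) {
    raw2 <- .sw_score_batch_cpp(.revcomp(query), subjects, params@match,
                                params@mismatch, params@gap_open,
                                params@gap_extend)
    raw <- pmax(raw, raw2)
  }
  bits <- ifelse(raw > 0, bitScore(raw, params), 0)
  ifelse(bits >= params@min_report_bits, bits, 0)
}

#' Tabular dump of an HSP chain (BLAST outfmt-6 column order)
#'
#' @param chain result of \code{\link{hspChain}}
#' @param qseqid,sseqid labels for the query and subject
#' @return data.frame with columns qseqid, sseqid, pident, length, bitscore,
#'   qstart, qend, sstart, send
#' @export
hspTable <- function(chain, qseqid = "query", sseqid = "subject") {
  h <- chain$hsps
  data.frame(
    qseqid = rep(qseqid, length(h)), sseqid = rep(sseqid, length(h)),
    pident = vapply(h, `[[`, numeric(1), "pident"),
    length = vapply(h, `[[`, integer(1), "aln_len"),
    bitscore = vapply(h, `[[`, numeric(1), "bit_score"),
    qstart = vapply(h, `[[`, integer(1), "q_start"),
    qend = vapply(h, `[[`, integer(1), "q_end"),
    sstart = vapply(h, `[[`, integer(1), "s_start"),
    send = vapply(h, `[[`, integer(1), "s_end"),
    stringsAsFactors = FALSE)
}
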