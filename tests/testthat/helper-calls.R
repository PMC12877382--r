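# minimal het-call table for phasing tests: k SNV sites at positions 10,20,...
calls_for_sites <- function(k, pos = seq_len(k) * 10L) {
  data.frame(chrom = "c", pos = pos, ref = "A", alt = "C", gt = "0/1",
             ad = "5,5", dp = 10L, qual = 50, stringsAsFactors = FALSE)
}

as_fragments <- function(M) {
  attr(M, "het_idx") <- seq_len(ncol(M))
  M
}

# simple single-end read records over a reference string
mk_reads <- function(seqs, pos, chrom = "chr1", mapq = 60L, qual_q = 35L,
                     ids = sprintf("r%03d", seq_along(seqs)), flag = 0L) {
  data.frame(read_id = ids, flag = flag, chrom = chrom, pos = as.integer(pos),
             mapq = mapq, cigar = sprintf("%dM", nchar(seqs)), seq = seqs,
             qual = strrep(intToUtf8(33L + qual_q), nchar(seqs)),
             stringsAsFactors = FALSE)
}
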