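cb_fixture <- function(seed = 1, chrom_len = 400) {
  set.seed(seed)
  chr <- rand_seq(chrom_len)
  genome <- Biostrings::DNAStringSet(chr); names(genome) <- "chr1"
  tg <- mhcTargets(list(G = list(chrom = "chr1",
                                 exons = list(exon2 = c(101, 160),
                                              exon3 = c(201, 260)))))
  list(chr = chr, genome = genome, tg = tg)
}

ph_call <- function(pos, ref, alt, hap1, hap2, ps = NA, chrom = "chr1") {
  het <- hap1 != hap2
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             gt = paste(min(hap1, hap2), max(hap1, hap2), sep = "/"),
             ad = "5,5", dp = 10L, qual = 60, phased = het,
             ps = if (het) as.integer(ps) else NA_integer_,
             hap1 = if (het) hap1 else NA_integer_,
             hap2 = if (het) hap2 else NA_integer_, stringsAsFactors = FALSE)
}

test_that("zero variants reproduce the reference substring exactly", {
  fx <- cb_fixture()
  empty <- ph_call(130L, "A", "C", 0L, 1L, ps = 130L)[0, ]
  ct <- buildContigs(empty, fx$genome, fx$tg, "G", flank = 50L)
  m <- contigMeta(ct)
  expect_equal(nrow(m), 1L)           # consensus only
  expect_equal(m$block, 0L)
  expect_equal(m$start, 51L); expect_equal(m$end, 310L)
  expect_identical(as.character(contigSeqs(ct)[[1]]),
                   substr(fx$chr, 51, 310))
})

test_that("one het SNV yields two contigs differing at exactly that offset", {
  fx <- cb_fixture()
  rb <- substr(fx$chr, 130, 130)
  alt <- setdiff(BASES, rb)[1]
  calls <- ph_call(130L, rb, alt, 0L, 1L, ps = 130L)
  ct <- buildContigs(calls, fx$genome, fx$tg, "G", flank = 20L)
  m <- contigMeta(ct)
  het <- which(m$block == 130L)
  expect_length(het, 2L)
  s1 <- as.character(contigSeqs(ct)[[het[1]]])
  s2 <- as.character(contigSeqs(ct)[[het[2]]])
  d <- which(strsplit(s1, "")[[1]] != strsplit(s2, "")[[1]])
  expect_equal(d, 21L)                # 130 - span_start(110) + 1
  expect_identical(s1, substr(fx$chr, 110, 150))   # hap1 carries REF here
  expect_equal(substr(s2, 21, 21), alt)
})

test_that("hom-alt bases land in both contigs, het bases differ", {
  fx <- cb_fixture()
  r1 <- substr(fx$chr, 120, 120); a1 <- setdiff(BASES, r1)[1]   # het
  r2 <- substr(fx$chr, 140, 140); a2 <- setdiff(BASES, r2)[1]   # hom-alt
  calls <- rbind(ph_call(120L, r1, a1, 1L, 0L, ps = 120L),
                 ph_call(140L, r2, a2, 1L, 1L))
  ct <- buildContigs(calls, fx$genome, fx$tg, "G", flank = 30L)
  m <- contigMeta(ct)
  het <- which(m$block == 120L)
  s1 <- as.character(contigSeqs(ct)[[het[1]]])
  s2 <- as.character(contigSeqs(ct)[[het[2]]])
  # string-substitution oracle over the span [90, 150]
  span <- substr(fx$chr, 90, 150)
  want1 <- span; substr(want1, 31, 31) <- a1; substr(want1, 51, 51) <- a2
  want2 <- span; substr(want2, 51, 51) <- a2
  expect_identical(s1, want1)
  expect_identical(s2, want2)
  # consensus carries only the hom-alt substitution
  cons <- as.character(contigSeqs(ct)[[which(m$block == 0L)]])
  expect_equal(substr(cons, 140 - m$start[m$block == 0L] + 1L,
                      140 - m$start[m$block == 0L] + 1L), a2)
  expect_equal(substr(cons, 120 - m$start[m$block == 0L] + 1L,
                      120 - m$start[m$block == 0L] + 1L), r1)
})

test_that("REF mismatches against the genome are hard errors", {
  fx <- cb_fixture()
  rb <- substr(fx$chr, 130, 130)
  wrong <- setdiff(BASES, rb)[1]
  calls <- ph_call(130L, wrong, rb, 0L, 1L, ps = 130L)
  expect_error(buildContigs(calls, fx$genome, fx$tg, "G"), "130")
})

test_that("contig building is invariant to record order within a block", {
  fx <- cb_fixture()
  r1 <- substr(fx$chr, 120, 120); a1 <- setdiff(BASES, r1)[1]
  r2 <- substr(fx$chr, 145, 145); a2 <- setdiff(BASES, r2)[1]
  calls <- rbind(ph_call(120L, r1, a1, 1L, 0L, ps = 120L),
                 ph_call(145L, r2, a2, 0L, 1L, ps = 120L))
  a <- buildContigs(calls, fx$genome, fx$tg, "G")
  b <- buildContigs(calls[2:1, ], fx$genome, fx$tg, "G")
  expect_identical(as.character(contigSeqs(a)), as.character(contigSeqs(b)))
})

test_that("FASTA headers follow the convention and round-trip", {
  fx <- cb_fixture()
  rb <- substr(fx$chr, 130, 130); alt <- setdiff(BASES, rb)[1]
  rb2 <- substr(fx$chr, 230, 230); alt2 <- setdiff(BASES, rb2)[1]
  calls <- rbind(ph_call(130L, rb, alt, 0L, 1L, ps = 130L),
                 ph_call(230L, rb2, alt2, 1L, 0L, ps = 230L))
  ct <- buildContigs(calls, fx$genome, fx$tg, "G", flank = 10L)
  expect_equal(nrow(contigMeta(ct)), 5L)  # 2 blocks x 2 haps + consensus
  f <- tempfile(fileext = ".fa")
  writeContigFasta(ct, f)
  back <- Biostrings::readDNAStringSet(f)
  expect_identical(as.character(back), as.character(contigSeqs(ct)),
                   ignore_attr = TRUE)
  expect_true("G|block=130|hap=1|chr1:120-140" %in% names(back))
})

test_that("planted haplotype substrings come back exactly from planted calls", {
  tr <- simulateFamily(simSpec(seed = 17))
  g <- targetGenes(simTargets(tr))[1]
  calls <- plantedCalls(tr)
  env <- geneEnvelope(simTargets(tr), g)
  calls <- calls[calls$pos >= GenomicRanges::start(env) - 200 &
                   calls$pos <= GenomicRanges::end(env) + 200, ]
  ct <- buildContigs(calls, simGenome(tr), simTargets(tr), g, flank = 200L)
  m <- contigMeta(ct)
  het <- which(m$block > 0L)
  if (length(het)) {
    haps <- as.character(simHaplotypes(tr))
    got <- sort(vapply(het, function(i)
      as.character(contigSeqs(ct)[[i]]), character(1)))
    want <- sort(vapply(1:2, function(h)
      substr(haps[h], m$start[het[1]], m$end[het[1]]), character(1)))
    expect_identical(got, want)
  }
})
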