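# target config used across these tests: two class-I-like genes with two
# exons each, on one small chromosome
ref_targets <- function() {
  mhcTargets(list(
    "SLA-X" = list(chrom = "chrT", exons = list(exon2 = c(101, 130),
                                                exon3 = c(171, 190))),
    "SLA-Y" = list(chrom = "chrT", exons = list(exon2 = c(301, 330),
                                                exon3 = c(371, 390)))))
}

write_fa <- function(seqs, path) {
  writeLines(paste0(">", names(seqs), "\n", unlist(seqs)), path)
  path
}

test_that("allele FASTA loading parses names, groups by gene and validates", {
  tg <- ref_targets()
  set.seed(1)
  fa <- write_fa(c("SLA-X*01:01 some description" = rand_seq(50),
                   "SLA-X*01:02" = rand_seq(50),
                   "SLA-Y*02:01" = rand_seq(50),
                   "SLA-Y*02:02" = rand_seq(50),
                   "SLA-Y*02:03" = rand_seq(50)),
                 tempfile(fileext = ".fa"))
  db <- loadAlleleDb(fa, tg)
  expect_equal(sort(alleleNames(db))[1], "SLA-X*01:01")
  expect_equal(as.integer(alleleCounts(db)[c("SLA-X", "SLA-Y")]), c(2L, 3L))
  expect_equal(unname(alleleGenes(db)[["SLA-Y*02:01"]]), "SLA-Y")

  dup <- write_fa(c("SLA-X*01:01" = "ACGT", "SLA-X*01:01" = "ACGG"),
                  tempfile(fileext = ".fa"))
  expect_error(loadAlleleDb(dup, tg), "duplicate allele name")
  bad <- write_fa(c("SLAX0101" = "ACGT"), tempfile(fileext = ".fa"))
  expect_error(loadAlleleDb(bad, tg), "SLAX0101")
  deg <- write_fa(c("SLA-X*01:01" = strrep("ACGR", 13)),
                  tempfile(fileext = ".fa"))
  expect_error(loadAlleleDb(deg, tg), "degenerate")
})

test_that("exon structure is inferred from length or taken from a sidecar", {
  tg <- ref_targets()
  set.seed(2)
  fa <- write_fa(c("SLA-X*01:01" = rand_seq(50),   # both exons (30 + 20)
                   "SLA-X*01:02" = rand_seq(30),   # exon2 only
                   "SLA-X*01:03" = rand_seq(20)),  # exon3 only
                 tempfile(fileext = ".fa"))
  db <- loadAlleleDb(fa, tg)
  expect_true(isComplete(db)[["SLA-X*01:01"]])
  expect_false(isComplete(db)[["SLA-X*01:02"]])
  expect_equal(alleleExonSpans(db, "SLA-X*01:02")$exon, "exon2")
  expect_equal(alleleExonSpans(db, "SLA-X*01:03")$exon, "exon3")
  expect_equal(alleleExonSpans(db, "SLA-X*01:01")$end, c(30L, 50L))
})

test_that("partial alleles are patched from the most similar complete allele", {
  tg <- ref_targets()
  set.seed(3)
  e2 <- rand_seq(30)
  a_e3 <- rand_seq(20); b_e3 <- rand_seq(20)
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    for (i in sample(length(ch), k)) ch[i] <- setdiff(BASES, ch[i])[1]
    paste(ch, collapse = "")
  }
  # P shares exon2; A is nearly identical to P there, B is farther
  fa <- write_fa(c("SLA-X*01:01" = paste0(mut(e2, 1), a_e3),  # A
                   "SLA-X*02:01" = paste0(mut(e2, 5), b_e3),  # B
                   "SLA-X*03:01" = e2),                       # P: exon2 only
                 tempfile(fileext = ".fa"))
  db0 <- loadAlleleDb(fa, tg)
  db <- completePartialAlleles(db0, tg)
  expect_equal(db@donor[[match("SLA-X*03:01", alleleNames(db))]], "SLA-X*01:01")
  patched <- as.character(alleleSeqs(db)[["SLA-X*03:01"]])
  expect_equal(substr(patched, 31, 50), a_e3)   # exon3 copied verbatim from A
  expect_equal(substr(patched, 1, 30), e2)      # own exon2 untouched
  expect_false(isComplete(db)[["SLA-X*03:01"]])
  # complete alleles are returned byte-identical; the operation is idempotent
  expect_identical(as.character(alleleSeqs(db)[["SLA-X*01:01"]]),
                   as.character(alleleSeqs(db0)[["SLA-X*01:01"]]))
  db2 <- completePartialAlleles(db, tg)
  expect_identical(as.character(alleleSeqs(db2)), as.character(alleleSeqs(db)))
})

test_that("equal-identity donors tie-break to the smallest allele name", {
  tg <- ref_targets()
  set.seed(4)
  e2 <- rand_seq(30)
  e3a <- rand_seq(20); e3b <- rand_seq(20)
  fa <- write_fa(c("SLA-X*02:01" = paste0(e2, e3b),
                   "SLA-X*01:01" = paste0(e2, e3a),
                   "SLA-X*09:01" = e2), tempfile(fileext = ".fa"))
  db <- completePartialAlleles(loadAlleleDb(fa, tg), tg)
  i <- match("SLA-X*09:01", alleleNames(db))
  expect_equal(db@donor[[i]], "SLA-X*01:01")
  expect_equal(substr(as.character(alleleSeqs(db)[[i]]), 31, 50), e3a)
})

test_that("patching fails when a gene has partial alleles but no complete one", {
  tg <- ref_targets()
  set.seed(5)
  fa <- write_fa(c("SLA-X*01:01" = rand_seq(30)), tempfile(fileext = ".fa"))
  expect_error(completePartialAlleles(loadAlleleDb(fa, tg), tg),
               "no complete allele")
})

test_that("write/load round-trip preserves names, sequences and counts", {
  tg <- ref_targets()
  set.seed(6)
  fa <- write_fa(c("SLA-X*01:01" = rand_seq(50), "SLA-X*01:02" = rand_seq(50),
                   "SLA-Y*02:01" = rand_seq(50)), tempfile(fileext = ".fa"))
  db <- loadAlleleDb(fa, tg)
  out <- tempfile(fileext = ".fa")
  writeAlleleDb(db, out)
  db2 <- loadAlleleDb(out, tg)
  expect_identical(alleleNames(db2), alleleNames(db))
  expect_identical(as.character(alleleSeqs(db2)), as.character(alleleSeqs(db)))
  expect_identical(alleleCounts(db2), alleleCounts(db))
})

test_that("config YAML round-trips through read/write", {
  tg <- ref_targets()
  f <- tempfile(fileext = ".yaml")
  writeTargetConfig(tg, f)
  tg2 <- readTargetConfig(f)
  expect_equal(targetGenes(tg2), targetGenes(tg))
  expect_equal(start(exonRegions(tg2, "SLA-X")), start(exonRegions(tg, "SLA-X")))
  expect_equal(paralogsOf(tg2, "SLA-X"), "SLA-Y")
})

test_that("paralog cross-check attributes alleles to their own region", {
  tg <- ref_targets()
  set.seed(8)
  chr <- rand_seq(400)
  genome <- Biostrings::DNAStringSet(chr); names(genome) <- "chrT"
  own_x <- paste0(substr(chr, 101, 130), substr(chr, 171, 190))
  fa <- write_fa(c("SLA-X*01:01" = own_x,
                   "SLA-Y*02:01" = paste0(substr(chr, 301, 330),
                                          substr(chr, 371, 390))),
                 tempfile(fileext = ".fa"))
  db <- loadAlleleDb(fa, tg)
  res <- paralogCrossCheck(db, genome, tg, scoringParams(min_report_bits = 0))
  expect_true(all(res$own_region))
  expect_true(all(res$pident == 100))
  sm <- summarizeCrossCheck(res)
  expect_true(all(sm$frac_own == 1))
})

test_that("cross-check on a simulated family keeps alleles on their own gene", {
  tr <- simulateFamily(simSpec(seed = 31, alleles_per_gene = 3))
  res <- paralogCrossCheck(simAlleleDb(tr), simGenome(tr), simTargets(tr))
  expect_true(all(res$own_region))  # ~8% divergence separates paralogs cleanly
})
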