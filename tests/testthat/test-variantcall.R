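vc_genome <- function(seq) {
  g <- Biostrings::DNAStringSet(seq); names(g) <- "chr1"; g
}
region_of <- function(genome) {
  GenomicRanges::GRanges("chr1", IRanges::IRanges(1, Biostrings::width(genome)[1]))
}

test_that("reads matching the reference yield no calls", {
  set.seed(1)
  ref <- rand_seq(300)
  genome <- vc_genome(ref)
  reads <- mk_reads(rep(substr(ref, 51, 200), 8), pos = rep(51, 8))
  calls <- callVariants(reads, genome, region_of(genome), "short")
  expect_equal(nrow(calls), 0L)
})

test_that("a balanced site is called het with correct allele depths", {
  set.seed(2)
  ref <- rand_seq(200)
  genome <- vc_genome(ref)
  rb <- substr(ref, 100, 100)
  alt <- setdiff(BASES, rb)[1]
  v <- ref
  substr(v, 100, 100) <- alt
  reads <- mk_reads(c(rep(substr(ref, 51, 150), 5), rep(substr(v, 51, 150), 5)),
                    pos = rep(51, 10))
  calls <- callVariants(reads, genome, region_of(genome), "short")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$pos, 100L)
  expect_equal(calls$ref, rb)
  expect_equal(calls$alt, alt)
  expect_equal(calls$gt, "0/1")
  expect_equal(calls$ad, "5,5")
  expect_equal(calls$dp, 10L)
})

test_that("singleton alternate observations fall below the depth floor", {
  set.seed(3)
  ref <- rand_seq(200)
  genome <- vc_genome(ref)
  v <- ref; substr(v, 100, 100) <- setdiff(BASES, substr(ref, 100, 100))[1]
  reads <- mk_reads(substr(v, 51, 150), pos = 51)
  calls <- callVariants(reads, genome, region_of(genome), "short")
  expect_equal(nrow(calls), 0L)
})

test_that("calls are invariant to read order", {
  set.seed(4)
  tr <- simulateFamily(simSpec(seed = 4))
  g <- targetGenes(simTargets(tr))[1]
  sim <- simulateReads(tr, mode = "short_pe", depth = 15, error_rate = 0.01)
  env <- geneEnvelope(simTargets(tr), g)
  reads <- subsetReads(sim$reads, "chrSim", start(env) - 300, end(env) + 300)
  c1 <- callVariants(reads, simGenome(tr), env, "short")
  shuffled <- reads[sample(nrow(reads)), , drop = FALSE]
  c2 <- callVariants(shuffled, simGenome(tr), env, "short")
  rownames(c1) <- rownames(c2) <- NULL
  expect_identical(c1, c2)
})

test_that("error-free planted diploids are recovered exactly", {
  for (sd in 1:3) {
    tr <- simulateFamily(simSpec(seed = sd))
    sim <- simulateReads(tr, mode = "long", depth = 12, error_rate = 0)
    tv <- truthVariants(tr)
    for (g in targetGenes(simTargets(tr))) {
      env <- geneEnvelope(simTargets(tr), g)
      calls <- callVariants(sim$reads, simGenome(tr), env, "long")
      want <- tv[tv$gene == g & tv$pos >= GenomicRanges::start(env) &
                   tv$pos <= GenomicRanges::end(env), ]
      expect_setequal(calls$pos, want$pos)
      for (i in seq_len(nrow(want))) {
        row <- calls[calls$pos == want$pos[i], ]
        called <- strsplit(row$gt, "/")[[1]]
        alleles <- c(row$ref, strsplit(row$alt, ",")[[1]])
        got <- sort(alleles[as.integer(called) + 1L])
        expect_equal(got, sort(c(want$hap1[i], want$hap2[i])),
                     info = sprintf("seed %d gene %s pos %d", sd, g, want$pos[i]))
      }
    }
  }
})

test_that("planted SNV recall stays high at 1% error and depth 30", {
  hits <- 0; tot <- 0
  for (sd in 1:3) {
    tr <- simulateFamily(simSpec(seed = sd))
    sim <- simulateReads(tr, mode = "long", depth = 30, error_rate = 0.01)
    g <- targetGenes(simTargets(tr))[1]
    env <- geneEnvelope(simTargets(tr), g)
    calls <- callVariants(sim$reads, simGenome(tr), env, "long")
    tv <- truthVariants(tr)
    want <- tv$pos[tv$gene == g & tv$pos >= GenomicRanges::start(env) &
                     tv$pos <= GenomicRanges::end(env)]
    hits <- hits + sum(want %in% calls$pos)
    tot <- tot + length(want)
  }
  expect_gte(hits / tot, 0.95)
})

test_that("VCF writing round-trips through the reader", {
  set.seed(6)
  ref <- rand_seq(200)
  genome <- vc_genome(ref)
  v <- ref; substr(v, 80, 80) <- setdiff(BASES, substr(ref, 80, 80))[1]
  reads <- mk_reads(c(rep(substr(ref, 51, 150), 4), rep(substr(v, 51, 150), 4)),
                    pos = rep(51, 8))
  calls <- callVariants(reads, genome, region_of(genome), "short")
  f <- tempfile(fileext = ".vcf.gz")
  writeVcfFile(calls, f, c(chr1 = 200L))
  back <- readVcfCalls(f)
  expect_equal(back$pos, calls$pos)
  expect_equal(back$ref, calls$ref)
  expect_equal(back$alt, calls$alt)
  expect_equal(back$gt, calls$gt)
  expect_false(any(back$phased))
})
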