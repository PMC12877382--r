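test_that("fragments record observed alleles at covered het sites", {
  # reference AAAA...; three het A->C SNVs at positions 10, 20, 30
  calls <- calls_for_sites(3)
  alt_read <- strrep("A", 41)
  for (p in c(10, 20, 30)) substr(alt_read, p, p) <- "C"
  reads <- rbind(mk_reads(alt_read, 1, chrom = "c", ids = "alt"),
                 mk_reads(strrep("A", 41), 1, chrom = "c", ids = "ref"),
                 mk_reads(strrep("G", 41), 1, chrom = "c", ids = "other"))
  M <- buildFragments(reads, calls)
  expect_equal(unname(M["alt", ]), c(1L, 1L, 1L))
  expect_equal(unname(M["ref", ]), c(0L, 0L, 0L))
  expect_true(all(is.na(M["other", ])))  # matches neither REF nor ALT
})

test_that("mates merge into a single fragment", {
  calls <- calls_for_sites(3)
  r1 <- strrep("A", 12); substr(r1, 10, 10) <- "C"    # covers site 1 (ALT)
  r2 <- strrep("A", 12)                                # covers site 3 (REF)
  reads <- data.frame(read_id = c("p1", "p1"), flag = c(99L, 147L),
                      chrom = "c", pos = c(1L, 25L), mapq = 60L,
                      cigar = "12M", seq = c(r1, r2),
                      qual = strrep("D", 12), stringsAsFactors = FALSE)
  M <- buildFragments(reads, calls)
  expect_equal(nrow(M), 1L)
  expect_equal(unname(M[1, ]), c(1L, NA_integer_, 0L))
})

test_that("consistent fragments phase into one block with MEC 0", {
  calls <- calls_for_sites(3)
  M <- as_fragments(matrix(rep(c(1L, 1L, 1L, 0L, 0L, 0L), 5), ncol = 3,
                           byrow = TRUE))
  ph <- phaseVariants(calls, M)
  expect_equal(nrow(ph$blocks), 1L)
  expect_equal(ph$blocks$mec, 0)
  expect_equal(ph$blocks$block_id, 10L)  # PS = leftmost variant position
  expect_true(all(ph$calls$phased))
  expect_true(all(ph$calls$hap1 != ph$calls$hap2))
  # haplotypes are all-ALT / all-REF up to labeling
  h1 <- ph$calls$hap1
  expect_true(all(h1 == h1[1]))
})

test_that("a single discordant fragment costs exactly one correction", {
  calls <- calls_for_sites(3)
  rows <- rep(list(c(1L, 1L, 1L), c(0L, 0L, 0L)), 5)
  rows[[11]] <- c(1L, 0L, 1L)
  M <- as_fragments(do.call(rbind, rows))
  ph <- phaseVariants(calls, M)
  expect_equal(ph$blocks$mec, 1)
  expect_equal(ref_mec(M), 1)
  h1 <- ph$calls$hap1
  expect_true(all(h1 == h1[1]))  # haplotypes unchanged by the noisy fragment
})

test_that("sites never co-covered become distinct singleton blocks", {
  calls <- calls_for_sites(2)
  M <- as_fragments(matrix(c(1L, NA, NA, 0L), ncol = 2, byrow = TRUE))
  ph <- phaseVariants(calls, M)
  expect_equal(nrow(ph$blocks), 2L)
  expect_true(all(ph$blocks$singleton))
  expect_equal(ph$blocks$block_id, c(10L, 20L))
  expect_true(all(ph$calls$phased))
})

test_that("greedy MEC matches exhaustive MEC on random instances", {
  set.seed(99)
  for (i in 1:60) {
    k <- sample(3:9, 1)
    M <- rand_fragment_matrix(k, n_frag = sample(5:25, 1))
    keep <- rowSums(!is.na(M)) > 0
    M <- M[keep, , drop = FALSE]
    if (!nrow(M)) next
    calls <- calls_for_sites(k)
    Mf <- as_fragments(M)
    exh <- phaseVariants(calls, Mf, exhaustive_max = 15L)
    gre <- phaseVariants(calls, Mf, exhaustive_max = 0L)
    expect_equal(sum(gre$blocks$mec), sum(exh$blocks$mec), info = paste("trial", i))
    # components are independent, so block MEC sums to the global optimum
    expect_equal(sum(exh$blocks$mec), ref_mec(M), info = paste("oracle trial", i))
  }
})

test_that("planted haplotypes are recovered up to a global flip", {
  set.seed(123)
  for (trial in 1:10) {
    k <- sample(4:10, 1)
    hap <- sample(0:1, k, replace = TRUE)
    # error-free fragments spanning adjacent sites, depth 5
    rows <- list()
    for (d in 1:5) for (s in 1:(k - 1)) {
      obs <- if (runif(1) < 0.5) hap[s:(s + 1)] else 1L - hap[s:(s + 1)]
      r <- rep(NA_integer_, k); r[s:(s + 1)] <- obs
      rows[[length(rows) + 1L]] <- r
    }
    M <- as_fragments(do.call(rbind, rows))
    ph <- phaseVariants(calls_for_sites(k), M)
    expect_equal(nrow(ph$blocks), 1L)
    expect_equal(ph$blocks$mec, 0)
    h1 <- ph$calls$hap1
    expect_true(all(h1 == hap) || all(h1 == 1L - hap))
  }
})

test_that("phasing output is invariant under haplotype relabeling", {
  # blocks are unordered pairs: flipping every fragment's alleles must give
  # the same blocks and MEC, with hap1/hap2 possibly swapped
  set.seed(7)
  k <- 5
  M <- rand_fragment_matrix(k, 20)
  calls <- calls_for_sites(k)
  a <- phaseVariants(calls, as_fragments(M))
  b <- phaseVariants(calls, as_fragments(1L - M))
  expect_equal(a$blocks$mec, b$blocks$mec)
  expect_equal(a$blocks$block_id, b$blocks$block_id)
  same <- all(a$calls$hap1 == b$calls$hap1)
  swapped <- all(a$calls$hap1 == b$calls$hap2)
  expect_true(same || swapped)
})
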