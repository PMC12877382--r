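# genotyping fixtures run on contigs built from planted calls of simulated
# families: the contigs equal the planted haplotype substrings exactly

geno_case <- function(seed, genotype = NULL, alleles_per_gene = 6) {
  tr <- simulateFamily(simSpec(seed = seed, n_paralogs = 1,
                               alleles_per_gene = alleles_per_gene,
                               planted_genotype = genotype))
  g <- targetGenes(simTargets(tr))[1]
  ct <- buildContigs(plantedCalls(tr), simGenome(tr), simTargets(tr), g)
  list(tr = tr, g = g, ct = ct, db = simAlleleDb(tr),
       tg = simTargets(tr), planted = plantedGenotype(tr)[[g]])
}

test_that("a contig equal to an allele's haplotype scores pident 100 for it", {
  fx <- geno_case(41)
  entries <- buildContigList(fx$ct, fx$db, fx$g, targets = fx$tg)
  het_blocks <- unique(entries$block[entries$block > 0])
  for (a in unique(fx$planted)) {
    rows <- entries[entries$allele == a & entries$block %in% het_blocks, ]
    expect_true(all(rows$pident == 100),
                info = paste("planted allele", a, "should match perfectly"))
  }
  expect_error(buildContigList(fx$ct, fx$db, "NOPE"), "absent")
})

test_that("planted heterozygous pairs are recovered as the unordered pair", {
  for (sd in 42:46) {
    fx <- geno_case(sd)
    if (fx$planted[1] == fx$planted[2]) next
    call <- genotypeGene(fx$ct, fx$db, fx$g, targets = fx$tg)
    expect_true(genotypeRecovered(call, fx$db, fx$planted),
                info = sprintf("seed %d planted %s", sd,
                               paste(fx$planted, collapse = "/")))
  }
})

test_that("homozygous plants are typed through the consensus contig", {
  tr0 <- simulateFamily(simSpec(seed = 50, n_paralogs = 1))
  nm <- alleleNames(simAlleleDb(tr0))[3]
  fx <- geno_case(50, genotype = stats::setNames(list(c(nm, nm)), "MHC-1"))
  m <- contigMeta(fx$ct)
  expect_true(all(m$block == 0L))          # no het blocks at all
  call <- genotypeGene(fx$ct, fx$db, fx$g, targets = fx$tg)
  expect_true(call@homozygousByConsensus)
  expect_true(genotypeRecovered(call, fx$db, c(nm, nm)))
})

test_that("exon-identical alleles are reported as an ' or ' ambiguity group", {
  fx <- geno_case(51)
  db <- fx$db
  # add a twin of the first planted allele, identical over the typed exons
  twin_of <- fx$planted[1]
  twin_name <- sub("\\*.*$", "*90:01", twin_of)
  seqs <- c(as.character(db@sequences),
            stats::setNames(as.character(db@sequences[[twin_of]]), twin_name))
  db2 <- tiny_db(seqs, exon_split = width(exonRegions(fx$tg, fx$g)))
  call <- genotypeGene(fx$ct, db2, fx$g, targets = fx$tg)
  grp <- if (twin_of %in% allele1Group(call)) allele1Group(call)
         else allele2Group(call)
  expect_setequal(grp, c(twin_of, twin_name))
  # report renders the group with the literal " or " separator
  f <- tempfile(fileext = ".tsv")
  writeReport(list(call), f)
  rep <- utils::read.delim(f)
  expect_true(any(grepl(" or ", c(rep$allele1, rep$allele2), fixed = TRUE)))
  # and nothing else about the call changes
  base <- genotypeGene(fx$ct, fx$db, fx$g, targets = fx$tg)
  expect_setequal(union(allele1Group(call), allele2Group(call)),
                  union(union(allele1Group(base), allele2Group(base)),
                        if (twin_of %in% c(allele1Group(base),
                                           allele2Group(base))) twin_name
                        else character(0)))
})

test_that("swapping haplotype labels leaves the unordered call unchanged", {
  fx <- geno_case(52)
  ct2 <- fx$ct
  m <- contigMeta(ct2)
  swap <- m$block > 0 & m$hap > 0
  m$hap[swap] <- 3L - m$hap[swap]
  o <- order(m$block, m$hap)
  ct2@meta <- m[o, ]
  ct2@sequences <- ct2@sequences[o]
  ct2@applied <- ct2@applied[o]
  a <- genotypeGene(fx$ct, fx$db, fx$g, targets = fx$tg)
  b <- genotypeGene(ct2, fx$db, fx$g, targets = fx$tg)
  pair_a <- list(allele1Group(a), allele2Group(a))
  pair_b <- list(allele1Group(b), allele2Group(b))
  expect_true(setequal(pair_a[[1]], pair_b[[1]]) &&
                setequal(pair_a[[2]], pair_b[[2]]) ||
              setequal(pair_a[[1]], pair_b[[2]]) &&
                setequal(pair_a[[2]], pair_b[[1]]))
})

test_that("two-round procedure matches the brute-force oracle", {
  set.seed(77)
  for (trial in 1:40) {
    n_alleles <- sample(2:6, 1)
    n_blocks <- sample(1:3, 1)
    alleles <- sprintf("G*%02d:01", seq_len(n_alleles))
    rows <- list()
    for (b in seq_len(n_blocks)) {
      haps <- if (runif(1) < 0.8) 1:2 else 1L
      for (h in haps) for (a in alleles) {
        rows[[length(rows) + 1L]] <- data.frame(
          allele = a, block = b * 100L, hap = h,
          bits = round(stats::runif(1, 50, 500), sample(0:2, 1)),
          stringsAsFactors = FALSE)
      }
    }
    if (runif(1) < 0.5) {
      for (a in alleles)
        rows[[length(rows) + 1L]] <- data.frame(
          allele = a, block = 0L, hap = 0L,
          bits = round(stats::runif(1, 50, 500), 2), stringsAsFactors = FALSE)
    }
    scores <- do.call(rbind, rows)
    # force occasional exact ties so the ambiguity path is exercised
    if (trial %% 4 == 0 && n_alleles >= 2) {
      scores$bits[scores$allele == alleles[2]] <-
        scores$bits[scores$allele == alleles[1]]
    }
    entries <- entries_from_scores(scores)
    got <- callGenotype(entries, NULL, "G")
    want <- ref_two_round(scores)
    expect_equal(allele1Group(got), want$g1, info = paste("trial", trial))
    expect_equal(allele2Group(got), want$g2, info = paste("trial", trial))
  }
})

test_that("degenerate inputs are rejected or rendered sensibly", {
  fx <- geno_case(53)
  empty <- fx$ct
  empty@meta <- empty@meta[0, ]
  empty@sequences <- empty@sequences[0]
  empty@applied <- list()
  expect_error(genotypeGene(empty, fx$db, fx$g, targets = fx$tg),
               "no typable sequence")
  f <- tempfile(fileext = ".tsv")
  writeReport(list(), f)
  rep <- utils::read.delim(f)
  expect_equal(nrow(rep), 0L)
  expect_true(all(c("gene", "allele1", "allele2") %in% names(rep)))
})
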