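#' Simulation parameters for a paralogous MHC-like gene family
#'
#' Defaults mirror the regime this pipeline targets: a class-I-like family of
#' 3 paralogs at ~8\% pairwise exon divergence, two typed exons of 270 and
#' 276 bp separated by an 800 bp intron with 1 kb flanks, 10 alleles per gene
#' whose SNVs concentrate in exons (Poisson mean 6 per exon), mean diploid
#' depth 20, and either 150 bp paired-end or ~3 kb long reads.
#'
#' @param n_paralogs number of paralogous genes
#' @param paralog_divergence target pairwise exon divergence between paralogs
#' @param exon_lengths,intron_lengths gene structure (introns between exons)
#' @param flank_length flanking sequence on each side of a locus
#' @param alleles_per_gene allele pool size per gene
#' @param allelic_snvs_per_exon Poisson mean of SNVs per exon per allele
#' @param planted_genotype optional named list gene -> character(2); default:
#'   sampled with replacement from the gene's pool
#' @param read_length short-read length (bp)
#' @param long_read_length long-read length (bp)
#' @param insert_mean,insert_sd paired-end fragment length distribution
#' @param mean_depth mean diploid depth over a locus
#' @param error_rate per-base substitution error rate of reads
#' @param seed integer seed fixing all randomness
#' @return a validated list of class "SimSpec"
#' @export
simSpec <- function(n_paralogs = 3L, paralog_divergence = 0.08,
                    exon_lengths = c(270L, 276L), intron_lengths = 800L,
                    flank_length = 1000L, alleles_per_gene = 10L,
                    allelic_snvs_per_exon = 6, planted_genotype = NULL,
                    read_length = 150L, long_read_length = 3000L,
                    insert_mean = 450, insert_sd = 50, mean_depth = 20,
                    error_rate = 0.01, seed = 1L) {
  stopifnot(n_paralogs >= 1L, paralog_divergence > 0, paralog_divergence < 0.25,
            alleles_per_gene >= 1L, mean_depth > 0,
            length(intron_lengths) == length(exon_lengths) - 1L ||
              length(exon_lengths) == 1L,
            error_rate >= 0, error_rate < 0.5)
  structure(list(
    n_paralogs = as.integer(n_paralogs), paralog_divergence = paralog_divergence,
    exon_lengths = as.integer(exon_lengths),
    intron_lengths = as.integer(intron_lengths),
    flank_length = as.integer(flank_length),
    alleles_per_gene = as.integer(alleles_per_gene),
    allelic_snvs_per_exon = allelic_snvs_per_exon,
    planted_genotype = planted_genotype, read_length = as.integer(read_length),
    long_read_length = as.integer(long_read_length),
    insert_mean = insert_mean, insert_sd = insert_sd, mean_depth = mean_depth,
    error_rate = error_rate, seed = as.integer(seed)), class = "SimSpec")
}

.BASES <- c("A", "C", "G", "T")

.mutate_positions <- function(chars, idx) {
  if (!length(idx)) return(chars)
  cur <- chars[idx]
  repl <- vapply(cur, function(b) sample(setdiff(.BASES, b), 1L), character(1))
  chars[idx] <- repl
  chars
}

#' Simulate a paralogous gene family with a planted diploid genotype
#'
#' An ancestral locus is drawn uniformly at random; each paralog derives from
#' it by independent per-base substitution at half the target divergence, so
#' the realized pairwise divergence between paralogs matches the target
#' (enforced to within 25\%, exons and introns mutated alike). Allele pools
#' place Poisson-distributed SNVs in each exon. The genome is the
#' concatenation of the paralog loci on one chromosome; the two haplotype
#' genomes realize the planted genotype by substituting each gene's planted
#' allele exons.
#'
#' @param spec a \code{\link{simSpec}}
#' @return \code{\link{SimTruth}}
#' @export
simulateFamily <- function(spec) {
  set.seed(spec$seed)
  ex_l <- spec$exon_lengths; in_l <- spec$intron_lengths
  fl <- spec$flank_length
  L <- 2L * fl + sum(ex_l) + sum(in_l)
  # exon start offsets within a locus
  ex_start <- integer(length(ex_l)); off <- fl
  for (i in seq_along(ex_l)) {
    ex_start[i] <- off + 1L
    off <- off + ex_l[i] + if (i < length(ex_l)) in_l[i] else 0L
  }
  ex_end <- ex_start + ex_l - 1L
  ex_idx <- unlist(mapply(seq, ex_start, ex_end, SIMPLIFY = FALSE))
  labels <- paste0("exon", seq_along(ex_l) + 1L)

  ancestor <- sample(.BASES, L, replace = TRUE)
  q <- spec$paralog_divergence / 2
  genes <- sprintf("MHC-%d", seq_len(spec$n_paralogs))
  lo <- spec$paralog_divergence * 0.75; hi <- spec$paralog_divergence * 1.25
  for (attempt in 1:50) {
    loci <- lapply(seq_len(spec$n_paralogs), function(p)
      .mutate_positions(ancestor, which(stats::runif(L) < q)))
    if (spec$n_paralogs == 1L) break
    dv <- utils::combn(spec$n_paralogs, 2, function(pr)
      mean(loci[[pr[1]]][ex_idx] != loci[[pr[2]]][ex_idx]))
    if (all(dv >= lo & dv <= hi)) break
    if (attempt == 50) stop("could not realize target paralog divergence")
  }
  realized_div <- if (spec$n_paralogs > 1L) mean(dv) else 0

  chrom <- "chrSim"
  genome_chars <- unlist(loci)
  genome <- DNAStringSet(paste(genome_chars, collapse = ""))
  names(genome) <- chrom
  offs <- (seq_len(spec$n_paralogs) - 1L) * L

  cfg <- lapply(seq_len(spec$n_paralogs), function(p) {
    ex <- stats::setNames(lapply(seq_along(ex_l), function(i)
      c(offs[p] + ex_start[i], offs[p] + ex_end[i])), labels)
    list(chrom = chrom, strand = "+", exons = ex)
  })
  names(cfg) <- genes
  targets <- mhcTargets(cfg)

  # allele pools: exon-concatenated sequences with exon-concentrated SNVs
  allele_names <- character(0); allele_gene <- character(0)
  allele_seq <- character(0); exons_list <- list()
  w <- ex_l; en <- cumsum(w)
  span_df <- data.frame(exon = labels, start = as.integer(en - w + 1L),
                        end = as.integer(en), stringsAsFactors = FALSE)
  allele_exons <- list()  # per allele: list of exon char vectors
  for (p in seq_len(spec$n_paralogs)) {
    base_ex <- lapply(seq_along(ex_l), function(i)
      loci[[p]][ex_start[i]:ex_end[i]])
    for (j in seq_len(spec$alleles_per_gene)) {
      exs <- lapply(base_ex, function(e) {
        k <- stats::rpois(1L, spec$allelic_snvs_per_exon)
        .mutate_positions(e, sample(length(e), min(k, length(e))))
      })
      nm <- sprintf("%s*%02d:01", genes[p], j)
      allele_names <- c(allele_names, nm)
      allele_gene <- c(allele_gene, genes[p])
      allele_seq <- c(allele_seq, paste(unlist(exs), collapse = ""))
      exons_list[[length(exons_list) + 1L]] <- span_df
      allele_exons[[nm]] <- exs
    }
  }
  seqs <- DNAStringSet(allele_seq); names(seqs) <- allele_names
  db <- new("AlleleDb", sequences = seqs, gene = allele_gene,
            exons = exons_list, isComplete = rep(TRUE, length(seqs)),
            donor = rep(NA_character_, length(seqs)),
            paralogs = stats::setNames(lapply(genes, function(g)
              setdiff(genes, g)), genes))

  genotype <- spec$planted_genotype
  if (is.null(genotype)) {
    genotype <- stats::setNames(lapply(genes, function(g)
      sort(sample(allele_names[allele_gene == g], 2L, replace = TRUE))),
      genes)
  } else {
    stopifnot(setequal(names(genotype), genes))
    genotype <- lapply(genotype, function(x) sort(as.character(x)))
  }

  # haplotype genomes realizing the planted genotype
  haps <- list(genome_chars, genome_chars)
  for (p in seq_len(spec$n_paralogs)) {
    for (h in 1:2) {
      exs <- allele_exons[[genotype[[genes[p]]][h]]]
      for (i in seq_along(ex_l)) {
        at <- offs[p] + (ex_start[i]:ex_end[i])
        haps[[h]][at] <- exs[[i]]
      }
    }
  }
  hap_set <- DNAStringSet(vapply(haps, paste, character(1), collapse = ""))
  names(hap_set) <- c("hap1", "hap2")

  diff_pos <- which(haps[[1]] != genome_chars | haps[[2]] != genome_chars)
  tv <- data.frame(chrom = rep(chrom, length(diff_pos)), pos = diff_pos,
                   ref = genome_chars[diff_pos],
                   hap1 = haps[[1]][diff_pos], hap2 = haps[[2]][diff_pos],
                   gene = genes[findInterval(diff_pos - 1L, offs)],
                   stringsAsFactors = FALSE)

  spec_out <- unclass(spec)
  spec_out$realized_divergence <- realized_div
  spec_out$locus_length <- L
  new("SimTruth", genome = genome, targets = targets, db = db,
      genotype = genotype, haplotypes = hap_set, truthVariants = tv,
      spec = spec_out)
}

.const_qual <- function(n, q = 35L) {
  strrep(intToUtf8(33L + q), n)
}

#' Simulate mapped reads from the planted diploid
#'
#' Fragments are sampled uniformly from each haplotype of every gene locus at
#' the stated mean diploid depth, substitution errors applied per base, and
#' emitted as alignment records at their true positions. In
#' \code{cross_mapped} mode every read — whichever paralog it came from — is
#' placed at the equivalent offset of the target gene's locus, emulating
#' mapper confusion between near-identical paralogs (the failure mode the
#' read filter corrects). Short mode emits proper pairs; long mode emits
#' single long reads.
#'
#' @param truth \code{\link{SimTruth}}
#' @param mode "short_pe" or "long"
#' @param depth,error_rate override the spec's values
#' @param cross_mapped place all paralog reads on the target gene's locus
#' @param target_gene target of cross-mapping (default: first gene)
#' @param seed seed for read sampling (default: spec seed + 1000)
#' @return list: \code{reads} (coordinate-sorted read data.frame with
#'   origin_gene/origin_hap columns) and \code{origins} (read_id, gene, hap)
#' @export
simulateReads <- function(truth, mode = c("short_pe", "long"), depth = NULL,
                          error_rate = NULL, cross_mapped = FALSE,
                          target_gene = NULL, seed = NULL) {
  mode <- match.arg(mode)
  spec <- truth@spec
  if (is.null(depth)) depth <- spec$mean_depth
  if (is.null(error_rate)) error_rate <- spec$error_rate
  if (is.null(seed)) seed <- spec$seed + 1000L
  set.seed(seed)
  genes <- targetGenes(truth@targets)
  if (is.null(target_gene)) target_gene <- genes[1]
  L <- spec$locus_length
  offs <- stats::setNames((seq_along(genes) - 1L) * L, genes)
  place_off <- if (cross_mapped) rep(offs[[target_gene]], length(genes)) else offs
  names(place_off) <- genes
  hap_chars <- lapply(seq_len(2L), function(h)
    strsplit(as.character(truth@haplotypes[[h]]), "")[[1]])

  with_errors <- function(chars) {
    idx <- which(stats::runif(length(chars)) < error_rate)
    .mutate_positions(chars, idx)
  }

  rows <- list(); orig <- list()
  for (g in genes) {
    for (h in 1:2) {
      hs <- hap_chars[[h]]
      lo <- offs[[g]]
      if (mode == "long") {
        rl <- min(spec$long_read_length, L)
        n <- max(1L, round(depth / 2 * L / rl))
        starts <- sample.int(L - rl + 1L, n, replace = TRUE)
        for (i in seq_len(n)) {
          s <- starts[i]
          chars <- with_errors(hs[(lo + s):(lo + s + rl - 1L)])
          id <- sprintf("L_%s_h%d_%05d", g, h, i)
          rows[[length(rows) + 1L]] <- data.frame(
            read_id = id, flag = 0L, chrom = names(truth@genome)[1],
            pos = place_off[[g]] + s, mapq = 60L,
            cigar = sprintf("%dM", rl), seq = paste(chars, collapse = ""),
            qual = .const_qual(rl, 30L), rnext = "*", pnext = 0L, tlen = 0L,
            origin_gene = g, origin_hap = h, stringsAsFactors = FALSE)
          orig[[length(orig) + 1L]] <- data.frame(
            read_id = id, gene = g, hap = h, stringsAsFactors = FALSE)
        }
      } else {
        rl <- spec$read_length
        n <- max(1L, round(depth / 2 * L / (2L * rl)))
        fr <- pmin(pmax(round(stats::rnorm(n, spec$insert_mean,
                                           spec$insert_sd)), 2L * rl), L)
        starts <- vapply(fr, function(f)
          sample.int(L - f + 1L, 1L), integer(1))
        for (i in seq_len(n)) {
          s <- starts[i]; f <- fr[i]
          id <- sprintf("S_%s_h%d_%05d", g, h, i)
          p1 <- s; p2 <- s + f - rl
          c1 <- with_errors(hs[(lo + p1):(lo + p1 + rl - 1L)])
          c2 <- with_errors(hs[(lo + p2):(lo + p2 + rl - 1L)])
          g1 <- place_off[[g]] + p1; g2 <- place_off[[g]] + p2
          rows[[length(rows) + 1L]] <- data.frame(
            read_id = c(id, id), flag = c(99L, 147L),
            chrom = names(truth@genome)[1], pos = c(g1, g2), mapq = 60L,
            cigar = sprintf("%dM", rl),
            seq = c(paste(c1, collapse = ""), paste(c2, collapse = "")),
            qual = .const_qual(rl, 35L), rnext = "=", pnext = c(g2, g1),
            tlen = c(f, -f), origin_gene = g, origin_hap = h,
            stringsAsFactors = FALSE)
          orig[[length(orig) + 1L]] <- data.frame(
            read_id = id, gene = g, hap = h, stringsAsFactors = FALSE)
        }
      }
    }
  }
  reads <- do.call(rbind, rows)
  reads <- reads[order(reads$pos, reads$read_id), , drop = FALSE]
  rownames(reads) <- NULL
  list(reads = reads, origins = do.call(rbind, orig))
}

#' Planted variant calls of a simulated truth, as a phased call table
#'
#' Heterozygous planted sites are phased by construction (one block per gene,
#' PS = the gene's leftmost het position); homozygous-alt sites carry 1/1.
#' Useful for exercising contig building and genotyping without reads.
#'
#' @param truth \code{\link{SimTruth}}
#' @return variant call data.frame with phasing columns
#' @export
plantedCalls <- function(truth) {
  tv <- truth@truthVariants
  if (!nrow(tv))
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), gt = character(), ad = character(),
                      dp = integer(), qual = numeric(), phased = logical(),
                      ps = integer(), hap1 = integer(), hap2 = integer(),
                      stringsAsFactors = FALSE))
  out <- lapply(seq_len(nrow(tv)), function(i) {
    alts <- unique(c(tv$hap1[i], tv$hap2[i]))
    alts <- alts[alts != tv$ref[i]]
    idx <- function(b) if (b == tv$ref[i]) 0L else match(b, alts)
    h1 <- idx(tv$hap1[i]); h2 <- idx(tv$hap2[i])
    het <- h1 != h2
    data.frame(chrom = tv$chrom[i], pos = tv$pos[i], ref = tv$ref[i],
               alt = paste(alts, collapse = ","),
               gt = paste(min(h1, h2), max(h1, h2), sep = "/"),
               ad = paste(rep(10L, 1L + length(alts)), collapse = ","),
               dp = 20L, qual = 100, phased = het,
               ps = NA_integer_, hap1 = if (het) h1 else NA_integer_,
               hap2 = if (het) h2 else NA_integer_, stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, out)
  for (g in unique(tv$gene)) {
    rows <- which(tv$gene == g & calls$phased)
    if (length(rows)) calls$ps[rows] <- min(calls$pos[rows])
  }
  calls
}

#' Write a complete simulation to disk in pipeline-ready formats
#'
#' Genome FASTA, per-gene allele FASTAs (reference-directory layout), target
#' config YAML, planted phased VCF, reads as SAM, origin labels TSV and a
#' JSON echo of the spec.
#'
#' @param truth \code{\link{SimTruth}}
#' @param sim result of \code{\link{simulateReads}} (or NULL to skip reads)
#' @param dir output directory (created)
#' @return invisibly, \code{dir}
#' @export
writeSimulation <- function(truth, sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(truth@genome, file.path(dir, "genome.fa"))
  ref_dir <- file.path(dir, "alleles")
  dir.create(ref_dir, showWarnings = FALSE)
  for (g in targetGenes(truth@targets)) {
    Biostrings::writeXStringSet(geneAlleles(truth@db, g),
                                file.path(ref_dir, paste0(g, ".fa")))
  }
  writeTargetConfig(truth@targets, file.path(dir, "config.yaml"))
  chrlen <- stats::setNames(Biostrings::width(truth@genome),
                            names(truth@genome))
  writeVcfFile(plantedCalls(truth), file.path(dir, "truth.vcf"), chrlen)
  if (!is.null(sim)) {
    writeSam(sim$reads, chrlen, file.path(dir, "reads.sam"))
    utils::write.table(sim$origins, file.path(dir, "origins.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(truth@spec, file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
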