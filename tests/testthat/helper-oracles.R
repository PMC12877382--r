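# Independent oracles, deliberately written with different algorithms /
# code paths than the package internals they validate.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# Reference affine-gap local alignment score by a plain-R Gotoh DP
# (full matrices, explicit loops; N mismatches everything).
ref_local_score <- function(q, s, match = 2, mismatch = -3, gap_open = 5,
                            gap_ext = 2) {
  qc <- strsplit(q, "")[[1]]; sc <- strsplit(s, "")[[1]]
  n <- length(qc); m <- length(sc)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sub <- if (qc[i - 1] == sc[j - 1] && qc[i - 1] %in% BASES) match else mismatch
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_ext, E[i, j - 1] - gap_ext)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_ext, F[i - 1, j] - gap_ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

revcomp_chr <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# Exhaustive MEC by explicit enumeration with per-fragment loops.
# frag: integer matrix fragments x sites, entries 0/1/NA.
ref_mec <- function(frag) {
  k <- ncol(frag)
  best <- Inf
  grid <- expand.grid(rep(list(0:1), k - 1))
  for (r in seq_len(nrow(grid))) {
    hap1 <- c(0L, as.integer(grid[r, ]))
    hap2 <- 1L - hap1
    tot <- 0
    for (f in seq_len(nrow(frag))) {
      obs <- frag[f, ]
      cov <- which(!is.na(obs))
      if (!length(cov)) next
      m1 <- sum(obs[cov] != hap1[cov])
      m2 <- sum(obs[cov] != hap2[cov])
      tot <- tot + min(m1, m2)
    }
    best <- min(best, tot)
  }
  best
}

# random fragment matrix over k het sites: contiguous-window fragments from a
# planted haplotype with flip noise
rand_fragment_matrix <- function(k, n_frag, flip = 0.1) {
  hap <- sample(0:1, k, replace = TRUE)
  M <- matrix(NA_integer_, n_frag, k)
  for (f in seq_len(n_frag)) {
    a <- sample.int(k, 1)
    b <- min(k, a + sample.int(max(1L, k - 1L), 1))
    obs <- if (runif(1) < 0.5) hap[a:b] else 1L - hap[a:b]
    noise <- runif(b - a + 1) < flip
    obs[noise] <- 1L - obs[noise]
    M[f, a:b] <- obs
  }
  M
}

# Brute-force two-round allele-pair determination from a score table
# (columns allele, block, hap, bits): written with naive loops, independent
# of callGenotype(). Implements the same rules: per-(allele, block) best
# contig with ties to hap 1; round-1 argmax on 2-dp-rounded totals with the
# ambiguity group restricted to the representative's contig-choice cohort;
# round 2 on the contigs the representative did not consume (single-contig
# blocks and block 0 reusable).
ref_two_round <- function(scores) {
  alleles <- sort(unique(scores$allele))
  blocks <- sort(unique(scores$block))
  hblocks <- blocks[blocks > 0]
  pick <- function(a, b) {
    sub <- scores[scores$allele == a & scores$block == b, ]
    sub <- sub[order(sub$hap), ]
    sub[which.max(round(sub$bits, 2)), ]
  }
  tot1 <- sapply(alleles, function(a) {
    s <- 0
    for (b in blocks) s <- s + pick(a, b)$bits
    s
  })
  g1 <- sort(alleles[round(tot1, 2) == max(round(tot1, 2))])
  rep1 <- g1[1]
  if (length(g1) > 1 && length(hblocks)) {
    ch <- function(a) sapply(hblocks, function(b) pick(a, b)$hap)
    g1 <- g1[sapply(g1, function(a) identical(ch(a), ch(rep1)))]
  }
  consumed <- sapply(hblocks, function(b) pick(rep1, b)$hap)
  tot2 <- sapply(alleles, function(a) {
    s <- 0
    for (bi in seq_along(hblocks)) {
      b <- hblocks[bi]
      haps <- sort(unique(scores$hap[scores$block == b]))
      h <- if (length(haps) > 1) setdiff(haps, consumed[bi]) else haps
      s <- s + scores$bits[scores$allele == a & scores$block == b &
                             scores$hap == h[1]]
    }
    if (0 %in% blocks)
      s <- s + scores$bits[scores$allele == a & scores$block == 0]
    s
  })
  g2 <- sort(alleles[round(tot2, 2) == max(round(tot2, 2))])
  list(g1 = g1, g2 = g2)
}

# fabricate a Contig List + scores attribute from a raw score table, the way
# buildContigList() structures its output
entries_from_scores <- function(scores) {
  scores$pident <- 100
  scores$n_ident <- as.integer(round(scores$bits))
  scores$aln_len <- as.integer(round(scores$bits))
  entries <- do.call(rbind, lapply(split(scores,
                                         paste(scores$allele, scores$block)),
    function(sub) {
      sub <- sub[order(sub$hap), ]
      best <- which.max(round(sub$bits, 2))
      e <- sub[best, , drop = FALSE]
      e$tie <- sum(round(sub$bits, 2) == round(sub$bits[best], 2)) > 1
      e
    }))
  rownames(entries) <- NULL
  attr(entries, "scores") <- scores
  entries
}

# a tiny in-memory allele database over one or more genes
tiny_db <- function(seqs, gene = sub("\\*.*", "", names(seqs)),
                    exon_split = NULL) {
  ss <- Biostrings::DNAStringSet(seqs)
  exons <- lapply(seq_along(seqs), function(i) {
    L <- nchar(seqs[[i]])
    if (is.null(exon_split)) {
      data.frame(exon = "exon2", start = 1L, end = L)
    } else {
      w <- exon_split; en <- cumsum(w)
      data.frame(exon = paste0("exon", seq_along(w) + 1L),
                 start = as.integer(en - w + 1L), end = as.integer(en))
    }
  })
  genes <- unique(gene)
  methods::new("AlleleDb", sequences = ss, gene = gene, exons = exons,
               isComplete = rep(TRUE, length(ss)),
               donor = rep(NA_character_, length(ss)),
               paralogs = stats::setNames(lapply(genes, function(g)
                 setdiff(genes, g)), genes))
}

table1_path <- function() {
  system.file("extdata", "sla_typing_12pigs.tsv", package = "mhctyper")
}
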