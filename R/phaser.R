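# Read-backed phasing of heterozygous calls into haplotype blocks by MEC
# (minimum error correction). Blocks are connected components of the
# fragment-covers-both graph; the PS tag of a block is the position of its
# leftmost variant (WhatsHap convention).

#' Build the fragment matrix over heterozygous sites
#'
#' One fragment per read (read pairs merged by name); entry = observed allele
#' index at each covered het site, or NA when the read base matches neither
#' REF nor an ALT, fails the base-quality floor, or the two mates disagree.
#' SNV alleles are read off aligned bases; indel alleles are observed via
#' CIGAR I/D events anchored at the site. Fragments covering fewer than two
#' sites carry no linkage information but still count toward MEC.
#'
#' @param reads read data.frame
#' @param calls variant call data.frame (\code{\link{callVariants}})
#' @param min_baseq base-quality floor for SNV observations
#' @param min_mapq MAPQ floor for fragments
#' @return integer matrix fragments x het sites (colnames = positions), NA
#'   for uncovered sites; attribute "het_idx" maps columns to rows of calls
#' @export
buildFragments <- function(reads, calls, min_baseq = 13L, min_mapq = 20L) {
  het_idx <- which(vapply(strsplit(calls$gt, "/"), function(g)
    g[1] != g[2], logical(1)))
  het <- calls[het_idx, , drop = FALSE]
  k <- nrow(het)
  rs <- reads[isPrimaryRecord(reads$flag) & reads$mapq >= min_mapq, ,
              drop = FALSE]
  frag_names <- unique(rs$read_id)
  M <- matrix(NA_integer_, nrow = length(frag_names), ncol = k,
              dimnames = list(frag_names, if (k) het$pos else NULL))
  if (!k || !nrow(rs)) {
    attr(M, "het_idx") <- het_idx
    return(M)
  }
  alt_list <- strsplit(het$alt, ",")
  is_snv <- nchar(het$ref) == 1L &
    vapply(alt_list, function(a) all(nchar(a) == 1L), logical(1))
  conflict <- matrix(FALSE, nrow = length(frag_names), ncol = k)

  ops_all <- explodeCigarOps(rs$cigar)
  lens_all <- explodeCigarOpLengths(rs$cigar)
  ends <- readRefEnd(rs)
  for (i in seq_len(nrow(rs))) {
    covered <- which(het$pos >= rs$pos[i] & het$pos <= ends[i] &
                       het$chrom == rs$chrom[i])
    if (!length(covered)) next
    f <- match(rs$read_id[i], frag_names)
    bases <- strsplit(rs$seq[i], "")[[1]]
    quals <- utf8ToInt(rs$qual[i]) - 33L
    ops <- ops_all[[i]]; lens <- lens_all[[i]]
    # walk CIGAR once, recording query offset of each covered ref position
    # and any indel event anchored there
    rpos <- rs$pos[i]; qpos <- 1L
    qat <- rep(NA_integer_, length(covered))      # query pos of site base
    ev <- rep("", length(covered))                # indel event at site anchor
    for (j in seq_along(ops)) {
      op <- ops[j]; ln <- lens[j]
      if (op %in% c("M", "=", "X")) {
        hit <- which(het$pos[covered] >= rpos & het$pos[covered] <= rpos + ln - 1L)
        if (length(hit)) qat[hit] <- qpos + (het$pos[covered][hit] - rpos)
        rpos <- rpos + ln; qpos <- qpos + ln
      } else if (op == "I") {
        hit <- which(het$pos[covered] == rpos - 1L)
        if (length(hit))
          ev[hit] <- paste0("I", paste(bases[qpos:(qpos + ln - 1L)], collapse = ""))
        qpos <- qpos + ln
      } else if (op == "D" || op == "N") {
        hit <- which(het$pos[covered] == rpos - 1L)
        if (length(hit) && op == "D") ev[hit] <- paste0("D", ln)
        rpos <- rpos + ln
      } else if (op == "S") {
        qpos <- qpos + ln
      }
    }
    for (u in seq_along(covered)) {
      s <- covered[u]
      obs <- NA_integer_
      if (is_snv[s]) {
        if (!is.na(qat[u]) && quals[qat[u]] >= min_baseq && ev[u] == "") {
          b <- bases[qat[u]]
          if (b == het$ref[s]) obs <- 0L
          else {
            m <- match(b, alt_list[[s]])
            if (!is.na(m)) obs <- m
          }
        }
      } else {
        # indel site: alleles distinguished by presence/shape of the event
        want <- vapply(alt_list[[s]], function(a) {
          if (nchar(a) > nchar(het$ref[s]))
            paste0("I", substr(a, nchar(het$ref[s]) + 1L, nchar(a)))
          else paste0("D", nchar(het$ref[s]) - nchar(a))
        }, character(1))
        if (ev[u] != "") {
          m <- match(ev[u], want)
          if (!is.na(m)) obs <- m
        } else if (!is.na(qat[u])) {
          obs <- 0L  # aligned straight through the anchor: reference allele
        }
      }
      if (!is.na(obs)) {
        prev <- M[f, s]
        if (is.na(prev)) M[f, s] <- obs
        else if (prev != obs) conflict[f, s] <- TRUE  # mates disagree
      }
    }
  }
  M[conflict] <- NA_integer_
  attr(M, "het_idx") <- het_idx
  M
}

# MEC of one orientation vector over a +/-1/0 encoded fragment matrix
.mec_of <- function(Fs, sigma) {
  agree <- Fs %*% sigma
  covered <- rowSums(abs(Fs))
  mism <- (covered - agree) / 2
  sum(pmin(mism, covered - mism))
}

# exhaustive MEC over 2^(k-1) orientations via one matrix product
.mec_exhaustive <- function(Fs) {
  k <- ncol(Fs)
  n_assign <- 2^(k - 1)
  bits <- t(vapply(0:(n_assign - 1), function(m)
    c(1, ifelse(bitwAnd(m, 2^(seq_len(k - 1) - 1)) > 0, -1, 1)),
    numeric(k)))
  A <- Fs %*% t(bits)                       # fragments x assignments
  covered <- rowSums(abs(Fs))
  mism <- (covered - A) / 2
  errs <- pmin(mism, covered - mism)
  mec <- colSums(errs)
  best <- which.min(mec)                    # first minimum: deterministic
  list(sigma = bits[best, ], mec = mec[best])
}

# greedy position sweep by accumulated linkage, then hill climbing over
# single-site flips and suffix flips (switch errors)
.mec_greedy <- function(Fs) {
  k <- ncol(Fs)
  sigma <- numeric(k); sigma[1] <- 1
  for (s in 2:k) {
    link <- sum(Fs[, s] * (Fs[, seq_len(s - 1), drop = FALSE] %*%
                             sigma[seq_len(s - 1)]))
    sigma[s] <- if (link >= 0) 1 else -1
  }
  cur <- .mec_of(Fs, sigma)
  repeat {
    improved <- FALSE
    for (s in seq_len(k)) {
      cand <- sigma; cand[s] <- -cand[s]
      m <- .mec_of(Fs, cand)
      if (m < cur) { sigma <- cand; cur <- m; improved <- TRUE }
    }
    for (s in 2:k) {
      cand <- sigma; cand[s:k] <- -cand[s:k]
      m <- .mec_of(Fs, cand)
      if (m < cur) { sigma <- cand; cur <- m; improved <- TRUE }
    }
    if (!improved) break
  }
  if (sigma[1] < 0) sigma <- -sigma
  list(sigma = sigma, mec = cur)
}

#' Phase heterozygous variants into haplotype blocks by MEC
#'
#' Builds the connectivity graph over het sites (edge when at least one
#' fragment covers both), takes connected components as blocks, and within
#' each block chooses the haplotype orientation minimizing MEC — exhaustively
#' over \eqn{2^{k-1}} orientations for blocks of up to \code{exhaustive_max}
#' sites, otherwise by a greedy linkage sweep refined with single-flip and
#' suffix-flip hill climbing. Unlinked het sites become singleton blocks
#' (arbitrary orientation, flagged). Homozygous-alt calls are not block
#' members. PS = position of the leftmost variant in the block.
#'
#' @param calls variant call data.frame
#' @param fragments fragment matrix from \code{\link{buildFragments}}
#' @param exhaustive_max largest block size phased exhaustively (default 15)
#' @return list: \code{calls} (input plus columns phased, ps, hap1, hap2) and
#'   \code{blocks} (data.frame block_id, n_variants, mec, singleton)
#' @export
phaseVariants <- function(calls, fragments, exhaustive_max = 15L) {
  het_idx <- attr(fragments, "het_idx")
  k <- ncol(fragments)
  calls$phased <- FALSE
  calls$ps <- NA_integer_
  calls$hap1 <- NA_integer_
  calls$hap2 <- NA_integer_
  blocks <- data.frame(block_id = integer(), n_variants = integer(),
                       mec = numeric(), singleton = logical())
  if (!k) return(list(calls = calls, blocks = blocks))

  het <- calls[het_idx, , drop = FALSE]
  gt_alleles <- strsplit(het$gt, "/")
  a_lo <- as.integer(vapply(gt_alleles, `[`, character(1), 1))
  a_hi <- as.integer(vapply(gt_alleles, `[`, character(1), 2))

  # union-find over sites linked by a shared fragment
  parent <- seq_len(k)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (f in seq_len(nrow(fragments))) {
    cov <- which(!is.na(fragments[f, ]))
    if (length(cov) > 1)
      for (s in cov[-1]) {
        ra <- find(cov[1]); rb <- find(s)
        if (ra != rb) parent[rb] <- ra
      }
  }
  comp <- vapply(seq_len(k), find, integer(1))

  # encode observations relative to the site's two genotype alleles:
  # +1 = lower allele index, -1 = higher, 0 = other/missing
  enc <- matrix(0, nrow = nrow(fragments), ncol = k)
  for (s in seq_len(k)) {
    enc[, s] <- ifelse(is.na(fragments[, s]), 0,
                       ifelse(fragments[, s] == a_lo[s], 1,
                              ifelse(fragments[, s] == a_hi[s], -1, 0)))
  }

  for (root in unique(comp)) {
    sites <- which(comp == root)
    kk <- length(sites)
    ps_val <- min(het$pos[sites])
    if (kk == 1L) {
      sol <- list(sigma = 1, mec = 0)
    } else {
      Fs <- enc[rowSums(abs(enc[, sites, drop = FALSE])) > 0, sites,
                drop = FALSE]
      sol <- if (kk <= exhaustive_max) .mec_exhaustive(Fs) else .mec_greedy(Fs)
    }
    rows <- het_idx[sites]
    calls$phased[rows] <- TRUE
    calls$ps[rows] <- ps_val
    calls$hap1[rows] <- ifelse(sol$sigma > 0, a_lo[sites], a_hi[sites])
    calls$hap2[rows] <- ifelse(sol$sigma > 0, a_hi[sites], a_lo[sites])
    blocks <- rbind(blocks, data.frame(
      block_id = ps_val, n_variants = kk, mec = sol$mec, singleton = kk == 1L))
  }
  blocks <- blocks[order(blocks$block_id), , drop = FALSE]
  rownames(blocks) <- NULL
  list(calls = calls, blocks = blocks)
}
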