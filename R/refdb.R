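#' Construct a target/paralog configuration in memory
#'
#' @param genes named list; each element is a list with \code{chrom},
#'   \code{exons} (named list of \code{c(start, end)} 1-based inclusive
#'   genomic intervals, in exon order), optional \code{strand} ("+" default)
#'   and optional \code{paralogs} (character vector; defaults to all other
#'   configured genes)
#' @return \code{\link{MhcTargets}}
#' @export
mhcTargets <- function(genes) {
  stopifnot(is.list(genes), length(genes) >= 1, !is.null(names(genes)))
  grl <- list(); paralogs <- list(); labels <- list()
  for (g in names(genes)) {
    cfg <- genes[[g]]
    ex <- cfg$exons
    if (is.null(ex) || !length(ex)) stop("gene ", g, ": no exon intervals")
    st <- vapply(ex, function(v) as.integer(v[1]), integer(1))
    en <- vapply(ex, function(v) as.integer(v[2]), integer(1))
    o <- order(st)
    gr <- GRanges(cfg$chrom, IRanges(st[o], en[o]),
                  strand = if (is.null(cfg$strand)) "+" else cfg$strand)
    mcols(gr)$gene <- g
    mcols(gr)$exon <- names(ex)[o]
    grl[[g]] <- gr
    labels[[g]] <- names(ex)
    if (!is.null(cfg$paralogs)) paralogs[[g]] <- as.character(cfg$paralogs)
  }
  regions <- suppressWarnings(do.call(c, unname(grl)))
  new("MhcTargets", regions = regions, paralogs = paralogs, exonLabels = labels)
}

#' Read a target-region/paralog configuration file (YAML)
#'
#' The file has one section per gene under a top-level \code{genes} key:
#' chromosome, strand, named exon intervals (1-based inclusive), and an
#' optional paralog list. When \code{paralogs} is omitted for a gene, all
#' other configured genes form its paralog group.
#'
#' @param path YAML file
#' @return \code{\link{MhcTargets}}
#' @export
readTargetConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$genes)) stop("config has no 'genes' section: ", path)
  mhcTargets(cfg$genes)
}

#' Write a target configuration as YAML
#' @param targets \code{\link{MhcTargets}}
#' @param path output file
#' @return invisibly, the path
#' @export
writeTargetConfig <- function(targets, path) {
  out <- list(genes = list())
  for (g in targetGenes(targets)) {
    r <- exonRegions(targets, g)
    ex <- stats::setNames(
      lapply(seq_along(r), function(i) c(start(r)[i], end(r)[i])),
      mcols(r)$exon)
    out$genes[[g]] <- list(chrom = as.character(seqnames(r))[1],
                           strand = targetStrand(targets, g), exons = ex,
                           paralogs = paralogsOf(targets, g))
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

# Determine which expected exons an allele sequence carries, from its length.
# With an explicit sidecar (character vector of exon labels) the answer is
# given; otherwise the sequence length must match the width-sum of exactly one
# subset of the expected exons.
.infer_exons <- function(len, widths, labels, sidecar = NULL, allele = "?") {
  if (!is.null(sidecar)) {
    bad <- setdiff(sidecar, labels)
    if (length(bad)) stop("allele ", allele, ": unknown exon label(s) ",
                          paste(bad, collapse = ","))
    keep <- labels[labels %in% sidecar]
    if (sum(widths[match(keep, labels)]) != len)
      stop("allele ", allele, ": sequence length ", len,
           " does not match declared exons ", paste(keep, collapse = "+"))
    return(keep)
  }
  n <- length(labels)
  hits <- list()
  for (m in seq_len(2^n - 1)) {
    sel <- as.logical(bitwAnd(m, 2^(seq_len(n) - 1)))
    if (sum(widths[sel]) == len) hits[[length(hits) + 1L]] <- labels[sel]
  }
  if (length(hits) == 1L) return(hits[[1L]])
  stop("allele ", allele, ": cannot infer exon structure from length ", len,
       " (", length(hits), " matching exon subsets); provide a sidecar table")
}

.parse_fasta_gene <- function(headers) {
  nm <- sub("\\s.*$", "", headers)
  no_star <- !grepl("\\*", nm)
  if (any(no_star))
    stop("FASTA header(s) without 'GENE*allele' shape: ",
         paste(headers[no_star], collapse = ", "))
  nm
}

#' Load an MHC allele reference database
#'
#' Reads one or more multi-FASTA files of exon-only allele references
#' (IPD-style headers \code{>GENE*fields [description]}; text after the first
#' whitespace is ignored) and groups the alleles by gene. \code{path} may be a
#' single FASTA or a reference directory holding one \code{<gene>.fa[sta]}
#' per gene. The exon composition of each allele is taken from an optional
#' sidecar table (\code{<path>.exons.tsv} next to each FASTA, or the
#' \code{exon_table} argument: columns \code{allele}, \code{exon}) and
#' otherwise inferred from sequence length against the expected per-gene exon
#' widths in \code{targets}.
#'
#' @param path FASTA file or reference directory
#' @param targets \code{\link{MhcTargets}} supplying expected exon labels and
#'   widths per gene
#' @param exon_table optional data.frame (allele, exon) listing the exons
#'   present in partial alleles
#' @param verbose report per-gene allele counts
#' @return \code{\link{AlleleDb}}
#' @export
loadAlleleDb <- function(path, targets, exon_table = NULL, verbose = FALSE) {
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.(fa|fasta|fna)$", full.names = TRUE)
  } else path
  if (!length(files)) stop("no FASTA files found at ", path)
  seqs <- DNAStringSet()
  sidecars <- exon_table
  for (f in files) {
    s <- Biostrings::readDNAStringSet(f)
    names(s) <- .parse_fasta_gene(names(s))
    seqs <- c(seqs, s)
    sc <- paste0(tools::file_path_sans_ext(f), ".exons.tsv")
    if (file.exists(sc)) {
      sidecars <- rbind(sidecars,
                        utils::read.delim(sc, stringsAsFactors = FALSE))
    }
  }
  if (anyDuplicated(names(seqs)))
    stop("duplicate allele name(s): ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  if (any(Biostrings::width(seqs) == 0L))
    stop("empty sequence for allele(s): ",
         paste(names(seqs)[Biostrings::width(seqs) == 0L], collapse = ", "))
  chr <- as.character(seqs)
  bad <- grepl("[^ACGTN]", chr)
  if (any(bad))
    stop("degenerate bases other than N in allele(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  seqs <- DNAStringSet(toupper(chr)); names(seqs) <- .parse_fasta_gene(names(seqs))

  gene <- sub("\\*.*$", "", names(seqs))
  unknown <- setdiff(unique(gene), targetGenes(targets))
  if (length(unknown))
    stop("allele gene(s) not in target config: ", paste(unknown, collapse = ", "))

  exons <- vector("list", length(seqs))
  complete <- logical(length(seqs))
  for (i in seq_along(seqs)) {
    g <- gene[i]
    labels <- exonLabels(targets, g)
    widths <- width(exonRegions(targets, g))
    sc <- NULL
    if (!is.null(sidecars)) {
      rows <- sidecars$allele == names(seqs)[i]
      if (any(rows)) sc <- sidecars$exon[rows]
    }
    present <- .infer_exons(Biostrings::width(seqs)[i], widths, labels, sc,
                            names(seqs)[i])
    w <- widths[match(present, labels)]
    en <- cumsum(w)
    exons[[i]] <- data.frame(exon = present, start = en - w + 1L, end = en,
                             stringsAsFactors = FALSE)
    complete[i] <- length(present) == length(labels)
  }
  present <- unique(gene)
  db <- new("AlleleDb", sequences = seqs, gene = gene, exons = exons,
            isComplete = complete, donor = rep(NA_character_, length(seqs)),
            paralogs = stats::setNames(
              lapply(present, function(g)
                intersect(paralogsOf(targets, g), present)),
              present))
  if (verbose) {
    tab <- table(gene)
    message("loaded ", length(seqs), " allele(s): ",
            paste(sprintf("%s:%d", names(tab), tab), collapse = ", "))
  }
  db
}

#' Write an allele database back to multi-FASTA
#' @param db \code{\link{AlleleDb}}
#' @param path output FASTA
#' @return invisibly, the path
#' @export
writeAlleleDb <- function(db, path) {
  Biostrings::writeXStringSet(db@sequences, path)
  invisible(path)
}

.exon_seq <- function(db, i, label) {
  ex <- db@exons[[i]]
  j <- match(label, ex$exon)
  if (is.na(j)) return(NULL)
  substr(as.character(db@sequences[[i]]), ex$start[j], ex$end[j])
}

#' Patch partial alleles with exons from their most similar complete allele
#'
#' For every allele missing expected exons, the donor is the complete allele
#' of the same gene with the highest global-alignment percent identity over
#' the exons both carry (ties broken by lexicographically smallest donor
#' name). Missing exons are copied verbatim from the donor; the patched
#' allele keeps \code{isComplete = FALSE} and records its donor. Idempotent.
#'
#' @param db \code{\link{AlleleDb}}
#' @param targets \code{\link{MhcTargets}} (expected exon order per gene)
#' @return a completed \code{\link{AlleleDb}}
#' @export
completePartialAlleles <- function(db, targets) {
  nms <- names(db@sequences)
  seqs <- as.character(db@sequences)
  exons <- db@exons
  donor <- db@donor
  for (g in unique(db@gene)) {
    labels <- exonLabels(targets, g)
    idx <- which(db@gene == g)
    have_all <- vapply(idx, function(i) {
      all(labels %in% db@exons[[i]]$exon)
    }, logical(1))
    partial <- idx[!have_all]
    if (!length(partial)) next
    full <- idx[have_all & db@isComplete[idx]]
    if (!length(full))
      stop("gene ", g, " has partial allele(s) but no complete allele to patch from")
    full <- full[order(nms[full])]  # lexicographic tie-break
    for (p in partial) {
      shared_sets <- lapply(full, function(f)
        intersect(db@exons[[p]]$exon, db@exons[[f]]$exon))
      usable <- which(lengths(shared_sets) > 0)
      if (!length(usable))
        stop("allele ", nms[p], " shares no exon with any complete allele of ", g)
      pid <- vapply(usable, function(k) {
        f <- full[k]
        ps <- paste(vapply(shared_sets[[k]], function(l) .exon_seq(db, p, l),
                           character(1)), collapse = "")
        fs <- paste(vapply(shared_sets[[k]], function(l) .exon_seq(db, f, l),
                           character(1)), collapse = "")
        aln <- Biostrings::pairwiseAlignment(ps, fs, type = "global",
                                             substitutionMatrix = NULL)
        Biostrings::pid(aln)
      }, numeric(1))
      best <- usable[which.max(pid)]  # which.max keeps the first (smallest name)
      f <- full[best]
      donor[p] <- nms[f]
      pieces <- vapply(labels, function(l) {
        s <- .exon_seq(db, p, l)
        if (is.null(s)) s <- .exon_seq(db, f, l)
        s
      }, character(1))
      w <- nchar(pieces)
      en <- cumsum(w)
      seqs[p] <- paste(pieces, collapse = "")
      exons[[p]] <- data.frame(exon = labels, start = as.integer(en - w + 1L),
                               end = as.integer(en), stringsAsFactors = FALSE)
    }
  }
  out <- DNAStringSet(seqs); names(out) <- nms
  new("AlleleDb", sequences = out, gene = db@gene, exons = exons,
      isComplete = db@isComplete, donor = donor, paralogs = db@paralogs)
}

#' Extract the genomic sequence of a gene's exon envelope
#' @param genome DNAStringSet reference genome
#' @param targets \code{\link{MhcTargets}}
#' @param gene gene name
#' @param flank bases of flank to include on each side
#' @return character(1) sequence
#' @export
extractEnvelopeSeq <- function(genome, targets, gene, flank = 0L) {
  env <- geneEnvelope(targets, gene)
  chrom <- as.character(seqnames(env))
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  chrlen <- Biostrings::width(genome)[match(chrom, names(genome))]
  lo <- max(1L, start(env) - flank); hi <- min(chrlen, end(env) + flank)
  if (end(env) > chrlen) stop("region outside chromosome bounds for ", gene)
  substr(as.character(genome[[chrom]]), lo, hi)
}

#' Cross-check allele references against the genome's paralog regions
#'
#' Aligns every allele, exon by exon, against the extracted genomic region of
#' each configured gene and reports which region wins on bit score. On a
#' well-behaved reference every allele's own gene should win; paralogous
#' gene families at high similarity are exactly where this fails.
#'
#' @param db \code{\link{AlleleDb}}
#' @param genome DNAStringSet reference genome
#' @param targets \code{\link{MhcTargets}}
#' @param params \code{\link{ScoringParams}}
#' @param flank flank to include around each gene's exon envelope
#' @return data.frame: allele, gene, exon, best_region, bits, pident,
#'   own_region (logical), tie (logical)
#' @export
paralogCrossCheck <- function(db, genome, targets, params = scoringParams(),
                              flank = 50L) {
  genes <- targetGenes(targets)
  region_seq <- vapply(genes, function(g)
    extractEnvelopeSeq(genome, targets, g, flank), character(1))
  rows <- list()
  for (i in seq_along(db@sequences)) {
    ex <- db@exons[[i]]
    for (j in seq_len(nrow(ex))) {
      qs <- substr(as.character(db@sequences[[i]]), ex$start[j], ex$end[j])
      res <- lapply(region_seq, function(s) alignLocal(qs, s, params))
      bits <- vapply(res, `[[`, numeric(1), "bit_score")
      best <- which.max(bits)  # first maximum = config order tie-break
      tie <- sum(abs(bits - bits[best]) < 1e-9) > 1
      rows[[length(rows) + 1L]] <- data.frame(
        allele = names(db@sequences)[i], gene = db@gene[i], exon = ex$exon[j],
        best_region = genes[best], bits = bits[best],
        pident = res[[best]]$pident,
        own_region = genes[best] == db@gene[i], tie = tie,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Per gene/exon summary of a paralog cross-check
#' @param detail result of \code{\link{paralogCrossCheck}}
#' @return data.frame: gene, exon, n, n_own, frac_own
#' @export
summarizeCrossCheck <- function(detail) {
  agg <- stats::aggregate(own_region ~ gene + exon, data = detail,
                          FUN = function(x) c(n = length(x), own = sum(x)))
  data.frame(gene = agg$gene, exon = agg$exon,
             n = agg$own_region[, "n"], n_own = agg$own_region[, "own"],
             frac_own = agg$own_region[, "own"] / agg$own_region[, "n"],
             stringsAsFactors = FALSE)
}
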