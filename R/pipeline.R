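#' Run the full typing pipeline for one target gene
#'
#' Filter (paralog-aware, short-read data) -> diploid variant calling ->
#' read-backed phasing -> haplotype contig construction -> two-round
#' bit-score allele determination. Intermediates are written under
#' \code{output_dir} in the conventional layout
#' (\code{output_bam/output.filt.bam}, \code{output_vcf/tmp.output.vcf.gz},
#' \code{output_vcf/output.vcf}, \code{output.contig.fa}, a report TSV and a
#' JSON-lines manifest). Inputs can be file paths or in-memory objects.
#'
#' @param reads read data.frame, or path to a SAM/BAM file
#' @param genome DNAStringSet, or path to a genome FASTA
#' @param db \code{\link{AlleleDb}}, or path to a reference directory of
#'   per-gene allele FASTAs
#' @param targets \code{\link{MhcTargets}}, or path to a config YAML
#' @param target_gene gene to type
#' @param mode "short" or "long"
#' @param output_dir directory for intermediates (NULL: keep in memory only)
#' @param disable_read_filtering skip the paralog read filter; default TRUE
#'   in long mode (mapping of long reads is already locus-specific)
#' @param external_vcf optional phased VCF; skips calling and phasing
#' @param params \code{\link{ScoringParams}}
#' @param flank contig flank (bp)
#' @param thresholds caller threshold overrides
#' @return \code{\link{GenotypeCall}}; intermediates accessible via
#'   attributes "decisions", "calls", "blocks", "contigs"
#' @export
runPipeline <- function(reads, genome, db, targets, target_gene,
                        mode = c("short", "long"), output_dir = NULL,
                        disable_read_filtering = NULL, external_vcf = NULL,
                        params = scoringParams(), flank = 200L,
                        thresholds = list()) {
  mode <- match.arg(mode)
  if (is.null(disable_read_filtering)) disable_read_filtering <- mode == "long"
  if (is.character(targets)) targets <- readTargetConfig(targets)
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (is.character(db)) db <- loadAlleleDb(db, targets)
  if (is.character(reads)) reads <- readAlignments(reads)
  if (!target_gene %in% targetGenes(targets))
    stop("target gene not in config: ", target_gene)

  log_lines <- character(0)
  note <- function(stage, ...) {
    entry <- jsonlite::toJSON(c(list(stage = stage), list(...)),
                              auto_unbox = TRUE)
    log_lines <<- c(log_lines, as.character(entry))
  }
  out_file <- function(...) {
    p <- file.path(output_dir, ...)
    dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
    p
  }
  chrlen <- stats::setNames(Biostrings::width(genome), names(genome))

  env <- geneEnvelope(targets, target_gene)
  margin <- flank + 500L
  reads <- subsetReads(reads, as.character(seqnames(env)),
                       max(1L, start(env) - margin), end(env) + margin)
  note("extract", n_reads = nrow(reads))

  decisions <- NULL
  if (!disable_read_filtering) {
    fr <- filterReads(reads, db, target_gene, targets, params)
    decisions <- fr$decisions
    note("filter", n_in = nrow(reads), n_kept = nrow(fr$kept),
         n_removed = sum(!fr$decisions$kept))
    reads <- fr$kept
    if (!is.null(output_dir)) {
      writeSam(reads, chrlen, out_file("output_bam", "output.filt.bam"))
      writeFilterLog(decisions, out_file("output_bam", "filter_decisions.tsv"))
    }
  } else {
    note("filter", skipped = TRUE)
  }

  if (!is.null(external_vcf)) {
    phased <- readVcfCalls(external_vcf)
    blocks <- NULL
    note("variants", source = "external", n_calls = nrow(phased))
  } else {
    calls <- callVariants(reads, genome, env, mode, thresholds)
    note("call", n_variants = nrow(calls))
    if (!is.null(output_dir))
      writeVcfFile(calls, out_file("output_vcf", "tmp.output.vcf.gz"), chrlen)
    th <- utils::modifyList(callerThresholds(mode), thresholds)
    frags <- buildFragments(reads, calls, min_baseq = th$min_baseq,
                            min_mapq = th$min_mapq)
    ph <- phaseVariants(calls, frags)
    phased <- ph$calls; blocks <- ph$blocks
    note("phase", n_blocks = nrow(blocks),
         total_mec = if (nrow(blocks)) sum(blocks$mec) else 0)
    if (!is.null(output_dir))
      writeVcfFile(phased, out_file("output_vcf", "output.vcf"), chrlen)
  }

  contigs <- buildContigs(phased, genome, targets, target_gene, flank)
  note("contigs", n_contigs = length(contigs@sequences))
  if (!is.null(output_dir))
    writeContigFasta(contigs, out_file("output.contig.fa"))

  call <- genotypeGene(contigs, db, target_gene, params,
                       targets = targets, flank = flank)
  note("genotype",
       allele1 = paste(call@allele1Group, collapse = " or "),
       allele2 = paste(call@allele2Group, collapse = " or "))
  if (!is.null(output_dir)) {
    writeReport(list(call), out_file("output.report.tsv"))
    writeLines(log_lines, out_file("run_manifest.jsonl"))
  }
  attr(call, "decisions") <- decisions
  attr(call, "calls") <- phased
  attr(call, "blocks") <- blocks
  attr(call, "contigs") <- contigs
  call
}

#' Did a genotype call recover a planted allele pair?
#'
#' Recovery is exact up to exon-sequence ambiguity: each called group must
#' equal the set of reference alleles exon-identical to one planted allele,
#' with the two groups matching the planted pair in either order.
#'
#' @param call \code{\link{GenotypeCall}}
#' @param db \code{\link{AlleleDb}}
#' @param planted character(2) planted allele names
#' @return logical(1)
#' @export
genotypeRecovered <- function(call, db, planted) {
  e1 <- ambiguityGroupOf(db, planted[1])
  e2 <- ambiguityGroupOf(db, planted[2])
  (setequal(call@allele1Group, e1) && setequal(call@allele2Group, e2)) ||
    (setequal(call@allele1Group, e2) && setequal(call@allele2Group, e1))
}
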