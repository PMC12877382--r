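# Allele-call level concordance between two typing call sets (e.g., the NGS
# pipeline vs PCR sequence-based typing), with ambiguity groups compared as
# sets and the optimal pairing of the two unordered allele calls per
# sample/gene.

.normalize_group <- function(x) {
  x <- gsub("\\s+", " ", trimws(x))
  members <- trimws(strsplit(x, " or ", fixed = TRUE)[[1]])
  members <- sort(unique(members[nzchar(members)]))
  paste(members, collapse = " or ")
}

.group_set <- function(x) {
  m <- trimws(strsplit(gsub("\\s+", " ", trimws(x)), " or ", fixed = TRUE)[[1]])
  sort(unique(m[nzchar(m)]))
}

#' Load a typing truth table from TSV
#'
#' Expected columns: sample, gene, method, allele1, allele2. Ambiguity groups
#' use the literal separator \code{" or "} (case-sensitive); surrounding
#' whitespace is collapsed.
#'
#' @param path TSV file
#' @return data.frame with normalized group strings
#' @export
loadTruthTsv <- function(path) {
  tt <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("sample", "gene", "method", "allele1", "allele2")
  miss <- setdiff(need, names(tt))
  if (length(miss))
    stop("truth table missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(tt)) {
    tt$allele1 <- vapply(tt$allele1, .normalize_group, character(1))
    tt$allele2 <- vapply(tt$allele2, .normalize_group, character(1))
    key <- paste(tt$sample, tt$gene, tt$method)
    if (anyDuplicated(key))
      stop("duplicate (sample, gene, method) row(s): ",
           paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  rownames(tt) <- NULL
  tt
}

.calls_concordant <- function(g1, g2, rule) {
  s1 <- .group_set(g1); s2 <- .group_set(g2)
  if (rule == "exact_group") setequal(s1, s2) else length(intersect(s1, s2)) > 0
}

#' Allele-call concordance between two call sets
#'
#' For each (sample, gene) key present in both inputs the two unordered
#' allele-call pairs are matched under whichever of the two pairings yields
#' more concordant calls. Under \code{exact_group} two calls agree when their
#' ambiguity groups are identical as sets of allele names; under
#' \code{intersect} when the sets share at least one name. Per-gene totals
#' aggregate two calls per sample; percent is reported rounded half-up to an
#' integer.
#'
#' @param a,b truth-table data.frames (\code{\link{loadTruthTsv}} rows, one
#'   method each)
#' @param rule "exact_group" (default) or "intersect"
#' @return list with \code{summary} (gene, n_allele_calls, n_concordant,
#'   percent) and \code{detail} (per sample and gene)
#' @export
compareCalls <- function(a, b, rule = c("exact_group", "intersect")) {
  rule <- match.arg(rule)
  ka <- paste(a$sample, a$gene, sep = "\r")
  kb <- paste(b$sample, b$gene, sep = "\r")
  if (!setequal(ka, kb)) {
    miss <- c(setdiff(ka, kb), setdiff(kb, ka))
    stop("sample/gene keys differ between call sets: ",
         paste(gsub("\r", ":", unique(miss)), collapse = ", "))
  }
  b <- b[match(ka, kb), , drop = FALSE]
  n <- nrow(a)
  conc <- integer(n)
  for (i in seq_len(n)) {
    p1 <- .calls_concordant(a$allele1[i], b$allele1[i], rule) +
      .calls_concordant(a$allele2[i], b$allele2[i], rule)
    p2 <- .calls_concordant(a$allele1[i], b$allele2[i], rule) +
      .calls_concordant(a$allele2[i], b$allele1[i], rule)
    conc[i] <- max(p1, p2)
  }
  detail <- data.frame(sample = a$sample, gene = a$gene,
                       a1 = a$allele1, a2 = a$allele2,
                       b1 = b$allele1, b2 = b$allele2,
                       n_concordant = conc, stringsAsFactors = FALSE)
  genes <- unique(a$gene)
  summary <- do.call(rbind, lapply(genes, function(g) {
    rows <- detail$gene == g
    nc <- sum(detail$n_concordant[rows]); nt <- 2L * sum(rows)
    data.frame(gene = g, n_allele_calls = nt, n_concordant = nc,
               percent = floor(100 * nc / nt + 0.5),  # round half-up
               stringsAsFactors = FALSE)
  }))
  list(summary = summary, detail = detail)
}

#' Count distinct printed ambiguity groups per gene for one method
#'
#' The number of distinct allele calls (normalized group strings) observed
#' across both allele columns of one method's rows — the allele diversity a
#' typing table reports per locus.
#'
#' @param truth truth-table data.frame
#' @param method method name to count (e.g., the pipeline's rows)
#' @return named integer vector, one entry per gene
#' @export
alleleDiversity <- function(truth, method) {
  tt <- truth[truth$method == method, , drop = FALSE]
  if (!nrow(tt)) stop("no rows for method ", method)
  vapply(split(tt, tt$gene), function(d)
    length(unique(c(d$allele1, d$allele2))), integer(1))
}

#' Write concordance results to TSV files
#' @param res result of \code{\link{compareCalls}}
#' @param summary_path per-gene summary TSV
#' @param detail_path optional per-sample detail TSV
#' @return invisibly, \code{summary_path}
#' @export
writeConcordance <- function(res, summary_path, detail_path = NULL) {
  utils::write.table(res$summary, summary_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(detail_path))
    utils::write.table(res$detail, detail_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(summary_path)
}
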