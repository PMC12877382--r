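# Generics and accessors for the S4 containers. Slot access from user code
# should go through these.

#' @rdname AlleleDb-class
#' @param x an object
#' @export
setGeneric("alleleNames", function(x) standardGeneric("alleleNames"))
#' @rdname AlleleDb-class
#' @export
setGeneric("alleleGenes", function(x) standardGeneric("alleleGenes"))
#' @rdname AlleleDb-class
#' @export
setGeneric("alleleSeqs", function(x) standardGeneric("alleleSeqs"))
#' @rdname AlleleDb-class
#' @param gene gene name
#' @export
setGeneric("geneAlleles", function(x, gene) standardGeneric("geneAlleles"))
#' @rdname AlleleDb-class
#' @export
setGeneric("alleleCounts", function(x) standardGeneric("alleleCounts"))
#' @rdname AlleleDb-class
#' @export
setGeneric("isComplete", function(x) standardGeneric("isComplete"))
#' @rdname AlleleDb-class
#' @param allele full allele name
#' @export
setGeneric("alleleExonSpans", function(x, allele) standardGeneric("alleleExonSpans"))

#' @rdname MhcTargets-class
#' @param x an object
#' @export
setGeneric("targetGenes", function(x) standardGeneric("targetGenes"))
#' @rdname MhcTargets-class
#' @param gene gene name (NULL for all)
#' @export
setGeneric("exonRegions", function(x, gene = NULL) standardGeneric("exonRegions"))
#' @rdname MhcTargets-class
#' @export
setGeneric("paralogsOf", function(x, gene) standardGeneric("paralogsOf"))
#' @rdname MhcTargets-class
#' @export
setGeneric("geneEnvelope", function(x, gene) standardGeneric("geneEnvelope"))
#' @rdname MhcTargets-class
#' @export
setGeneric("exonLabels", function(x, gene) standardGeneric("exonLabels"))
#' @rdname MhcTargets-class
#' @export
setGeneric("targetStrand", function(x, gene) standardGeneric("targetStrand"))

#' @rdname HaplotypeContigs-class
#' @param x an object
#' @export
setGeneric("contigMeta", function(x) standardGeneric("contigMeta"))
#' @rdname HaplotypeContigs-class
#' @export
setGeneric("contigSeqs", function(x) standardGeneric("contigSeqs"))

#' @rdname GenotypeCall-class
#' @param x an object
#' @export
setGeneric("typedGene", function(x) standardGeneric("typedGene"))
#' @rdname GenotypeCall-class
#' @export
setGeneric("allele1Group", function(x) standardGeneric("allele1Group"))
#' @rdname GenotypeCall-class
#' @export
setGeneric("allele2Group", function(x) standardGeneric("allele2Group"))
#' @rdname GenotypeCall-class
#' @export
setGeneric("contigList", function(x) standardGeneric("contigList"))
#' @rdname GenotypeCall-class
#' @export
setGeneric("totalBits", function(x) standardGeneric("totalBits"))
#' @rdname GenotypeCall-class
#' @export
setGeneric("avgPident", function(x) standardGeneric("avgPident"))

#' @rdname SimTruth-class
#' @param x an object
#' @export
setGeneric("simGenome", function(x) standardGeneric("simGenome"))
#' @rdname SimTruth-class
#' @export
setGeneric("simTargets", function(x) standardGeneric("simTargets"))
#' @rdname SimTruth-class
#' @export
setGeneric("simAlleleDb", function(x) standardGeneric("simAlleleDb"))
#' @rdname SimTruth-class
#' @export
setGeneric("plantedGenotype", function(x) standardGeneric("plantedGenotype"))
#' @rdname SimTruth-class
#' @export
setGeneric("simHaplotypes", function(x) standardGeneric("simHaplotypes"))
#' @rdname SimTruth-class
#' @export
setGeneric("truthVariants", function(x) standardGeneric("truthVariants"))

setMethod("alleleNames", "AlleleDb", function(x) names(x@sequences))
setMethod("alleleGenes", "AlleleDb", function(x) {
  stats::setNames(x@gene, names(x@sequences))
})
setMethod("alleleSeqs", "AlleleDb", function(x) x@sequences)
setMethod("geneAlleles", "AlleleDb", function(x, gene) {
  if (!gene %in% x@gene) stop("unknown gene: ", gene)
  x@sequences[x@gene == gene]
})
setMethod("alleleCounts", "AlleleDb", function(x) table(x@gene))
setMethod("isComplete", "AlleleDb", function(x) {
  stats::setNames(x@isComplete, names(x@sequences))
})
setMethod("alleleExonSpans", "AlleleDb", function(x, allele) {
  i <- match(allele, names(x@sequences))
  if (is.na(i)) stop("unknown allele: ", allele)
  x@exons[[i]]
})

setMethod("targetGenes", "MhcTargets", function(x) {
  unique(mcols(x@regions)$gene)
})
setMethod("exonRegions", "MhcTargets", function(x, gene = NULL) {
  if (is.null(gene)) return(x@regions)
  r <- x@regions[mcols(x@regions)$gene == gene]
  if (!length(r)) stop("unknown gene: ", gene)
  r[order(start(r))]
})
setMethod("paralogsOf", "MhcTargets", function(x, gene) {
  if (!gene %in% targetGenes(x)) stop("unknown gene: ", gene)
  if (!is.null(x@paralogs[[gene]])) return(x@paralogs[[gene]])
  setdiff(targetGenes(x), gene)  # default: all other configured genes
})
setMethod("geneEnvelope", "MhcTargets", function(x, gene) {
  r <- exonRegions(x, gene)
  GRanges(seqnames(r)[1], IRanges(min(start(r)), max(end(r))),
          strand = as.character(strand(r))[1])
})
setMethod("exonLabels", "MhcTargets", function(x, gene) {
  if (!is.null(x@exonLabels[[gene]])) return(x@exonLabels[[gene]])
  mcols(exonRegions(x, gene))$exon
})
setMethod("targetStrand", "MhcTargets", function(x, gene) {
  s <- as.character(strand(exonRegions(x, gene)))[1]
  if (s == "*") "+" else s
})

setMethod("contigMeta", "HaplotypeContigs", function(x) x@meta)
setMethod("contigSeqs", "HaplotypeContigs", function(x) x@sequences)

setMethod("typedGene", "GenotypeCall", function(x) x@gene)
setMethod("allele1Group", "GenotypeCall", function(x) x@allele1Group)
setMethod("allele2Group", "GenotypeCall", function(x) x@allele2Group)
setMethod("contigList", "GenotypeCall", function(x) x@contigList)
setMethod("totalBits", "GenotypeCall", function(x) {
  c(allele1 = x@totalBits1, allele2 = x@totalBits2)
})
setMethod("avgPident", "GenotypeCall", function(x) {
  c(allele1 = x@avgPident1, allele2 = x@avgPident2)
})

setMethod("simGenome", "SimTruth", function(x) x@genome)
setMethod("simTargets", "SimTruth", function(x) x@targets)
setMethod("simAlleleDb", "SimTruth", function(x) x@db)
setMethod("plantedGenotype", "SimTruth", function(x) x@genotype)
setMethod("simHaplotypes", "SimTruth", function(x) x@haplotypes)
setMethod("truthVariants", "SimTruth", function(x) x@truthVariants)
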