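#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges GRangesList seqnames strand start end width
#' @importFrom IRanges IRanges IRangesList
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assayNames colData rowRanges
NULL

#' Extract introns implied by a gene's exon chain
#'
#' @param x an object with gene structure, typically a
#'   [SpliceAnnotation-class].
#' @param ... further arguments for methods.
#' @return A `GRanges` of introns (see method documentation).
#' @export
setGeneric("introns", function(x, ...) standardGeneric("introns"))

#' @rdname junctionAccessors
#' @export
setGeneric("donor", function(x) standardGeneric("donor"))

#' @rdname junctionAccessors
#' @export
setGeneric("acceptor", function(x) standardGeneric("acceptor"))

#' @rdname JunctionExperiment-class
#' @export
setGeneric("totalMapped", function(x) standardGeneric("totalMapped"))

#' @rdname JunctionExperiment-class
#' @export
setGeneric("junctionCounts", function(x) standardGeneric("junctionCounts"))

#' @rdname JunctionExperiment-class
#' @export
setGeneric("junctionCPM", function(x) standardGeneric("junctionCPM"))

#' @rdname SpliceAnnotation-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname SpliceAnnotation-class
#' @export
setGeneric("exonsByGene", function(x) standardGeneric("exonsByGene"))

#' @rdname qpcr
#' @export
setGeneric("efficiency", function(x) standardGeneric("efficiency"))
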