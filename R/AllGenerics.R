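#' Accessors for titration objects
#'
#' \code{titrationDesign} returns the \linkS4class{TitrationDesign} attached
#' to an object; \code{counts} returns the count matrix;
#' \code{sampleDepths} the per-sample column sums; \code{subjects} the
#' subject identifiers; \code{titrationFactors} the titration factors.
#'
#' @param x a \linkS4class{TitrationExperiment} or
#'   \linkS4class{TitrationDesign}.
#' @return See each accessor's description.
#' @name titration-accessors
NULL

#' @rdname titration-accessors
#' @export
setGeneric("titrationDesign", function(x) standardGeneric("titrationDesign"))

#' @rdname titration-accessors
#' @export
setMethod("titrationDesign", "TitrationExperiment", function(x) x@design)

#' @rdname titration-accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname titration-accessors
#' @export
setMethod("counts", "TitrationExperiment",
    function(x) SummarizedExperiment::assay(x, "counts"))

#' @rdname titration-accessors
#' @export
setGeneric("sampleDepths", function(x) standardGeneric("sampleDepths"))

#' @rdname titration-accessors
#' @export
setMethod("sampleDepths", "TitrationExperiment",
    function(x) colSums(counts(x)))

#' @rdname titration-accessors
#' @export
setGeneric("subjects", function(x) standardGeneric("subjects"))

#' @rdname titration-accessors
#' @export
setMethod("subjects", "TitrationDesign", function(x) x@subjects)

#' @rdname titration-accessors
#' @export
setMethod("subjects", "TitrationExperiment", function(x) {
    s <- unique(SummarizedExperiment::colData(x)$subject)
    s[!is.na(s)]
})

#' @rdname titration-accessors
#' @export
setGeneric("titrationFactors", function(x) standardGeneric("titrationFactors"))

#' @rdname titration-accessors
#' @export
setMethod("titrationFactors", "TitrationDesign", function(x) x@titrationFactors)

#' @rdname titration-accessors
#' @export
setMethod("titrationFactors", "TitrationExperiment",
    function(x) titrationFactors(x@design))

#' Sparsity of a count table
#'
#' The fraction of zero-valued cells in the count table, a qualitative
#' indicator of how pipelines treat low-abundance and artifactual features.
#'
#' @param x a \linkS4class{TitrationExperiment} or a numeric matrix.
#' @return proportion of zero cells, in [0, 1].
#' @examples
#' sparsity(matrix(c(0, 1, 2, 3), 2))
#' @export
setGeneric("sparsity", function(x) standardGeneric("sparsity"))

#' @rdname sparsity
#' @export
setMethod("sparsity", "matrix", function(x) {
    if (length(x) == 0L)
        stop("sparsity is undefined for an empty matrix")
    mean(x == 0)
})

#' @rdname sparsity
#' @export
setMethod("sparsity", "TitrationExperiment", function(x) sparsity(counts(x)))
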