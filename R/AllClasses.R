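#' @import methods
#' @importClassesFrom S4Vectors DFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

SAMPLE_TYPES <- c("PRE", "POST", "TITRATION", "NTC")

FEATURE_TYPES <- c("PRE_SPECIFIC", "PRE_DOMINANT", "POST_SPECIFIC",
                   "POST_DOMINANT", "SHARED_FULL", "UNMIXED_SPECIFIC",
                   "TITRATION_SPECIFIC", "OTHER")

#' TitrationDesign: the two-sample titration mixture design
#'
#' Describes a two-sample titration series in which POST sample DNA is mixed
#' into PRE sample DNA following a log2 dilution series. A titration factor
#' \eqn{t} corresponds to a design POST proportion \eqn{\theta = 2^{-t}}.
#' When \code{includeUnmixed} is \code{TRUE} the unmixed PRE
#' (\eqn{\theta = 0}) and POST (\eqn{\theta = 1}) samples are part of the
#' series. Each sample is amplified in \code{pcrReplicates} replicate PCRs,
#' and \code{nNTC} no-template-control wells are carried alongside.
#'
#' @slot subjects character vector of subject identifiers, one independent
#'   titration series per subject.
#' @slot titrationFactors integer vector of distinct non-negative titration
#'   factors (exponents of the log2 dilution series).
#' @slot includeUnmixed logical; include unmixed PRE and POST samples.
#' @slot pcrReplicates positive integer, PCR replicates per sample.
#' @slot nNTC non-negative integer, number of no-template-control wells.
#'
#' @name TitrationDesign-class
#' @aliases TitrationDesign-class
#' @exportClass TitrationDesign
setClass("TitrationDesign",
    representation(
        subjects = "character",
        titrationFactors = "integer",
        includeUnmixed = "logical",
        pcrReplicates = "integer",
        nNTC = "integer"
    )
)

setValidity("TitrationDesign", function(object) {
    msg <- NULL
    if (length(object@subjects) < 1L || anyDuplicated(object@subjects))
        msg <- c(msg, "'subjects' must be a non-empty set of unique ids")
    tf <- object@titrationFactors
    if (anyNA(tf) || any(tf < 0L))
        msg <- c(msg, "'titrationFactors' must be non-negative integers")
    if (anyDuplicated(tf))
        msg <- c(msg, "'titrationFactors' must be unique")
    if (length(object@includeUnmixed) != 1L || is.na(object@includeUnmixed))
        msg <- c(msg, "'includeUnmixed' must be TRUE or FALSE")
    if (length(object@pcrReplicates) != 1L || is.na(object@pcrReplicates) ||
        object@pcrReplicates < 1L)
        msg <- c(msg, "'pcrReplicates' must be a positive integer")
    if (length(object@nNTC) != 1L || is.na(object@nNTC) || object@nNTC < 0L)
        msg <- c(msg, "'nNTC' must be a non-negative integer")
    if (is.null(msg)) TRUE else msg
})

#' Construct a TitrationDesign
#'
#' @param subjects character vector of subject identifiers.
#' @param titrationFactors non-negative integer titration factors; factor
#'   \eqn{t} encodes the design POST proportion \eqn{\theta = 2^{-t}}.
#' @param includeUnmixed include the unmixed PRE/POST samples (default TRUE).
#' @param pcrReplicates PCR replicates per sample (default 4).
#' @param nNTC number of no-template-control wells (default 0).
#'
#' @return A \linkS4class{TitrationDesign} object.
#' @examples
#' TitrationDesign(c("S1", "S2"), c(1, 2, 3))
#' @export
TitrationDesign <- function(subjects,
                            titrationFactors = c(1L, 2L, 3L, 4L, 5L, 10L, 15L),
                            includeUnmixed = TRUE,
                            pcrReplicates = 4L,
                            nNTC = 0L) {
    new("TitrationDesign",
        subjects = as.character(subjects),
        titrationFactors = sort(as.integer(titrationFactors)),
        includeUnmixed = as.logical(includeUnmixed),
        pcrReplicates = as.integer(pcrReplicates),
        nNTC = as.integer(nNTC))
}

#' The ETEC vaccine-trial assessment design
#'
#' The design of the framework's reference dataset: five subjects, titration
#' factors \{1, 2, 3, 4, 5, 10, 15\} (POST proportions 1/2 ... 1/32768),
#' unmixed PRE and POST samples, four PCR replicates per sample, and twelve
#' no-template controls (45 samples, 192 PCR assays in total).
#'
#' @return A \linkS4class{TitrationDesign}.
#' @examples
#' nrow(enumerateSamples(defaultDesign()))
#' @export
defaultDesign <- function() {
    TitrationDesign(
        subjects = c("E01JH0004", "E01JH0011", "E01JH0016",
                     "E01JH0017", "E01JH0038"),
        titrationFactors = c(1L, 2L, 3L, 4L, 5L, 10L, 15L),
        includeUnmixed = TRUE,
        pcrReplicates = 4L,
        nNTC = 12L)
}

#' @describeIn TitrationDesign-class display a design summary
#' @param object a \code{TitrationDesign}
#' @export
setMethod("show", "TitrationDesign", function(object) {
    cat("TitrationDesign with", length(object@subjects), "subject(s)\n")
    cat("  titration factors:",
        paste(object@titrationFactors, collapse = ", "),
        sprintf("(theta = %s)",
                paste(signif(2^-object@titrationFactors, 3), collapse = ", ")),
        "\n")
    cat("  unmixed PRE/POST included:", object@includeUnmixed, "\n")
    cat("  PCR replicates:", object@pcrReplicates,
        " NTC wells:", object@nNTC, "\n")
})

#' TitrationExperiment: a count table joined to titration metadata
#'
#' A \linkS4class{SummarizedExperiment} holding one \code{counts} assay
#' (features x samples, non-negative) whose \code{colData} carries the
#' titration sample annotation: \code{subject}, \code{sample_type}
#' (PRE/POST/TITRATION/NTC), \code{titration_factor} (integer, \code{NA}
#' unless the sample is a titration), \code{pcr_replicate}, and optionally
#' \code{raw_read_count} (reads entering the pipeline, used for drop-out
#' rates). The generating \linkS4class{TitrationDesign} travels with the
#' object.
#'
#' Counts are integer-valued for real sequencing data; fractional values
#' are tolerated so that noiseless oracle datasets (see
#' \code{\link{noiselessDataset}}) can be represented exactly. The file
#' readers enforce integrality at parse time.
#'
#' @slot design the \linkS4class{TitrationDesign} the samples follow.
#' @name TitrationExperiment-class
#' @aliases TitrationExperiment-class
#' @exportClass TitrationExperiment
setClass("TitrationExperiment",
    contains = "SummarizedExperiment",
    representation(design = "TitrationDesign")
)

setValidity("TitrationExperiment", function(object) {
    msg <- NULL
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' is required")
    m <- SummarizedExperiment::assay(object, "counts")
    if (any(!is.finite(m)) || any(m < 0))
        msg <- c(msg, "counts must be finite and non-negative")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "feature ids must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be present and unique")
    cd <- SummarizedExperiment::colData(object)
    need <- c("subject", "sample_type", "titration_factor", "pcr_replicate")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        return(paste("colData misses column(s):", paste(miss, collapse = ", ")))
    if (!all(cd$sample_type %in% SAMPLE_TYPES))
        msg <- c(msg, paste("sample_type must be one of",
                            paste(SAMPLE_TYPES, collapse = "/")))
    isT <- cd$sample_type == "TITRATION"
    if (any(isT & is.na(cd$titration_factor)))
        msg <- c(msg, "titration samples need a titration_factor")
    if (any(!isT & !is.na(cd$titration_factor)))
        msg <- c(msg, "titration_factor must be NA for non-titration samples")
    if (is.null(msg)) TRUE else msg
})

#' Construct a TitrationExperiment
#'
#' @param counts numeric matrix (features x samples) with rownames and
#'   colnames; non-negative.
#' @param colData data.frame or DataFrame of sample metadata with columns
#'   \code{sample_id} (or rownames matching \code{colnames(counts)}),
#'   \code{subject}, \code{sample_type}, \code{titration_factor},
#'   \code{pcr_replicate} and optionally \code{raw_read_count}.
#' @param design a \linkS4class{TitrationDesign}.
#'
#' @return A \linkS4class{TitrationExperiment}.
#' @export
TitrationExperiment <- function(counts, colData, design) {
    colData <- as.data.frame(colData)
    if ("sample_id" %in% colnames(colData)) {
        rownames(colData) <- as.character(colData$sample_id)
        colData$sample_id <- NULL
    }
    if (is.null(colnames(counts)))
        stop("'counts' must have sample ids as colnames")
    missing <- setdiff(colnames(counts), rownames(colData))
    if (length(missing))
        stop("samples present in the count table but absent from metadata: ",
             paste(missing, collapse = ", "))
    colData <- colData[colnames(counts), , drop = FALSE]
    if (!"titration_factor" %in% colnames(colData))
        colData$titration_factor <- NA_integer_
    colData$titration_factor <- as.integer(colData$titration_factor)
    colData$sample_type <- as.character(colData$sample_type)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = as.matrix(counts)),
        colData = S4Vectors::DataFrame(colData))
    new("TitrationExperiment", se, design = design)
}

#' @describeIn TitrationExperiment-class display a summary
#' @param object a \code{TitrationExperiment}
#' @export
setMethod("show", "TitrationExperiment", function(object) {
    cat("TitrationExperiment:", nrow(object), "features x",
        ncol(object), "samples\n")
    cat("  subjects:",
        paste(unique(SummarizedExperiment::colData(object)$subject),
              collapse = ", "), "\n")
    tab <- table(SummarizedExperiment::colData(object)$sample_type)
    cat("  sample types:",
        paste(names(tab), tab, sep = ":", collapse = "  "), "\n")
    cat("  sparsity:", signif(sparsity(object), 3), "\n")
})

#' FeatureCatalog: per-(feature, subject) feature-type classification
#'
#' A \code{DataFrame} subclass with one row per (feature, subject) pair and
#' columns \code{feature_id}, \code{subject}, \code{feature_type} (one of
#' PRE_SPECIFIC, PRE_DOMINANT, POST_SPECIFIC, POST_DOMINANT, SHARED_FULL,
#' UNMIXED_SPECIFIC, TITRATION_SPECIFIC, OTHER), \code{n_pre_present},
#' \code{n_post_present}, \code{n_titration_present}, \code{q_pre},
#' \code{q_post} (pooled unmixed proportions). Built by
#' \code{\link{buildCatalog}}.
#'
#' @name FeatureCatalog-class
#' @aliases FeatureCatalog-class
#' @exportClass FeatureCatalog
setClass("FeatureCatalog", contains = "DFrame")

setValidity("FeatureCatalog", function(object) {
    need <- c("feature_id", "subject", "feature_type",
              "n_pre_present", "n_post_present", "n_titration_present",
              "q_pre", "q_post")
    miss <- setdiff(need, colnames(object))
    if (length(miss))
        return(paste("missing column(s):", paste(miss, collapse = ", ")))
    if (!all(object$feature_type %in% FEATURE_TYPES))
        return("invalid feature_type label")
    if (anyDuplicated(paste(object$feature_id, object$subject)))
        return("(feature, subject) pairs must be unique")
    TRUE
})

#' @describeIn FeatureCatalog-class display type counts per subject
#' @param object a \code{FeatureCatalog}
#' @export
setMethod("show", "FeatureCatalog", function(object) {
    cat("FeatureCatalog:", length(unique(object$feature_id)), "features x",
        length(unique(object$subject)), "subject(s)\n")
    print(table(object$subject, factor(object$feature_type, FEATURE_TYPES)))
})
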