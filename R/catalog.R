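#' Classify a feature's titration presence pattern
#'
#' Assigns one of the framework's feature types to a feature within a
#' subject's titration series, from its counts in the unmixed PRE and POST
#' PCR replicates and in the titration samples. "Observed" means a count of
#' at least 1 in a PCR replicate. Precedence:
#' \enumerate{
#'   \item all counts zero: \code{OTHER};
#'   \item observed only in titrations: \code{TITRATION_SPECIFIC};
#'   \item observed only in unmixed samples: \code{UNMIXED_SPECIFIC};
#'   \item observed in all PRE replicates, no POST replicate:
#'     \code{PRE_SPECIFIC};
#'   \item observed in all PRE replicates, at least one POST replicate, and
#'     depth-normalized PRE:POST log2 fold-change above
#'     \code{logfc_threshold}: \code{PRE_DOMINANT} (and the POST-side
#'     mirror images of these two rules);
#'   \item observed in all PRE and all POST replicates: \code{SHARED_FULL};
#'   \item anything else: \code{OTHER}.
#' }
#' The dominance log fold-change is computed on replicate-pooled counts
#' with \code{\link{estimateLogFC}} and prior count \code{prior_count}.
#'
#' @param pre_counts,post_counts counts in each PRE / POST PCR replicate.
#' @param titration_counts counts in each (titration, replicate) cell.
#' @param pre_depths,post_depths total sample depths of the PRE / POST
#'   replicates (used to depth-normalize the dominance log fold-change).
#' @param logfc_threshold dominance threshold on the PRE:POST log2
#'   fold-change (default 5).
#' @param prior_count prior count of the dominance log fold-change
#'   estimator (default 0.5).
#' @return a feature type label (character scalar).
#' @examples
#' classifyFeature(c(5, 3, 8, 2), c(0, 0, 0, 0), c(3, 1, 0, 2),
#'                 rep(1000, 4), rep(1000, 4))
#' @export
classifyFeature <- function(pre_counts, post_counts, titration_counts,
                            pre_depths, post_depths,
                            logfc_threshold = 5, prior_count = 0.5) {
    if (anyNA(pre_counts) || anyNA(post_counts) || anyNA(titration_counts))
        stop("replicate counts must be complete (no NA cells)")
    .classifyMatrix(matrix(pre_counts, nrow = 1L),
                    matrix(post_counts, nrow = 1L),
                    matrix(titration_counts, nrow = 1L),
                    pre_depths, post_depths,
                    logfc_threshold, prior_count)
}

## Vectorized classification over a feature matrix (rows = features).
.classifyMatrix <- function(pre, post, titr, pre_depths, post_depths,
                            logfc_threshold = 5, prior_count = 0.5) {
    stopifnot(ncol(pre) == length(pre_depths),
              ncol(post) == length(post_depths))
    n_pre <- rowSums(pre >= 1)
    n_post <- rowSums(post >= 1)
    n_titr <- rowSums(titr >= 1)
    unmixed_any <- (n_pre + n_post) > 0
    all_pre <- n_pre == ncol(pre)
    all_post <- n_post == ncol(post)

    lfc <- estimateLogFC(rowSums(pre), sum(pre_depths),
                         rowSums(post), sum(post_depths),
                         prior_count = prior_count)

    type <- rep("OTHER", nrow(pre))
    type[!unmixed_any & n_titr > 0] <- "TITRATION_SPECIFIC"
    type[unmixed_any & n_titr == 0] <- "UNMIXED_SPECIFIC"
    mixed <- unmixed_any & n_titr > 0
    type[mixed & all_pre & n_post == 0] <- "PRE_SPECIFIC"
    type[mixed & all_post & n_pre == 0] <- "POST_SPECIFIC"
    type[mixed & all_pre & n_post >= 1 & lfc > logfc_threshold] <-
        "PRE_DOMINANT"
    type[mixed & all_post & n_pre >= 1 & -lfc > logfc_threshold] <-
        "POST_DOMINANT"
    shared <- mixed & all_pre & all_post &
        !(lfc > logfc_threshold) & !(-lfc > logfc_threshold)
    type[shared] <- "SHARED_FULL"
    type
}

#' Build the feature catalog of a titration experiment
#'
#' Classifies every (feature, subject) pair with
#' \code{\link{classifyFeature}} and records replicate presence counts and
#' the pooled unmixed proportions \code{q_pre}, \code{q_post} (replicate
#' counts summed, divided by summed depths) used throughout the
#' quantitative assessment.
#'
#' @param te a \linkS4class{TitrationExperiment}.
#' @param logfc_threshold,prior_count see \code{\link{classifyFeature}}.
#' @return a \linkS4class{FeatureCatalog}.
#' @export
buildCatalog <- function(te, logfc_threshold = 5, prior_count = 0.5) {
    stopifnot(is(te, "TitrationExperiment"))
    cd <- SummarizedExperiment::colData(te)
    m <- counts(te)
    depth <- colSums(m)
    rows <- lapply(subjects(te), function(s) {
        in_s <- !is.na(cd$subject) & cd$subject == s
        i_pre <- which(in_s & cd$sample_type == "PRE")
        i_post <- which(in_s & cd$sample_type == "POST")
        i_titr <- which(in_s & cd$sample_type == "TITRATION")
        if (!length(i_pre) || !length(i_post))
            stop("subject '", s, "' lacks unmixed PRE or POST replicates")
        pre <- m[, i_pre, drop = FALSE]
        post <- m[, i_post, drop = FALSE]
        titr <- m[, i_titr, drop = FALSE]
        type <- .classifyMatrix(pre, post, titr,
                                depth[i_pre], depth[i_post],
                                logfc_threshold, prior_count)
        S4Vectors::DataFrame(
            feature_id = rownames(m),
            subject = s,
            feature_type = type,
            n_pre_present = rowSums(pre >= 1),
            n_post_present = rowSums(post >= 1),
            n_titration_present = rowSums(titr >= 1),
            q_pre = rowSums(pre) / sum(depth[i_pre]),
            q_post = rowSums(post) / sum(depth[i_post]))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    new("FeatureCatalog", out)
}

#' Per-subject feature-type counts
#'
#' @param catalog a \linkS4class{FeatureCatalog}.
#' @return a \code{data.frame} with one row per (subject, feature_type) and
#'   the number of features of that type.
#' @export
catalogSummary <- function(catalog) {
    tab <- table(subject = catalog$subject,
                 feature_type = factor(catalog$feature_type, FEATURE_TYPES))
    as.data.frame(tab, responseName = "n", stringsAsFactors = FALSE)
}

#' Feature sets routed into each assessment
#'
#' \code{eligibleRelabundFeatures} returns the features entering the
#' relative-abundance assessment for a subject: features observed in every
#' PRE and POST replicate (\code{SHARED_FULL}) plus the \code{PRE_SPECIFIC}
#' and \code{POST_SPECIFIC} features. \code{eligibleLogFCFeatures} returns
#' the features entering the differential-abundance assessment:
#' \code{PRE_SPECIFIC} and \code{PRE_DOMINANT} features (POST-side features
#' are excluded because they are rarely observed in more than one
#' titration). An empty result is legitimate and simply reported.
#'
#' @param catalog a \linkS4class{FeatureCatalog}.
#' @param subject subject identifier.
#' @return character vector of feature ids.
#' @name eligible-features
NULL

#' @rdname eligible-features
#' @export
eligibleRelabundFeatures <- function(catalog, subject) {
    sel <- catalog$subject == subject &
        catalog$feature_type %in% c("SHARED_FULL", "PRE_SPECIFIC",
                                    "POST_SPECIFIC")
    as.character(catalog$feature_id[sel])
}

#' @rdname eligible-features
#' @export
eligibleLogFCFeatures <- function(catalog, subject) {
    sel <- catalog$subject == subject &
        catalog$feature_type %in% c("PRE_SPECIFIC", "PRE_DOMINANT")
    as.character(catalog$feature_id[sel])
}

#' Write a feature catalog as TSV
#'
#' @param catalog a \linkS4class{FeatureCatalog}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCatalog <- function(catalog, path) {
    df <- as.data.frame(catalog)
    con <- file(path, open = "wb")
    on.exit(close(con))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
    invisible(path)
}
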