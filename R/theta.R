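#' Features informative for mixture-proportion inference
#'
#' Features whose unmixed PRE and POST proportions differ are informative
#' for estimating the realized POST proportion of a titration. Eligible
#' types are PRE_SPECIFIC, PRE_DOMINANT, POST_SPECIFIC, POST_DOMINANT and
#' SHARED_FULL, filtered to \eqn{|q_{post} - q_{pre}|} above a floor.
#'
#' @param catalog a \linkS4class{FeatureCatalog}.
#' @param subject subject identifier.
#' @param floor minimum absolute PRE/POST proportion difference
#'   (default 1e-5).
#' @return character vector of feature ids (possibly empty).
#' @export
informativeFeatures <- function(catalog, subject, floor = 1e-5) {
    sel <- catalog$subject == subject &
        catalog$feature_type %in% c("PRE_SPECIFIC", "PRE_DOMINANT",
                                    "POST_SPECIFIC", "POST_DOMINANT",
                                    "SHARED_FULL") &
        abs(catalog$q_post - catalog$q_pre) > floor
    as.character(catalog$feature_id[sel])
}

#' Infer the realized POST proportion of one titration
#'
#' Constrained least-squares estimate of the POST proportion \eqn{\theta}
#' from the sequencing data itself: over the informative features the
#' mixture expectation gives
#' \eqn{q_{obs,j} - q_{pre,j} = \theta (q_{post,j} - q_{pre,j})}, solved
#' for \eqn{\theta} by least squares on pooled-replicate proportions and
#' clamped to [0, 1]. When prokaryotic DNA proportions differ between the
#' unmixed samples, the estimate recovers the effective (16S-visible)
#' POST proportion, not the design value.
#'
#' @param te a \linkS4class{TitrationExperiment}.
#' @param catalog a \linkS4class{FeatureCatalog} built from \code{te}.
#' @param subject subject identifier.
#' @param titration_factor titration factor of the target titration.
#' @param features feature ids to use; defaults to
#'   \code{\link{informativeFeatures}}.
#' @param weighted use inverse-expected-variance weights (weights
#'   proportional to \eqn{1/(q_j(1-q_j))} at the design expectation);
#'   default \code{FALSE} for transparency.
#' @param floor informative-feature floor, see
#'   \code{\link{informativeFeatures}}.
#' @return one-row \code{data.frame}: \code{subject},
#'   \code{titration_factor}, \code{theta_design}, \code{theta_hat},
#'   \code{theta_source} (\code{"inferred"} or \code{"design"} on
#'   fallback), \code{n_features_used}, \code{residual_sse},
#'   \code{fallback} flag.
#' @export
inferTheta <- function(te, catalog, subject, titration_factor,
                       features = NULL, weighted = FALSE, floor = 1e-5) {
    stopifnot(is(te, "TitrationExperiment"))
    cd <- SummarizedExperiment::colData(te)
    th_design <- thetaFromFactor(titration_factor)
    if (is.null(features))
        features <- informativeFeatures(catalog, subject, floor = floor)
    fallback <- function(reason) {
        warning("theta inference fallback to design value for subject '",
                subject, "', factor ", titration_factor, ": ", reason)
        data.frame(subject = subject, titration_factor = titration_factor,
                   theta_design = th_design, theta_hat = th_design,
                   theta_source = "design", n_features_used = 0L,
                   residual_sse = NA_real_, fallback = TRUE,
                   stringsAsFactors = FALSE)
    }
    if (length(features) < 3L)
        return(fallback("fewer than 3 informative features"))
    i_titr <- which(!is.na(cd$subject) & cd$subject == subject &
                    cd$sample_type == "TITRATION" &
                    cd$titration_factor == titration_factor)
    if (!length(i_titr))
        stop("no samples for subject '", subject, "', titration factor ",
             titration_factor)
    m <- counts(te)
    pooled <- rowSums(m[, i_titr, drop = FALSE])
    q_obs <- (pooled / sum(pooled))[features]
    cat_s <- catalog[catalog$subject == subject, ]
    idx <- match(features, cat_s$feature_id)
    q_pre <- cat_s$q_pre[idx]
    q_post <- cat_s$q_post[idx]
    x <- q_post - q_pre
    y <- q_obs - q_pre
    if (sum(x^2) <= .Machine$double.eps)
        return(fallback("degenerate regressor: q_post == q_pre throughout"))
    if (weighted) {
        q0 <- expectedProportion(q_pre, q_post, th_design)
        wts <- ifelse(q0 > 0 & q0 < 1, 1 / (q0 * (1 - q0)), 0)
    } else {
        wts <- rep(1, length(x))
    }
    theta_hat <- sum(wts * x * y) / sum(wts * x^2)
    theta_hat <- min(1, max(0, theta_hat))
    sse <- sum((y - theta_hat * x)^2)
    data.frame(subject = subject, titration_factor = titration_factor,
               theta_design = th_design, theta_hat = theta_hat,
               theta_source = "inferred",
               n_features_used = length(features),
               residual_sse = sse, fallback = FALSE,
               stringsAsFactors = FALSE)
}

#' Infer POST proportions for every (subject, titration)
#'
#' Applies \code{\link{inferTheta}} across all subjects and titration
#' factors of the experiment's design.
#'
#' @inheritParams inferTheta
#' @return \code{data.frame}, one row per (subject, titration factor); see
#'   \code{\link{inferTheta}}.
#' @export
inferThetaAll <- function(te, catalog = NULL, weighted = FALSE,
                          floor = 1e-5) {
    if (is.null(catalog)) catalog <- buildCatalog(te)
    grid <- expand.grid(subject = subjects(te),
                        titration_factor = titrationFactors(te),
                        stringsAsFactors = FALSE)
    out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
        inferTheta(te, catalog, grid$subject[i], grid$titration_factor[i],
                   weighted = weighted, floor = floor)
    }))
    rownames(out) <- NULL
    out
}
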