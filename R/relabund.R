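#' Replicate-averaged relative abundance via a negative binomial model
#'
#' Average feature relative abundance across PCR replicates, computed as
#' the fitted mean of an intercept-only negative binomial regression with
#' log link and log-depth offset. The NB average down-weights outlier
#' replicates relative to the pooled proportion. The fit falls back to the
#' pooled proportion \eqn{\sum c_i / \sum d_i} when the counts are all
#' zero, are non-integer (noiseless oracle data), are nearly constant, or
#' when the NB fit fails to converge.
#'
#' @param x replicate counts (non-negative).
#' @param depths replicate total depths (same length).
#' @return the averaged proportion.
#' @examples
#' nbMeanProportion(c(10, 10, 10, 10), rep(1000, 4))  # 0.01
#' @export
nbMeanProportion <- function(x, depths) {
    if (length(x) != length(depths))
        stop("'x' and 'depths' must have the same length")
    drop <- depths == 0
    if (any(drop)) {
        warning(sum(drop), " replicate(s) with zero depth dropped")
        x <- x[!drop]
        depths <- depths[!drop]
    }
    if (!length(x))
        stop("no replicates with positive depth")
    pooled <- sum(x) / sum(depths)
    if (all(x == 0))
        return(0)
    integral <- all(x == round(x))
    if (!integral || length(x) < 2L || stats::var(x) == 0)
        return(pooled)
    fit <- tryCatch(
        suppressWarnings(
            MASS::glm.nb(x ~ 1 + offset(log(depths)),
                         control = stats::glm.control(maxit = 50))),
        error = function(e) NULL)
    if (is.null(fit) || !fit$converged)
        return(pooled)
    unname(exp(stats::coef(fit)[1L]))
}

#' Relative abundance error rate
#'
#' \eqn{|expected - observed| / expected}; undefined when the expectation
#' is zero (\code{NA} is returned and the record should be flagged).
#'
#' @param observed,expected proportions.
#' @return non-negative error rate(s), \code{NA} where
#'   \code{expected == 0}.
#' @examples
#' relabundError(0.2, 0.4)  # 0.5
#' @export
relabundError <- function(observed, expected) {
    ifelse(expected > 0, abs(expected - observed) / expected, NA_real_)
}

#' Feature-level bias and variance of relative-abundance errors
#'
#' Summarizes a feature's titration error rates into the framework's
#' feature-level metrics: bias = median error rate, variance = robust
#' coefficient of variation \eqn{RCOV = IQR / |median|}. Quantiles use
#' linear interpolation (R type 7). A zero median with positive IQR gives
#' an infinite RCOV; all-zero errors give RCOV 0.
#'
#' @param errors numeric vector of error rates (at least 2).
#' @return list with \code{bias}, \code{variance}, \code{n}.
#' @examples
#' featureErrorSummary(c(0.1, 0.2, 0.3, 0.4))  # bias 0.25, RCOV 0.6
#' @export
featureErrorSummary <- function(errors) {
    errors <- errors[is.finite(errors)]
    if (length(errors) < 2L)
        stop("at least 2 error values are required")
    med <- stats::median(errors)
    iqr <- stats::IQR(errors, type = 7)
    v <- if (iqr == 0) 0 else if (med == 0) Inf else iqr / abs(med)
    list(bias = med, variance = v, n = length(errors))
}

#' Relative abundance assessment
#'
#' Compares replicate-averaged observed feature proportions in each
#' titration against the mixture expectation computed from the pooled
#' unmixed proportions. Eligible features are those observed in every PRE
#' and POST replicate plus the PRE-/POST-specific features. Expected
#' values use the inferred POST proportion \eqn{\theta} when available
#' (falling back to design values), or design \eqn{\theta} throughout when
#' \code{theta_mode = "design"}.
#'
#' @param te a \linkS4class{TitrationExperiment}.
#' @param catalog a \linkS4class{FeatureCatalog}; built with defaults if
#'   missing.
#' @param theta theta estimate table from \code{\link{inferThetaAll}};
#'   computed on the fly when missing and \code{theta_mode = "inferred"}.
#' @param theta_mode \code{"inferred"} (default) or \code{"design"}.
#' @return list with \code{records} (one row per feature x titration:
#'   observed, expected, error rate) and \code{features} (one row per
#'   feature: bias, variance, number of titrations).
#' @export
assessRelativeAbundance <- function(te, catalog = NULL, theta = NULL,
                                    theta_mode = c("inferred", "design")) {
    stopifnot(is(te, "TitrationExperiment"))
    theta_mode <- match.arg(theta_mode)
    if (is.null(catalog)) catalog <- buildCatalog(te)
    if (theta_mode == "inferred" && is.null(theta))
        theta <- inferThetaAll(te, catalog)
    cd <- SummarizedExperiment::colData(te)
    m <- counts(te)
    depth <- colSums(m)
    recs <- list()
    for (s in subjects(te)) {
        feats <- eligibleRelabundFeatures(catalog, s)
        if (!length(feats)) next
        cat_s <- catalog[catalog$subject == s, ]
        idx <- match(feats, cat_s$feature_id)
        q_pre <- cat_s$q_pre[idx]
        q_post <- cat_s$q_post[idx]
        for (tf in titrationFactors(te)) {
            i_t <- which(!is.na(cd$subject) & cd$subject == s &
                         cd$sample_type == "TITRATION" &
                         cd$titration_factor == tf)
            if (!length(i_t)) next
            th <- thetaFromFactor(tf)
            src <- "design"
            if (theta_mode == "inferred") {
                k <- match(paste(s, tf),
                           paste(theta$subject, theta$titration_factor))
                if (!is.na(k)) {
                    th <- theta$theta_hat[k]
                    src <- theta$theta_source[k]
                }
            }
            obs <- vapply(feats, function(f)
                nbMeanProportion(m[f, i_t], depth[i_t]), numeric(1))
            expd <- expectedProportion(q_pre, q_post, th)
            recs[[length(recs) + 1L]] <- data.frame(
                feature_id = feats, subject = s, titration_factor = tf,
                theta = th, theta_source = src,
                observed = unname(obs), expected = expd,
                error_rate = relabundError(unname(obs), expd),
                stringsAsFactors = FALSE)
        }
    }
    records <- if (length(recs)) do.call(rbind, recs) else
        data.frame(feature_id = character(), subject = character(),
                   titration_factor = integer(), theta = numeric(),
                   theta_source = character(), observed = numeric(),
                   expected = numeric(), error_rate = numeric(),
                   stringsAsFactors = FALSE)
    rownames(records) <- NULL
    keep <- is.finite(records$error_rate)
    feats <- do.call(rbind, lapply(
        split(records[keep, , drop = FALSE],
              paste(records$subject[keep], records$feature_id[keep])),
        function(d) {
            if (nrow(d) < 2L) return(NULL)
            sm <- featureErrorSummary(d$error_rate)
            data.frame(feature_id = d$feature_id[1L],
                       subject = d$subject[1L],
                       bias = sm$bias, variance = sm$variance,
                       n_titrations = sm$n, stringsAsFactors = FALSE)
        }))
    if (is.null(feats))
        feats <- data.frame(feature_id = character(), subject = character(),
                            bias = numeric(), variance = numeric(),
                            n_titrations = integer(),
                            stringsAsFactors = FALSE)
    rownames(feats) <- NULL
    list(records = records, features = feats)
}
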