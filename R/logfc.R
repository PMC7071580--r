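#' Moderated log2 fold-change between two samples
#'
#' Transparent proportion-ratio estimator with a prior count:
#' \deqn{logFC = \log_2\frac{(c_l + p)/(d_l + 2p)}{(c_m + p)/(d_m + 2p)}}
#' for counts \eqn{c}, depths \eqn{d} and prior count \eqn{p}. Replicates
#' are pooled by summation before estimation. With \eqn{p = 0} and a zero
#' count the estimate is undefined and an error instructs using a positive
#' prior.
#'
#' @param count_l,count_m (pooled) counts in the two samples.
#' @param depth_l,depth_m (pooled) depths; must be positive.
#' @param prior_count non-negative prior count (default 0.5).
#' @return log2 fold-change(s), sample \eqn{l} relative to \eqn{m}.
#' @examples
#' estimateLogFC(20, 1000, 10, 1000, prior_count = 0)  # 1
#' @export
estimateLogFC <- function(count_l, depth_l, count_m, depth_m,
                          prior_count = 0.5) {
    if (any(depth_l <= 0) || any(depth_m <= 0))
        stop("depths must be positive")
    if (prior_count < 0)
        stop("'prior_count' must be non-negative")
    if (prior_count == 0 && (any(count_l == 0) || any(count_m == 0)))
        stop("zero count with prior_count = 0: log fold-change undefined; ",
             "use a positive prior count")
    log2((count_l + prior_count) / (depth_l + 2 * prior_count)) -
        log2((count_m + prior_count) / (depth_m + 2 * prior_count))
}

#' Mixture-level pairs of a titration design
#'
#' All unordered pairs among the design's mixture levels (unmixed POST,
#' the titrations, unmixed PRE), oriented as (higher theta, lower theta).
#' For \eqn{k} levels there are \eqn{k(k-1)/2} pairs.
#'
#' @param design a \linkS4class{TitrationDesign}.
#' @param include_unmixed include the unmixed PRE/POST levels (defaults to
#'   the design's flag).
#' @return \code{data.frame} with columns \code{level_l}, \code{level_m}
#'   (labels \code{"POST"}, \code{"T<factor>"}, \code{"PRE"}),
#'   \code{theta_l}, \code{theta_m} (design values, \code{theta_l >
#'   theta_m}) and \code{factor_l}, \code{factor_m} (\code{NA} for
#'   unmixed levels).
#' @examples
#' nrow(titrationPairs(defaultDesign()))  # 36
#' @export
titrationPairs <- function(design, include_unmixed = design@includeUnmixed) {
    tf <- titrationFactors(design)
    lev <- data.frame(label = sprintf("T%02d", tf),
                      theta = thetaFromFactor(tf),
                      factor = tf, stringsAsFactors = FALSE)
    if (include_unmixed) {
        lev <- rbind(data.frame(label = "POST", theta = 1,
                                factor = NA_integer_),
                     lev,
                     data.frame(label = "PRE", theta = 0,
                                factor = NA_integer_))
    }
    lev <- lev[order(-lev$theta), , drop = FALSE]
    k <- nrow(lev)
    if (k < 2L)
        return(data.frame(level_l = character(), level_m = character(),
                          theta_l = numeric(), theta_m = numeric(),
                          factor_l = integer(), factor_m = integer(),
                          stringsAsFactors = FALSE))
    idx <- utils::combn(k, 2L)
    out <- data.frame(
        level_l = lev$label[idx[1L, ]], level_m = lev$label[idx[2L, ]],
        theta_l = lev$theta[idx[1L, ]], theta_m = lev$theta[idx[2L, ]],
        factor_l = lev$factor[idx[1L, ]], factor_m = lev$factor[idx[2L, ]],
        stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Per-feature linear fit of estimated on expected log fold-change
#'
#' Ordinary least squares of the estimated log2 fold-changes on the
#' expected values across mixture-level pairs. The feature-level bias
#' metric is \eqn{|1 - slope|} (0 when estimates track expectations) and
#' the variance metric is the fit's \eqn{R^2} (1 when the relationship is
#' exact).
#'
#' @param estimated,expected numeric vectors of log2 fold-changes over the
#'   same pairs; non-finite pairs are dropped.
#' @return list with \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{bias}, \code{n_pairs}; all \code{NA} with \code{skipped = TRUE}
#'   when fewer than 3 finite pairs remain or the expected values are
#'   constant.
#' @examples
#' featureLogFCFit(c(1, 2, 3), c(1, 2, 3))
#' @export
featureLogFCFit <- function(estimated, expected) {
    keep <- is.finite(estimated) & is.finite(expected)
    x <- expected[keep]
    y <- estimated[keep]
    bad <- function(reason) list(slope = NA_real_, intercept = NA_real_,
                                 r_squared = NA_real_, bias = NA_real_,
                                 n_pairs = length(x), skipped = TRUE,
                                 reason = reason)
    if (length(x) < 3L)
        return(bad("fewer than 3 finite pairs"))
    if (stats::var(x) == 0)
        return(bad("zero variance in expected values"))
    slope <- stats::cov(x, y) / stats::var(x)
    intercept <- mean(y) - slope * mean(x)
    ssr <- sum((y - intercept - slope * x)^2)
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst == 0) 1 else 1 - ssr / sst
    list(slope = slope, intercept = intercept, r_squared = r2,
         bias = abs(1 - slope), n_pairs = length(x), skipped = FALSE,
         reason = NA_character_)
}

#' Differential abundance assessment
#'
#' Estimates log2 fold-changes between every pair of mixture levels
#' (replicates pooled, prior-count moderated) for the PRE-specific and
#' PRE-dominant features of each subject, compares them to the expected
#' values from the mixture design (design \eqn{\theta} always; for
#' PRE-specific features the expectation
#' \eqn{\log_2[(1-\theta_l)/(1-\theta_m)]} is count-free), and fits the
#' per-feature linear model yielding the bias (\eqn{|1-slope|}) and
#' variance (\eqn{R^2}) metrics. Pairs whose expected value is undefined
#' (PRE-specific features against the unmixed POST) are dropped from the
#' fit.
#'
#' @param te a \linkS4class{TitrationExperiment}.
#' @param catalog a \linkS4class{FeatureCatalog}; built with defaults if
#'   missing.
#' @param prior_count prior count of the estimator (default 0.5).
#' @param pairs optional subset of mixture-level pairs (as returned by
#'   \code{\link{titrationPairs}}); defaults to all pairs.
#' @param external_logfc optional externally computed log fold-change table
#'   (columns \code{feature_id}, \code{subject}, \code{level_l},
#'   \code{level_m}, \code{estimated_logfc}) replacing the built-in
#'   estimator, e.g. from a dedicated differential-abundance package.
#' @return list with \code{records} (per feature x pair: estimated,
#'   expected, absolute error), \code{features} (per feature: slope,
#'   r_squared, bias) and \code{excluded_subjects} (subjects with no
#'   eligible features).
#' @export
assessLogFC <- function(te, catalog = NULL, prior_count = 0.5,
                        pairs = NULL, external_logfc = NULL) {
    stopifnot(is(te, "TitrationExperiment"))
    if (is.null(catalog)) catalog <- buildCatalog(te)
    if (is.null(pairs)) pairs <- titrationPairs(titrationDesign(te))
    cd <- SummarizedExperiment::colData(te)
    m <- counts(te)
    depth <- colSums(m)
    level_index <- function(s, label) {
        in_s <- !is.na(cd$subject) & cd$subject == s
        if (label == "PRE") which(in_s & cd$sample_type == "PRE")
        else if (label == "POST") which(in_s & cd$sample_type == "POST")
        else which(in_s & cd$sample_type == "TITRATION" &
                   cd$titration_factor == as.integer(sub("^T", "", label)))
    }
    recs <- list()
    excluded <- character()
    for (s in subjects(te)) {
        feats <- eligibleLogFCFeatures(catalog, s)
        if (!length(feats)) {
            excluded <- c(excluded, s)
            next
        }
        cat_s <- catalog[catalog$subject == s, ]
        idx <- match(feats, cat_s$feature_id)
        q_pre <- cat_s$q_pre[idx]
        q_post <- cat_s$q_post[idx]
        pre_specific <- cat_s$feature_type[idx] == "PRE_SPECIFIC"
        for (p in seq_len(nrow(pairs))) {
            i_l <- level_index(s, pairs$level_l[p])
            i_m <- level_index(s, pairs$level_m[p])
            if (!length(i_l) || !length(i_m)) next
            c_l <- rowSums(m[feats, i_l, drop = FALSE])
            c_m <- rowSums(m[feats, i_m, drop = FALSE])
            if (!is.null(external_logfc)) {
                k <- match(paste(feats, s, pairs$level_l[p],
                                 pairs$level_m[p]),
                           paste(external_logfc$feature_id,
                                 external_logfc$subject,
                                 external_logfc$level_l,
                                 external_logfc$level_m))
                est <- external_logfc$estimated_logfc[k]
            } else if (prior_count == 0) {
                ## zero counts give +/-Inf here and are dropped by the
                ## per-feature fit (the exported estimator errors instead)
                est <- log2(c_l / sum(depth[i_l])) -
                    log2(c_m / sum(depth[i_m]))
            } else {
                est <- estimateLogFC(c_l, sum(depth[i_l]),
                                     c_m, sum(depth[i_m]),
                                     prior_count = prior_count)
            }
            th_l <- pairs$theta_l[p]
            th_m <- pairs$theta_m[p]
            expd <- numeric(length(feats))
            ## PRE-specific: count-free expectation, undefined at theta = 1
            if (any(pre_specific)) {
                expd[pre_specific] <-
                    if (th_l >= 1 || th_m >= 1) NA_real_
                    else expectedLogFCPreSpecific(th_l, th_m)
            }
            if (any(!pre_specific)) {
                num <- expectedProportion(q_pre[!pre_specific],
                                          q_post[!pre_specific], th_l)
                den <- expectedProportion(q_pre[!pre_specific],
                                          q_post[!pre_specific], th_m)
                e <- ifelse(num > 0 & den > 0, log2(num / den), NA_real_)
                expd[!pre_specific] <- e
            }
            recs[[length(recs) + 1L]] <- data.frame(
                feature_id = feats, subject = s,
                level_l = pairs$level_l[p], level_m = pairs$level_m[p],
                theta_l = th_l, theta_m = th_m,
                estimated_logfc = unname(est), expected_logfc = expd,
                error = abs(expd - unname(est)),
                stringsAsFactors = FALSE)
        }
    }
    records <- if (length(recs)) do.call(rbind, recs) else
        data.frame(feature_id = character(), subject = character(),
                   level_l = character(), level_m = character(),
                   theta_l = numeric(), theta_m = numeric(),
                   estimated_logfc = numeric(), expected_logfc = numeric(),
                   error = numeric(), stringsAsFactors = FALSE)
    rownames(records) <- NULL
    feats <- do.call(rbind, lapply(
        split(records, paste(records$subject, records$feature_id)),
        function(d) {
            fit <- featureLogFCFit(d$estimated_logfc, d$expected_logfc)
            data.frame(feature_id = d$feature_id[1L],
                       subject = d$subject[1L],
                       slope = fit$slope, intercept = fit$intercept,
                       r_squared = fit$r_squared, bias = fit$bias,
                       n_pairs = fit$n_pairs, skipped = fit$skipped,
                       stringsAsFactors = FALSE)
        }))
    if (is.null(feats))
        feats <- data.frame(feature_id = character(), subject = character(),
                            slope = numeric(), intercept = numeric(),
                            r_squared = numeric(), bias = numeric(),
                            n_pairs = integer(), skipped = logical(),
                            stringsAsFactors = FALSE)
    rownames(feats) <- NULL
    list(records = records, features = feats, excluded_subjects = excluded)
}
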