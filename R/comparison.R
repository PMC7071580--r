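#' Median-centered IQR outlier filter
#'
#' Retains values within \code{median +/- 1.5 * IQR} (the framework's
#' literal rule: the band is centered on the median, not anchored at the
#' quartiles). The conventional quartile-anchored Tukey fence
#' \code{[Q1 - 1.5 IQR, Q3 + 1.5 IQR]} is available via
#' \code{rule = "quartile"}. Quantiles use linear interpolation. With zero
#' IQR only exact-median values are retained under the median rule.
#'
#' @param values numeric vector (at least 4 values).
#' @param rule \code{"median"} (default) or \code{"quartile"}.
#' @return list with \code{retained} (values), \code{keep} (logical mask)
#'   and \code{n_excluded}.
#' @examples
#' metricOutlierFilter(c(1, 2, 3, 4))$n_excluded  # 0
#' @export
metricOutlierFilter <- function(values, rule = c("median", "quartile")) {
    rule <- match.arg(rule)
    if (length(values) < 4L)
        stop("at least 4 values are required")
    q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3L] - q[1L]
    if (rule == "median") {
        lo <- q[2L] - 1.5 * iqr
        hi <- q[2L] + 1.5 * iqr
    } else {
        lo <- q[1L] - 1.5 * iqr
        hi <- q[3L] + 1.5 * iqr
    }
    keep <- values >= lo & values <= hi
    list(retained = values[keep], keep = keep, n_excluded = sum(!keep))
}

#' Mixed-effects comparison of feature-level metrics across pipelines
#'
#' Fits \eqn{e_{ijk} = b + b_i + z_j + \epsilon_{ijk}} by REML, where
#' \eqn{e_{ijk}} are feature-level metric values for pipeline \eqn{i} and
#' subject \eqn{j}, \eqn{b_i} is a fixed pipeline effect and \eqn{z_j} a
#' random subject intercept. With a single subject, or when the random
#' intercept is estimated at zero (singular fit), the model falls back to
#' a fixed-effects linear model with a flag.
#'
#' @param observations \code{data.frame} with columns \code{pipeline},
#'   \code{subject}, \code{value} (outliers already filtered).
#' @return list with \code{model} (the \code{lmerMod} or \code{lm} fit),
#'   \code{fixed} (pipeline effect estimates), \code{vcov} (their
#'   covariance), \code{pipelines}, \code{df} (residual df by the
#'   containment method), \code{singular_fallback},
#'   \code{subject_sd}, \code{residual_sd}, \code{anova_f} and
#'   \code{anova_p} (pipeline-effect F test).
#' @export
fitMetricModel <- function(observations) {
    need <- c("pipeline", "subject", "value")
    miss <- setdiff(need, colnames(observations))
    if (length(miss))
        stop("observations miss column(s): ", paste(miss, collapse = ", "))
    obs <- observations[is.finite(observations$value), , drop = FALSE]
    obs$pipeline <- factor(obs$pipeline)
    obs$subject <- factor(obs$subject)
    if (nlevels(obs$pipeline) < 2L)
        stop("at least 2 pipelines are required")
    n <- nrow(obs)
    k <- nlevels(obs$pipeline)
    j <- nlevels(obs$subject)
    fallback <- j < 2L
    fit <- NULL
    if (!fallback) {
        fit <- suppressMessages(
            lme4::lmer(value ~ pipeline + (1 | subject), data = obs,
                       REML = TRUE))
        fallback <- lme4::isSingular(fit, tol = 1e-5)
    }
    if (fallback) {
        fit <- stats::lm(value ~ pipeline, data = obs)
        fixed <- stats::coef(fit)
        V <- stats::vcov(fit)
        df <- n - k
        subject_sd <- 0
        residual_sd <- summary(fit)$sigma
        a <- stats::anova(fit)
        anova_f <- a$`F value`[1L]
        anova_p <- a$`Pr(>F)`[1L]
    } else {
        fixed <- lme4::fixef(fit)
        V <- as.matrix(stats::vcov(fit))
        ## containment df: pipeline varies within subjects
        df <- n - k - (j - 1L)
        vc <- as.data.frame(lme4::VarCorr(fit))
        subject_sd <- vc$sdcor[vc$grp == "subject"]
        residual_sd <- vc$sdcor[vc$grp == "Residual"]
        a <- stats::anova(fit)
        ms <- a["pipeline", "Mean Sq"]
        anova_f <- ms / residual_sd^2
        anova_p <- stats::pf(anova_f, k - 1L, df, lower.tail = FALSE)
    }
    list(model = fit, fixed = fixed, vcov = V,
         pipelines = levels(obs$pipeline), df = df,
         singular_fallback = fallback,
         subject_sd = subject_sd, residual_sd = residual_sd,
         anova_f = anova_f, anova_p = anova_p)
}

#' Tukey HSD pairwise pipeline comparisons
#'
#' All pairwise pipeline contrasts from a \code{\link{fitMetricModel}}
#' fit, with p-values adjusted via the studentized range distribution
#' (Tukey HSD) at the fit's containment degrees of freedom. With
#' \code{one_sided = TRUE} the alternative is "the first pipeline of the
#' pair has the smaller metric" (smaller error is better): the one-sided
#' adjusted p is half the two-sided Tukey p when the estimate points in
#' the alternative's direction.
#'
#' @param fit result of \code{\link{fitMetricModel}}.
#' @param one_sided use the one-sided "less" alternative (default TRUE).
#' @return \code{data.frame}: \code{pipeline_a}, \code{pipeline_b},
#'   \code{estimate} (a minus b), \code{se}, \code{t}, \code{adj_p}.
#' @export
tukeyPairwise <- function(fit, one_sided = TRUE) {
    pl <- fit$pipelines
    k <- length(pl)
    if (k < 2L)
        stop("at least 2 pipelines are required")
    ## cell means: intercept + effect (treatment contrasts)
    est <- c(0, fit$fixed[-1L])
    names(est) <- pl
    idx <- utils::combn(k, 2L)
    out <- do.call(rbind, lapply(seq_len(ncol(idx)), function(c2) {
        a <- idx[1L, c2]
        b <- idx[2L, c2]
        contrast <- numeric(length(fit$fixed))
        if (a > 1L) contrast[a] <- 1
        if (b > 1L) contrast[b] <- contrast[b] - 1
        d <- est[a] - est[b]
        se <- sqrt(drop(t(contrast) %*% fit$vcov %*% contrast))
        tt <- d / se
        p2 <- stats::ptukey(sqrt(2) * abs(tt), nmeans = k, df = fit$df,
                            lower.tail = FALSE)
        p <- if (!one_sided) p2 else if (d < 0) p2 / 2 else 1 - p2 / 2
        data.frame(pipeline_a = pl[a], pipeline_b = pl[b],
                   estimate = unname(d), se = se, t = unname(tt),
                   adj_p = unname(p), stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

#' Compare feature-level metrics across pipelines
#'
#' End-to-end comparison stage: concatenates per-feature metric summaries
#' from several pipelines, removes outliers with
#' \code{\link{metricOutlierFilter}} (within pipeline), fits the
#' mixed-effects model and computes one-sided Tukey HSD contrasts.
#'
#' @param summaries named list of per-feature summary \code{data.frame}s
#'   (as produced by \code{\link{assessRelativeAbundance}} or
#'   \code{\link{assessLogFC}}), one per pipeline; names are the pipeline
#'   ids.
#' @param metric column to compare (\code{"bias"}, \code{"variance"},
#'   \code{"r_squared"}, ...).
#' @param outlier_rule see \code{\link{metricOutlierFilter}}; \code{"none"}
#'   disables filtering.
#' @param one_sided see \code{\link{tukeyPairwise}}.
#' @return list with \code{fit}, \code{pairwise}, \code{n_excluded},
#'   \code{observations} and \code{means} (per-pipeline metric means, for
#'   ranking).
#' @export
comparePipelines <- function(summaries, metric = "bias",
                             outlier_rule = c("median", "quartile", "none"),
                             one_sided = TRUE) {
    outlier_rule <- match.arg(outlier_rule)
    if (is.null(names(summaries)) || any(names(summaries) == ""))
        stop("'summaries' must be a named list (pipeline ids)")
    obs <- do.call(rbind, lapply(names(summaries), function(pid) {
        d <- summaries[[pid]]
        if (!metric %in% colnames(d))
            stop("metric '", metric, "' not found for pipeline '", pid, "'")
        data.frame(pipeline = pid, subject = d$subject,
                   value = d[[metric]], stringsAsFactors = FALSE)
    }))
    obs <- obs[is.finite(obs$value), , drop = FALSE]
    n_excluded <- 0L
    if (outlier_rule != "none") {
        kept <- unlist(lapply(split(seq_len(nrow(obs)), obs$pipeline),
            function(i) {
                if (length(i) < 4L) return(i)
                i[metricOutlierFilter(obs$value[i], rule = outlier_rule)$keep]
            }))
        n_excluded <- nrow(obs) - length(kept)
        obs <- obs[sort(kept), , drop = FALSE]
    }
    fit <- fitMetricModel(obs)
    pw <- tukeyPairwise(fit, one_sided = one_sided)
    means <- tapply(obs$value, obs$pipeline, mean)
    list(fit = fit, pairwise = pw, n_excluded = n_excluded,
         observations = obs, means = means)
}
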