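## Run code under a temporary RNG state so seeded helpers do not disturb
## the caller's stream.
.withSeed <- function(seed, code) {
    if (is.null(seed))
        return(force(code))
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
                add = TRUE)
    }
    set.seed(seed)
    force(code)
}

## Deterministic 31-bit hash of id strings; used to derive per-test RNG
## substreams from a single run seed.
.strHash <- function(...) {
    s <- paste(..., sep = "\r")
    h <- 0
    for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
    as.integer(h)
}

#' Minimum detectable mixture proportion
#'
#' The detection floor used as reference proportion by the Bayesian
#' titration-specific test: the mixture expectation evaluated at the
#' subject-level minimum observed nonzero PRE and POST relative abundances,
#' \eqn{\pi_{min} = \theta \min(Q_{post}) + (1-\theta)\min(Q_{pre})}.
#'
#' @param theta POST proportion of the titration, in [0, 1].
#' @param min_q_pre,min_q_post minimum nonzero feature relative abundance
#'   in the unmixed PRE / POST samples.
#' @return \eqn{\pi_{min}}, a proportion.
#' @examples
#' piMin(0.5, 1e-4, 2e-4)  # 1.5e-4
#' @export
piMin <- function(theta, min_q_pre, min_q_post) {
    if (all(min_q_pre == 0 & min_q_post == 0))
        stop("both minimum proportions are zero; pi_min is undefined")
    expectedProportion(min_q_pre, min_q_post, theta)
}

#' Binomial sampling test for unmixed-specific features
#'
#' One-sided lower-tail binomial test of whether a feature's absence (or
#' low count) in a titration PCR replicate is consistent with random
#' sampling at the replicate's depth: \eqn{p = P(X \le C_{obs})} for
#' \eqn{X \sim Binomial(N, q)} with \eqn{q} the expected mixture
#' proportion. At \eqn{C_{obs} = 0} this is \eqn{(1-q)^N}. A degenerate
#' expectation \eqn{q = 0} fully explains absence and returns 1.
#'
#' @param c_obs observed count(s) in the replicate.
#' @param n replicate sequencing depth(s).
#' @param q_expected expected feature proportion(s) under the mixture
#'   design.
#' @return one-sided p-value(s).
#' @examples
#' binomialAbsenceTest(0, 1000, 0.001)  # 0.999^1000
#' @export
binomialAbsenceTest <- function(c_obs, n, q_expected) {
    if (any(c_obs < 0) || any(c_obs > n))
        stop("'c_obs' must lie in [0, n]")
    if (any(q_expected < 0 | q_expected > 1))
        stop("'q_expected' must lie in [0, 1]")
    stats::pbinom(c_obs, size = n, prob = q_expected)
}

#' Monte Carlo Bayesian sampling test for titration-specific features
#'
#' Titration-specific features have zero counts in the unmixed samples, so
#' the binomial test's expected proportion is zero and the test fails.
#' Instead the posterior probability that the true feature proportion
#' \eqn{\pi} lies below the detection floor \eqn{\pi_{min}} given that at
#' least \eqn{C_{obs}} counts were observed is used:
#' \deqn{p = P(\pi < \pi_{min} \mid C \ge C_{obs})
#'   = \frac{P(C \ge C_{obs} \mid \pi < \pi_{min}) w}
#'          {P(C \ge C_{obs} \mid \pi < \pi_{min}) w +
#'           P(C \ge C_{obs} \mid \pi \ge \pi_{min}) (1 - w)}}
#' with prior null mass \eqn{w}, \eqn{\pi \sim Uniform(0, \pi_{min})} under
#' the null and \eqn{\pi \sim \pi_{min} + (1-\pi_{min}) Beta(\alpha,\beta)}
#' under the alternative. The conditional tail probabilities are estimated
#' by Monte Carlo over \eqn{\pi} with the binomial tail computed exactly
#' for each draw (the draw of \eqn{C} is marginalized out), which makes the
#' estimate deterministic given \code{seed} and monotone non-increasing in
#' \code{c_obs} under common random numbers. At \eqn{C_{obs} = 0} the
#' tails are 1 and \eqn{p = w} exactly.
#'
#' @param c_obs observed count in the titration PCR replicate.
#' @param n replicate sequencing depth.
#' @param pi_min detection floor, in (0, 1); see \code{\link{piMin}}.
#' @param alpha,beta shape parameters of the alternative's Beta prior
#'   (default 1, 1: uniform above \eqn{\pi_{min}}).
#' @param prior_null_mass prior mass \eqn{w} on \eqn{\pi < \pi_{min}}
#'   (default 0.5, equal priors).
#' @param n_draws Monte Carlo draws (default 1e5).
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @return posterior probability that sampling alone explains the
#'   observation; small values flag the feature as artifactual. Carries an
#'   attribute \code{mc_se}, the Monte Carlo standard error.
#' @examples
#' bayesTitrationTest(0, 1e4, 1e-4)   # exactly 0.5 under equal priors
#' bayesTitrationTest(50, 1e4, 1e-4, seed = 1)
#' @export
bayesTitrationTest <- function(c_obs, n, pi_min, alpha = 1, beta = 1,
                               prior_null_mass = 0.5, n_draws = 1e5,
                               seed = NULL) {
    if (length(pi_min) != 1L || is.na(pi_min) || pi_min <= 0 || pi_min >= 1)
        stop("'pi_min' must lie strictly inside (0, 1)")
    if (c_obs > n)
        stop("'c_obs' cannot exceed the depth 'n'")
    stopifnot(alpha > 0, beta > 0,
              prior_null_mass > 0, prior_null_mass < 1, n_draws >= 1)
    w <- prior_null_mass
    if (c_obs == 0) {
        out <- w
        attr(out, "mc_se") <- 0
        return(out)
    }
    .withSeed(seed, {
        pi0 <- stats::runif(n_draws, 0, pi_min)
        pi1 <- pi_min + (1 - pi_min) * stats::rbeta(n_draws, alpha, beta)
        t0 <- stats::pbinom(c_obs - 1, n, pi0, lower.tail = FALSE)
        t1 <- stats::pbinom(c_obs - 1, n, pi1, lower.tail = FALSE)
        num <- w * mean(t0)
        den <- num + (1 - w) * mean(t1)
        if (den == 0) {
            warning("zero acceptance probability in Monte Carlo; returning 1")
            out <- 1
            attr(out, "mc_se") <- NA_real_
            return(out)
        }
        p <- num / den
        ## delta-method SE of the ratio from the two independent MC means
        se0 <- stats::sd(t0) / sqrt(n_draws)
        se1 <- stats::sd(t1) / sqrt(n_draws)
        g0 <- w * (1 - p) / den
        g1 <- (1 - w) * p / den
        attr(p, "mc_se") <- sqrt((g0 * se0)^2 + (g1 * se1)^2)
        p
    })
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values
#' (order-preserving, capped at 1).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same order as \code{p}.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))
#' @export
bhAdjust <- function(p) {
    if (anyNA(p) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Qualitative assessment: sampling tests for artifact-candidate features
#'
#' Runs the framework's presence/absence hypothesis tests on a titration
#' experiment. Unmixed-specific features (observed only in unmixed
#' samples) are tested with the one-sided binomial test in every titration
#' PCR replicate of their subject, using the mixture expectation of their
#' pooled unmixed proportions as reference. Titration-specific features
#' (observed only in titrations) are tested with the Monte Carlo Bayesian
#' test in every titration replicate where they were observed, against the
#' subject-level detection floor \eqn{\pi_{min}}. P-values are BH-adjusted
#' within each (subject, test kind) family.
#'
#' @param te a \linkS4class{TitrationExperiment}.
#' @param catalog a \linkS4class{FeatureCatalog} built from \code{te}; if
#'   missing it is built with default settings.
#' @param theta optional theta estimates (the \code{data.frame} returned by
#'   \code{\link{inferThetaAll}}); when supplied, inferred \eqn{\theta}
#'   values replace the design values in the mixture expectations.
#' @param alpha flagging threshold on the adjusted p-value (default 0.05).
#' @param prior_alpha,prior_beta,prior_null_mass,n_draws Bayesian test
#'   configuration, see \code{\link{bayesTitrationTest}}.
#' @param seed integer seed; per-test substreams are derived by hashing
#'   the (feature, sample) ids so results do not depend on test order.
#' @return \code{data.frame} with one row per test: \code{feature_id},
#'   \code{subject}, \code{sample_id}, \code{titration_factor},
#'   \code{test_kind} (\code{"binomial"}/\code{"bayesian"}), \code{c_obs},
#'   \code{depth}, \code{reference_proportion}, \code{p}, \code{adj_p},
#'   \code{flagged}.
#' @export
assessQualitative <- function(te, catalog = NULL, theta = NULL,
                              alpha = 0.05, prior_alpha = 1, prior_beta = 1,
                              prior_null_mass = 0.5, n_draws = 1e5,
                              seed = 1L) {
    stopifnot(is(te, "TitrationExperiment"))
    if (is.null(catalog)) catalog <- buildCatalog(te)
    cd <- SummarizedExperiment::colData(te)
    m <- counts(te)
    depth <- colSums(m)
    out <- list()
    for (s in subjects(te)) {
        cat_s <- catalog[catalog$subject == s, ]
        i_titr <- which(!is.na(cd$subject) & cd$subject == s &
                        cd$sample_type == "TITRATION")
        if (!length(i_titr)) next
        th_design <- thetaFromFactor(cd$titration_factor[i_titr])
        th <- th_design
        if (!is.null(theta)) {
            key <- match(paste(s, cd$titration_factor[i_titr]),
                         paste(theta$subject, theta$titration_factor))
            th <- ifelse(is.na(key), th_design, theta$theta_hat[key])
        }
        ## binomial tests: unmixed-specific features x titration replicates
        um <- cat_s[cat_s$feature_type == "UNMIXED_SPECIFIC", ]
        if (nrow(um)) {
            fid <- as.character(um$feature_id)
            for (k in seq_along(i_titr)) {
                j <- i_titr[k]
                q_exp <- expectedProportion(um$q_pre, um$q_post, th[k])
                c_obs <- m[fid, j]
                out[[length(out) + 1L]] <- data.frame(
                    feature_id = fid, subject = s,
                    sample_id = colnames(m)[j],
                    titration_factor = cd$titration_factor[j],
                    test_kind = "binomial",
                    c_obs = c_obs, depth = depth[j],
                    reference_proportion = q_exp,
                    p = binomialAbsenceTest(c_obs, depth[j], q_exp),
                    stringsAsFactors = FALSE)
            }
        }
        ## Bayesian tests: titration-specific features x replicates with
        ## nonzero counts, against the subject detection floor
        ts <- cat_s[cat_s$feature_type == "TITRATION_SPECIFIC", ]
        if (nrow(ts)) {
            qp <- cat_s$q_pre[cat_s$q_pre > 0]
            qq <- cat_s$q_post[cat_s$q_post > 0]
            min_q_pre <- if (length(qp)) min(qp) else 0
            min_q_post <- if (length(qq)) min(qq) else 0
            fid <- as.character(ts$feature_id)
            for (k in seq_along(i_titr)) {
                j <- i_titr[k]
                c_obs <- m[fid, j]
                keep <- which(c_obs > 0)
                if (!length(keep)) next
                pm <- piMin(th[k], min_q_pre, min_q_post)
                pvals <- vapply(keep, function(r) {
                    as.numeric(bayesTitrationTest(
                        c_obs[r], depth[j], pm,
                        alpha = prior_alpha, beta = prior_beta,
                        prior_null_mass = prior_null_mass,
                        n_draws = n_draws,
                        seed = (seed + .strHash(fid[r], colnames(m)[j])) %%
                            2147483647))
                }, numeric(1))
                out[[length(out) + 1L]] <- data.frame(
                    feature_id = fid[keep], subject = s,
                    sample_id = colnames(m)[j],
                    titration_factor = cd$titration_factor[j],
                    test_kind = "bayesian",
                    c_obs = c_obs[keep], depth = depth[j],
                    reference_proportion = pm,
                    p = pvals, stringsAsFactors = FALSE)
            }
        }
    }
    if (!length(out)) {
        return(data.frame(
            feature_id = character(), subject = character(),
            sample_id = character(), titration_factor = integer(),
            test_kind = character(), c_obs = numeric(), depth = numeric(),
            reference_proportion = numeric(), p = numeric(),
            adj_p = numeric(), flagged = logical(),
            stringsAsFactors = FALSE))
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res$adj_p <- NA_real_
    for (fam in split(seq_len(nrow(res)),
                      paste(res$subject, res$test_kind))) {
        res$adj_p[fam] <- bhAdjust(res$p[fam])
    }
    res$flagged <- res$adj_p < alpha
    res
}

#' Artifactual feature proportion
#'
#' Fraction of unmixed- and titration-specific feature observations that
#' random sampling cannot explain: tests with BH-adjusted p below
#' \code{alpha}. With \code{unit = "replicate"} every test counts once;
#' with \code{unit = "feature"} a feature is artifactual when any of its
#' replicate tests is flagged. The proportion is reported overall and
#' stratified by subject and test kind; an empty stratum yields \code{NaN}
#' (undefined), not 0.
#'
#' @param tests the test table returned by \code{\link{assessQualitative}}.
#' @param alpha flagging threshold on the adjusted p-value (default 0.05).
#' @param unit aggregation unit, \code{"replicate"} (default) or
#'   \code{"feature"}.
#' @return \code{data.frame} with columns \code{subject},
#'   \code{test_kind} (including an \code{"all"} margin), \code{n_flagged},
#'   \code{n_total}, \code{proportion}.
#' @export
artifactualFeatureProportion <- function(tests, alpha = 0.05,
                                         unit = c("replicate", "feature")) {
    unit <- match.arg(unit)
    if (nrow(tests) == 0L) {
        return(data.frame(subject = "all", test_kind = "all",
                          n_flagged = 0L, n_total = 0L,
                          proportion = NaN, stringsAsFactors = FALSE))
    }
    flag <- tests$adj_p < alpha
    if (unit == "feature") {
        key <- paste(tests$subject, tests$test_kind, tests$feature_id)
        agg <- tapply(flag, key, any)
        first <- !duplicated(key)
        tests <- tests[first, , drop = FALSE]
        flag <- as.logical(agg[paste(tests$subject, tests$test_kind,
                                     tests$feature_id)])
    }
    strata <- rbind(
        data.frame(subject = "all", test_kind = "all",
                   stringsAsFactors = FALSE),
        unique(data.frame(subject = "all", test_kind = tests$test_kind,
                          stringsAsFactors = FALSE)),
        unique(data.frame(subject = tests$subject,
                          test_kind = tests$test_kind,
                          stringsAsFactors = FALSE)))
    strata <- unique(strata)
    res <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
        sel <- rep(TRUE, nrow(tests))
        if (strata$subject[i] != "all")
            sel <- sel & tests$subject == strata$subject[i]
        if (strata$test_kind[i] != "all")
            sel <- sel & tests$test_kind == strata$test_kind[i]
        n <- sum(sel)
        data.frame(subject = strata$subject[i],
                   test_kind = strata$test_kind[i],
                   n_flagged = sum(flag[sel]), n_total = n,
                   proportion = if (n) sum(flag[sel]) / n else NaN,
                   stringsAsFactors = FALSE)
    }))
    rownames(res) <- NULL
    res
}
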