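#' Design POST proportion for a titration factor
#'
#' In the log2 dilution series a titration with factor \eqn{t} contains a
#' POST DNA proportion \eqn{\theta = 2^{-t}}; factor 0 denotes the unmixed
#' POST sample (\eqn{\theta = 1}).
#'
#' @param factor non-negative integer titration factor(s).
#' @return design \eqn{\theta}, in (0, 1].
#' @examples
#' thetaFromFactor(1)   # 0.5
#' thetaFromFactor(15)  # 1/32768
#' @export
thetaFromFactor <- function(factor) {
    if (anyNA(factor) || any(factor < 0))
        stop("titration factor must be non-negative")
    2^-as.numeric(factor)
}

#' Expected mixture proportion of a feature in a titration
#'
#' The two-sample mixture expectation: a titration with POST proportion
#' \eqn{\theta} has expected feature proportion
#' \deqn{q = \theta q_{post} + (1 - \theta) q_{pre}.}
#'
#' @param q_pre,q_post feature relative abundance in the unmixed PRE and
#'   POST samples, in [0, 1]. Vectorized.
#' @param theta POST proportion(s) in [0, 1].
#' @return expected proportion(s), always between \code{q_pre} and
#'   \code{q_post}.
#' @examples
#' expectedProportion(0.2, 0.4, 0.5)  # 0.3
#' @export
expectedProportion <- function(q_pre, q_post, theta) {
    stopifnot(length(q_pre) >= 1L)
    bad <- function(x) anyNA(x) || any(x < 0 | x > 1)
    if (bad(q_pre) || bad(q_post) || bad(theta))
        stop("'q_pre', 'q_post' and 'theta' must lie in [0, 1]")
    theta * q_post + (1 - theta) * q_pre
}

#' Expected log2 fold-change of a feature between two titrations
#'
#' Expected log2 fold-change between mixture levels \eqn{l} and \eqn{m},
#' the log2 ratio of the two mixture expectations:
#' \deqn{logFC_{lm} = \log_2\frac{\theta_l q_{post} + (1-\theta_l) q_{pre}}
#'                               {\theta_m q_{post} + (1-\theta_m) q_{pre}}.}
#'
#' @inheritParams expectedProportion
#' @param theta_l,theta_m POST proportions of the two mixture levels.
#' @return expected log2 fold-change; \code{-Inf}/\code{Inf} when only one
#'   of the mixture expectations is zero.
#' @examples
#' expectedLogFC(0.2, 0.4, 0.5, 0)  # log2(0.3/0.2)
#' @export
expectedLogFC <- function(q_pre, q_post, theta_l, theta_m) {
    num <- expectedProportion(q_pre, q_post, theta_l)
    den <- expectedProportion(q_pre, q_post, theta_m)
    if (any(num == 0 & den == 0))
        stop("expected log fold-change undefined: both mixture values zero")
    log2(num) - log2(den)
}

#' Expected log2 fold-change for a PRE-specific feature
#'
#' For features absent from the POST sample (\eqn{q_{post} = 0}) the
#' expected log2 fold-change between mixture levels does not depend on the
#' observed unmixed counts:
#' \deqn{logFC_{lm} = \log_2\frac{1-\theta_l}{1-\theta_m}.}
#'
#' @param theta_l,theta_m POST proportions of the two mixture levels; both
#'   must be < 1.
#' @return expected log2 fold-change.
#' @examples
#' expectedLogFCPreSpecific(0.5, 0)  # -1
#' @export
expectedLogFCPreSpecific <- function(theta_l, theta_m) {
    if (any(theta_l >= 1) || any(theta_m >= 1))
        stop("PRE-specific expected log fold-change undefined at theta = 1")
    log2(1 - theta_l) - log2(1 - theta_m)
}

#' Paired-end overlap of an amplicon
#'
#' Overlap length between forward and reverse reads for a given amplicon:
#' \code{2 * read_length - amplicon_length}. The framework's reference
#' dataset targets the 464 bp V3-V5 16S rRNA region with 2 x 300 bp
#' paired-end sequencing, a 136 bp overlap.
#'
#' @param read_length read length in bp.
#' @param amplicon_length amplicon length in bp.
#' @return overlap in bp.
#' @examples
#' ampliconOverlap(300, 464)  # 136
#' @export
ampliconOverlap <- function(read_length, amplicon_length) {
    if (any(read_length <= 0) || any(amplicon_length <= 0))
        stop("lengths must be positive")
    2 * read_length - amplicon_length
}

#' Enumerate the samples of a titration design
#'
#' Expands a \linkS4class{TitrationDesign} into one row per PCR assay:
#' every subject x mixture level x PCR replicate, plus the no-template
#' controls. Ordering is deterministic: subject, then descending
#' \eqn{\theta} (POST, titrations, PRE), then replicate; NTC wells last.
#'
#' @param design a \linkS4class{TitrationDesign}.
#' @return \code{data.frame} with columns \code{sample_id}, \code{subject},
#'   \code{sample_type}, \code{titration_factor}, \code{theta},
#'   \code{pcr_replicate}.
#' @examples
#' d <- TitrationDesign("S1", c(1, 2), pcrReplicates = 2)
#' enumerateSamples(d)
#' @export
enumerateSamples <- function(design) {
    stopifnot(is(design, "TitrationDesign"))
    tf <- titrationFactors(design)
    lev <- data.frame(
        sample_type = rep("TITRATION", length(tf)),
        titration_factor = tf,
        theta = thetaFromFactor(tf),
        stringsAsFactors = FALSE)
    if (design@includeUnmixed) {
        lev <- rbind(
            data.frame(sample_type = "POST", titration_factor = NA_integer_,
                       theta = 1),
            lev,
            data.frame(sample_type = "PRE", titration_factor = NA_integer_,
                       theta = 0))
    }
    lev <- lev[order(-lev$theta), , drop = FALSE]
    reps <- seq_len(design@pcrReplicates)
    out <- do.call(rbind, lapply(subjects(design), function(s) {
        do.call(rbind, lapply(seq_len(nrow(lev)), function(i) {
            data.frame(
                subject = s,
                sample_type = lev$sample_type[i],
                titration_factor = lev$titration_factor[i],
                theta = lev$theta[i],
                pcr_replicate = reps,
                stringsAsFactors = FALSE)
        }))
    }))
    if (design@nNTC > 0L) {
        out <- rbind(out, data.frame(
            subject = NA_character_,
            sample_type = "NTC",
            titration_factor = NA_integer_,
            theta = NA_real_,
            pcr_replicate = seq_len(design@nNTC),
            stringsAsFactors = FALSE))
    }
    lab <- ifelse(out$sample_type == "TITRATION",
                  sprintf("T%02d", out$titration_factor), out$sample_type)
    out$sample_id <- ifelse(out$sample_type == "NTC",
                            sprintf("NTC_R%02d", out$pcr_replicate),
                            sprintf("%s_%s_R%d", out$subject, lab,
                                    out$pcr_replicate))
    rownames(out) <- NULL
    out[, c("sample_id", "subject", "sample_type", "titration_factor",
            "theta", "pcr_replicate")]
}

#' Effective POST proportion under unequal prokaryotic DNA content
#'
#' Stool DNA extracts contain both eukaryotic and prokaryotic DNA. If the
#' unmixed PRE and POST samples carry prokaryotic DNA proportions
#' \eqn{\gamma_{pre}} and \eqn{\gamma_{post}}, the POST fraction visible to
#' 16S rRNA sequencing in a titration with design proportion \eqn{\theta} is
#' \deqn{\theta_{eff} = \frac{\theta\gamma_{post}}
#'       {\theta\gamma_{post} + (1-\theta)\gamma_{pre}}.}
#' Equal \eqn{\gamma} values recover the design \eqn{\theta}.
#'
#' @param theta_design design POST proportion(s) in [0, 1].
#' @param gamma_pre,gamma_post prokaryotic DNA proportions of the unmixed
#'   samples, each in (0, 1].
#' @return effective POST proportion(s) in [0, 1].
#' @examples
#' effectiveTheta(0.5, 0.5, 1.0)  # 2/3
#' @export
effectiveTheta <- function(theta_design, gamma_pre, gamma_post) {
    if (any(gamma_pre <= 0 | gamma_pre > 1) ||
        any(gamma_post <= 0 | gamma_post > 1))
        stop("'gamma_pre' and 'gamma_post' must lie in (0, 1]")
    if (anyNA(theta_design) || any(theta_design < 0 | theta_design > 1))
        stop("'theta_design' must lie in [0, 1]")
    den <- theta_design * gamma_post + (1 - theta_design) * gamma_pre
    if (any(den == 0))
        stop("degenerate mixture: zero prokaryotic DNA")
    theta_design * gamma_post / den
}
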