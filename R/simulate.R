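#' SimulationConfig: parameters of the synthetic titration generator
#'
#' Configuration of \code{\link{simulateDataset}}. Feature compositions
#' are drawn per subject from a log-normal abundance model and renormalized
#' to proportions, with class structure imposed: shared features occur in
#' both unmixed samples (log2 PRE:POST ratio within +/- 3),
#' PRE-/POST-specific features in only one, and PRE-/POST-dominant
#' features in both with a log2 ratio of 7-10 (above the dominance
#' threshold of 5 with margin for normalization shift and sampling
#' noise). Unequal prokaryotic DNA
#' proportions \eqn{\gamma_{pre}, \gamma_{post}} distort the design
#' \eqn{\theta} into the effective \eqn{\theta} actually sampled (see
#' \code{\link{effectiveTheta}}). Sequencing is multinomial per PCR
#' replicate at a negative-binomially drawn depth, optionally with a
#' Dirichlet-multinomial overdispersion layer emulating PCR replicate
#' variance. Artifacts are injected afterwards and recorded: false
#' positives add a novel low-abundance feature (count 1-5) to a random
#' sample; false negatives zero a (feature, sample) cell.
#'
#' @slot nShared,nPreSpecific,nPostSpecific,nPreDominant,nPostDominant
#'   features per class.
#' @slot meanlog,sdlog log-normal abundance parameters.
#' @slot minProportion optional floor on nonzero proportions (0 = off);
#'   setting it to a few times \code{1/depthMean} yields a detection-safe
#'   dataset where every true feature is observed in every replicate.
#' @slot gammaPre,gammaPost prokaryotic DNA proportions of the unmixed
#'   samples, recycled across subjects.
#' @slot depthMean,depthDispersion negative binomial depth model (mean and
#'   size; large size approaches Poisson).
#' @slot dmPrecision Dirichlet-multinomial precision (0 = pure
#'   multinomial).
#' @slot falsePositiveRate expected spurious features injected per sample.
#' @slot falseNegativeRate per-(feature, sample) dropout probability.
#' @slot seed integer RNG seed.
#' @name SimulationConfig-class
#' @aliases SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig",
    representation(
        nShared = "integer", nPreSpecific = "integer",
        nPostSpecific = "integer", nPreDominant = "integer",
        nPostDominant = "integer",
        meanlog = "numeric", sdlog = "numeric", minProportion = "numeric",
        gammaPre = "numeric", gammaPost = "numeric",
        depthMean = "numeric", depthDispersion = "numeric",
        dmPrecision = "numeric",
        falsePositiveRate = "numeric", falseNegativeRate = "numeric",
        seed = "integer"
    )
)

setValidity("SimulationConfig", function(object) {
    msg <- NULL
    n <- object@nShared + object@nPreSpecific + object@nPostSpecific +
        object@nPreDominant + object@nPostDominant
    if (n < 1L)
        msg <- c(msg, "feature class counts must sum to at least 1")
    if (any(c(object@nShared, object@nPreSpecific, object@nPostSpecific,
              object@nPreDominant, object@nPostDominant) < 0L))
        msg <- c(msg, "feature class counts must be non-negative")
    if (object@sdlog < 0) msg <- c(msg, "'sdlog' must be non-negative")
    if (any(object@gammaPre <= 0 | object@gammaPre > 1) ||
        any(object@gammaPost <= 0 | object@gammaPost > 1))
        msg <- c(msg, "gamma values must lie in (0, 1]")
    if (object@depthMean < 1) msg <- c(msg, "'depthMean' must be >= 1")
    if (object@depthDispersion <= 0)
        msg <- c(msg, "'depthDispersion' must be positive")
    if (object@dmPrecision < 0)
        msg <- c(msg, "'dmPrecision' must be non-negative")
    if (object@falsePositiveRate < 0)
        msg <- c(msg, "'falsePositiveRate' must be non-negative")
    if (object@falseNegativeRate < 0 || object@falseNegativeRate > 1)
        msg <- c(msg, "'falseNegativeRate' must lie in [0, 1]")
    if (object@minProportion < 0 || object@minProportion >= 1)
        msg <- c(msg, "'minProportion' must lie in [0, 1)")
    if (is.null(msg)) TRUE else msg
})

#' Construct a SimulationConfig
#'
#' Defaults mirror the reference dataset's scale: ~100 features per
#' subject dominated by shared features with a small complement of
#' PRE-/POST-specific and -dominant features, log-normal abundances with
#' \code{sdlog = 2} (a realistic long-tailed 16S community), mean depth
#' 1e5 per PCR replicate, one spurious feature per sample and a 1 percent
#' per-cell dropout rate.
#'
#' @param nShared,nPreSpecific,nPostSpecific,nPreDominant,nPostDominant
#'   features per class.
#' @param meanlog,sdlog log-normal abundance parameters.
#' @param minProportion floor on nonzero proportions (default 0 = off).
#' @param gammaPre,gammaPost prokaryotic DNA proportions (default 1, 1:
#'   no distortion).
#' @param depthMean,depthDispersion negative binomial depth model.
#' @param dmPrecision Dirichlet-multinomial precision (default 0).
#' @param falsePositiveRate spurious features per sample (default 1).
#' @param falseNegativeRate per-cell dropout probability (default 0.01).
#' @param seed RNG seed.
#' @return a \linkS4class{SimulationConfig}.
#' @export
SimulationConfig <- function(nShared = 60L, nPreSpecific = 10L,
                             nPostSpecific = 10L, nPreDominant = 5L,
                             nPostDominant = 5L,
                             meanlog = 0, sdlog = 2, minProportion = 0,
                             gammaPre = 1, gammaPost = 1,
                             depthMean = 1e5, depthDispersion = 20,
                             dmPrecision = 0,
                             falsePositiveRate = 1,
                             falseNegativeRate = 0.01,
                             seed = 1L) {
    new("SimulationConfig",
        nShared = as.integer(nShared),
        nPreSpecific = as.integer(nPreSpecific),
        nPostSpecific = as.integer(nPostSpecific),
        nPreDominant = as.integer(nPreDominant),
        nPostDominant = as.integer(nPostDominant),
        meanlog = meanlog, sdlog = sdlog, minProportion = minProportion,
        gammaPre = gammaPre, gammaPost = gammaPost,
        depthMean = depthMean, depthDispersion = depthDispersion,
        dmPrecision = dmPrecision,
        falsePositiveRate = falsePositiveRate,
        falseNegativeRate = falseNegativeRate,
        seed = as.integer(seed))
}

## Feature class labels and ids for a config.
.simClasses <- function(config) {
    cls <- c(rep("SHARED_FULL", config@nShared),
             rep("PRE_SPECIFIC", config@nPreSpecific),
             rep("POST_SPECIFIC", config@nPostSpecific),
             rep("PRE_DOMINANT", config@nPreDominant),
             rep("POST_DOMINANT", config@nPostDominant))
    data.frame(feature_id = sprintf("F%04d", seq_along(cls)),
               class = cls, stringsAsFactors = FALSE)
}

## Draw one subject's PRE/POST composition honoring the class structure.
## Shared features get a POST abundance correlated with PRE (log2 ratio
## within +/- 3, safely below the dominance threshold of 5); dominant
## features get a ratio of 7-10, safely above it. The margins absorb the
## normalization shift between the PRE and POST profiles plus sampling
## noise, so the truth labels remain recoverable by classification.
.simComposition <- function(classes, config) {
    n <- nrow(classes)
    cls <- classes$class
    z <- stats::rlnorm(n, config@meanlog, config@sdlog)
    floor_abs <- config@minProportion * sum(z)
    if (floor_abs > 0) z <- pmax(z, floor_abs)
    q_pre <- z
    q_post <- z
    i <- cls == "SHARED_FULL"
    if (any(i)) {
        q_post[i] <- z[i] * 2^stats::runif(sum(i), -3, 3)
        if (floor_abs > 0) q_post[i] <- pmax(q_post[i], floor_abs)
    }
    q_post[cls == "PRE_SPECIFIC"] <- 0
    q_pre[cls == "POST_SPECIFIC"] <- 0
    i <- cls == "PRE_DOMINANT"
    if (any(i)) {
        r <- stats::runif(sum(i), 7, 10)
        q_pre[i] <- pmax(z[i], floor_abs * 2^(r + 1))
        q_post[i] <- q_pre[i] / 2^r
    }
    i <- cls == "POST_DOMINANT"
    if (any(i)) {
        r <- stats::runif(sum(i), 7, 10)
        q_post[i] <- pmax(z[i], floor_abs * 2^(r + 1))
        q_pre[i] <- q_post[i] / 2^r
    }
    list(q_pre = q_pre / sum(q_pre), q_post = q_post / sum(q_post))
}

## Expected proportion vector for one sample of the enumeration.
.simSampleProb <- function(row, comp, theta_eff_map) {
    switch(row$sample_type,
           PRE = comp$q_pre,
           POST = comp$q_post,
           TITRATION = expectedProportion(
               comp$q_pre, comp$q_post,
               theta_eff_map[[as.character(row$titration_factor)]]),
           NTC = NULL)
}

#' Simulate a titration dataset with known ground truth
#'
#' Generates a full titration experiment following a
#' \linkS4class{TitrationDesign}: per-subject PRE/POST compositions,
#' mixture proportions at the effective \eqn{\theta}, multinomial
#' (optionally Dirichlet-multinomial) counts per PCR replicate at
#' negative-binomially drawn depths, and injected false-positive /
#' false-negative artifacts recorded in a truth registry. Fully
#' reproducible from the config seed; the caller's RNG state is left
#' untouched. NTC wells are included as all-zero columns.
#'
#' @param design a \linkS4class{TitrationDesign}.
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with \code{te} (a \linkS4class{TitrationExperiment}) and
#'   \code{truth}: \code{classes} (feature class labels),
#'   \code{compositions} (per-subject true \code{q_pre}/\code{q_post}),
#'   \code{theta} (design and effective \eqn{\theta} per subject and
#'   titration), \code{artifacts} (registry of injected cells),
#'   \code{depths} (drawn pre-artifact depths).
#' @export
simulateDataset <- function(design, config = SimulationConfig()) {
    stopifnot(is(design, "TitrationDesign"), is(config, "SimulationConfig"))
    .withSeed(config@seed, .simulateCore(design, config, noiseless = FALSE))
}

#' Noiseless oracle titration dataset
#'
#' Like \code{\link{simulateDataset}} but with the sampling step removed:
#' every sample receives \code{depthMean} times its expected proportion
#' vector, with no depth variation and no artifacts. By default the cells
#' are exact (fractional) intensities so that downstream recovery is exact
#' to numerical precision; \code{round_counts = TRUE} rounds them to
#' integers (introducing an error bounded by 1/depth per cell).
#'
#' @param design a \linkS4class{TitrationDesign}.
#' @param config a \linkS4class{SimulationConfig}.
#' @param round_counts round cells to integers (default \code{FALSE}).
#' @return as \code{\link{simulateDataset}}.
#' @export
noiselessDataset <- function(design, config = SimulationConfig(),
                             round_counts = FALSE) {
    stopifnot(is(design, "TitrationDesign"), is(config, "SimulationConfig"))
    .withSeed(config@seed,
              .simulateCore(design, config, noiseless = TRUE,
                            round_counts = round_counts))
}

.simulateCore <- function(design, config, noiseless = FALSE,
                          round_counts = FALSE) {
    classes <- .simClasses(config)
    enum <- enumerateSamples(design)
    n_feat <- nrow(classes)
    gp <- rep(config@gammaPre, length.out = length(subjects(design)))
    gq <- rep(config@gammaPost, length.out = length(subjects(design)))
    names(gp) <- names(gq) <- subjects(design)

    comps <- lapply(subjects(design), function(s) .simComposition(classes,
                                                                  config))
    names(comps) <- subjects(design)
    tf <- titrationFactors(design)
    theta_tab <- do.call(rbind, lapply(subjects(design), function(s) {
        data.frame(subject = s, titration_factor = tf,
                   theta_design = thetaFromFactor(tf),
                   theta_effective = effectiveTheta(thetaFromFactor(tf),
                                                    gp[s], gq[s]),
                   stringsAsFactors = FALSE)
    }))

    m <- matrix(0, nrow = n_feat, ncol = nrow(enum),
                dimnames = list(classes$feature_id, enum$sample_id))
    depths <- numeric(nrow(enum))
    for (i in seq_len(nrow(enum))) {
        row <- enum[i, ]
        if (row$sample_type == "NTC") next
        comp <- comps[[row$subject]]
        th_map <- theta_tab[theta_tab$subject == row$subject, ]
        map <- stats::setNames(as.list(th_map$theta_effective),
                               th_map$titration_factor)
        prob <- .simSampleProb(row, comp, map)
        if (noiseless) {
            depth <- config@depthMean
            cellv <- depth * prob
            if (round_counts) cellv <- round(cellv)
        } else {
            depth <- max(1, stats::rnbinom(1, mu = config@depthMean,
                                           size = config@depthDispersion))
            if (config@dmPrecision > 0) {
                a <- prob * config@dmPrecision
                g <- stats::rgamma(length(a), shape = a)
                g[a == 0] <- 0
                prob <- g / sum(g)
            }
            cellv <- stats::rmultinom(1, size = depth, prob = prob)[, 1L]
        }
        m[, i] <- cellv
        depths[i] <- depth
    }

    artifacts <- data.frame(feature_id = character(),
                            sample_id = character(),
                            kind = character(), stringsAsFactors = FALSE)
    if (!noiseless) {
        real <- enum$sample_type != "NTC"
        ## false negatives: zero cells, depth renormalized implicitly
        if (config@falseNegativeRate > 0) {
            mask <- matrix(stats::runif(n_feat * sum(real)) <
                               config@falseNegativeRate,
                           nrow = n_feat)
            mask <- mask & m[, real, drop = FALSE] > 0
            if (any(mask)) {
                idx <- which(mask, arr.ind = TRUE)
                sample_ids <- colnames(m)[real][idx[, 2L]]
                mm <- m[, real, drop = FALSE]
                mm[mask] <- 0
                m[, real] <- mm
                artifacts <- rbind(artifacts, data.frame(
                    feature_id = rownames(m)[idx[, 1L]],
                    sample_id = sample_ids,
                    kind = "false_negative", stringsAsFactors = FALSE))
            }
        }
        ## false positives: novel low-abundance features
        if (config@falsePositiveRate > 0) {
            n_fp <- stats::rpois(sum(real), config@falsePositiveRate)
            total_fp <- sum(n_fp)
            if (total_fp > 0) {
                fp_ids <- sprintf("ART%04d", seq_len(total_fp))
                fp <- matrix(0, nrow = total_fp, ncol = ncol(m),
                             dimnames = list(fp_ids, colnames(m)))
                k <- 0L
                fp_rows <- list()
                for (jj in which(real)) {
                    nf <- n_fp[match(jj, which(real))]
                    if (nf == 0) next
                    for (r in seq_len(nf)) {
                        k <- k + 1L
                        fp[k, jj] <- sample(5L, 1L)
                        fp_rows[[k]] <- data.frame(
                            feature_id = fp_ids[k],
                            sample_id = colnames(m)[jj],
                            kind = "false_positive",
                            stringsAsFactors = FALSE)
                    }
                }
                m <- rbind(m, fp)
                artifacts <- rbind(artifacts, do.call(rbind, fp_rows))
            }
        }
    }

    meta <- enum
    depth_final <- colSums(m)
    ## raw reads upstream of the pipeline: implied drop-out of 10-30%
    dropout <- stats::runif(nrow(enum), 0.1, 0.3)
    meta$raw_read_count <- ifelse(enum$sample_type == "NTC", 0L,
                                  as.integer(ceiling(depth_final /
                                                     (1 - dropout))))
    meta$theta <- NULL
    te <- TitrationExperiment(m, meta, design)
    truth <- list(classes = classes,
                  compositions = comps,
                  theta = theta_tab,
                  artifacts = artifacts,
                  depths = stats::setNames(depths, enum$sample_id),
                  gamma_pre = gp, gamma_post = gq)
    list(te = te, truth = truth)
}
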