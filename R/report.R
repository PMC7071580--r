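.writeTSV <- function(df, path) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
    invisible(path)
}

## Provenance header recorded in every summary JSON.
.runProvenance <- function(design, seed) {
    cfg <- list(subjects = subjects(design),
                titration_factors = titrationFactors(design),
                pcr_replicates = design@pcrReplicates,
                n_ntc = design@nNTC)
    list(schema_version = 1L,
         package_version = as.character(utils::packageVersion("titrassess")),
         seed = seed,
         config = cfg,
         config_hash = .strHash(paste(unlist(cfg), collapse = ",")))
}

#' Run the full assessment and write a report bundle
#'
#' Executes the complete framework on one or more count tables sharing a
#' design: feature catalog, qualitative assessment (sampling tests and
#' artifactual feature proportion), \eqn{\theta} inference, relative
#' abundance assessment and differential abundance assessment, writing
#' all result tables (TSV) and a machine-readable summary (JSON) into
#' \code{outdir}. With more than one pipeline the feature-level metrics
#' are additionally compared across pipelines (mixed-effects model +
#' one-sided Tukey HSD) and per-metric pipeline ranks are reported.
#' Re-running with the same inputs and seed reproduces identical outputs.
#'
#' @param tes a \linkS4class{TitrationExperiment} or a named list of them
#'   (one per pipeline).
#' @param outdir output directory (created if needed).
#' @param alpha flagging threshold of the qualitative assessment.
#' @param n_draws Monte Carlo draws of the Bayesian test.
#' @param theta_mode \code{"inferred"} or \code{"design"} for the
#'   relative-abundance expectations.
#' @param prior_count prior count of the log fold-change estimator.
#' @param seed integer seed for all stochastic stages.
#' @return invisibly, the summary list written to
#'   \code{outdir/summary.json}.
#' @export
runFullAssessment <- function(tes, outdir, alpha = 0.05, n_draws = 1e4,
                              theta_mode = "inferred", prior_count = 0.5,
                              seed = 1L) {
    if (is(tes, "TitrationExperiment"))
        tes <- list(pipeline = tes)
    if (is.null(names(tes)) || any(names(tes) == ""))
        stop("'tes' must be a named list of TitrationExperiment objects")
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    design <- titrationDesign(tes[[1L]])
    summary <- .runProvenance(design, seed)
    summary$pipelines <- list()
    relab_feats <- list()
    logfc_feats <- list()
    for (pid in names(tes)) {
        te <- tes[[pid]]
        pdir <- file.path(outdir, pid)
        dir.create(pdir, showWarnings = FALSE, recursive = TRUE)
        stage <- "catalog"
        res <- tryCatch({
            catalog <- buildCatalog(te)
            writeCatalog(catalog, file.path(pdir, "catalog.tsv"))

            stage <- "qualitative"
            qual <- assessQualitative(te, catalog, alpha = alpha,
                                      n_draws = n_draws, seed = seed)
            .writeTSV(qual, file.path(pdir, "qualitative_tests.tsv"))
            afp <- artifactualFeatureProportion(qual, alpha = alpha)
            .writeTSV(afp, file.path(pdir, "afp_summary.tsv"))

            stage <- "theta_inference"
            theta <- inferThetaAll(te, catalog)
            .writeTSV(theta, file.path(pdir, "theta_estimates.tsv"))

            stage <- "relabund"
            relab <- assessRelativeAbundance(te, catalog, theta = theta,
                                             theta_mode = theta_mode)
            .writeTSV(relab$records, file.path(pdir, "relabund_records.tsv"))
            .writeTSV(relab$features, file.path(pdir, "relabund_features.tsv"))

            stage <- "logfc"
            lfc <- assessLogFC(te, catalog, prior_count = prior_count)
            .writeTSV(lfc$records, file.path(pdir, "logfc_pairs.tsv"))
            .writeTSV(lfc$features, file.path(pdir, "logfc_features.tsv"))

            list(catalog = catalog, qual = qual, afp = afp, theta = theta,
                 relab = relab, lfc = lfc)
        }, error = function(e) {
            stop("assessment stage '", stage, "' failed for pipeline '",
                 pid, "': ", conditionMessage(e), call. = FALSE)
        })
        relab_feats[[pid]] <- res$relab$features
        logfc_feats[[pid]] <- res$lfc$features
        tab <- summarizeTable(te)
        afp_all <- res$afp[res$afp$subject == "all" &
                           res$afp$test_kind == "all", ]
        summary$pipelines[[pid]] <- list(
            n_features = tab$n_features,
            sparsity = tab$sparsity,
            total_abundance = tab$total_abundance,
            dropout_rate = tab$dropout_rate,
            individual_sparsity = stats::setNames(
                lapply(subjects(te), function(s) individualSparsity(te, s)),
                subjects(te)),
            afp = list(proportion = afp_all$proportion,
                       n_flagged = afp_all$n_flagged,
                       n_total = afp_all$n_total),
            relabund = list(
                n_features = nrow(res$relab$features),
                mean_bias = if (nrow(res$relab$features))
                    mean(res$relab$features$bias) else NA,
                median_bias = if (nrow(res$relab$features))
                    stats::median(res$relab$features$bias) else NA),
            logfc = list(
                n_features = nrow(res$lfc$features),
                mean_bias = mean(res$lfc$features$bias, na.rm = TRUE),
                excluded_subjects = res$lfc$excluded_subjects))
    }
    if (length(tes) > 1L) {
        comp <- list()
        rank_tab <- list()
        for (metric in c("relabund_bias", "relabund_variance",
                         "logfc_bias", "logfc_variance")) {
            src <- if (startsWith(metric, "relabund")) relab_feats else
                logfc_feats
            col <- if (endsWith(metric, "bias")) "bias" else
                if (startsWith(metric, "logfc")) "r_squared" else "variance"
            usable <- vapply(src, function(d) sum(is.finite(d[[col]])) >= 4L,
                             logical(1))
            if (sum(usable) < 2L) next
            cc <- tryCatch(
                comparePipelines(src[usable], metric = col),
                error = function(e) NULL)
            if (is.null(cc)) next
            .writeTSV(cc$pairwise,
                      file.path(outdir, paste0("compare_", metric, ".tsv")))
            comp[[metric]] <- list(
                anova_f = cc$fit$anova_f, anova_p = cc$fit$anova_p,
                means = as.list(cc$means),
                n_excluded_outliers = cc$n_excluded)
            ## rank 1 = best; for R^2 (logfc variance) larger is better
            mns <- unlist(cc$means)
            if (col == "r_squared") mns <- -mns
            rank_tab[[metric]] <- as.list(rank(mns, ties.method = "min"))
        }
        summary$comparison <- comp
        summary$ranks <- rank_tab
    }
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(summary)
}
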