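test_that("presence-pattern classification follows the precedence rules", {
    dep <- rep(1000, 4)
    # observed in all PRE replicates, never in POST, seen in titrations
    expect_identical(
        classifyFeature(c(5, 3, 8, 2), c(0, 0, 0, 0), c(3, 0, 1, 2),
                        dep, dep),
        "PRE_SPECIFIC")
    # only in titrations
    expect_identical(
        classifyFeature(rep(0, 4), rep(0, 4), c(0, 0, 0, 2), dep, dep),
        "TITRATION_SPECIFIC")
    # only in unmixed samples
    expect_identical(
        classifyFeature(c(1, 0, 0, 0), rep(0, 4), rep(0, 6), dep, dep),
        "UNMIXED_SPECIFIC")
    # everywhere
    expect_identical(
        classifyFeature(c(9, 9, 9, 9), c(8, 9, 9, 9), c(5, 5, 5), dep, dep),
        "SHARED_FULL")
    # all-zero profile
    expect_identical(
        classifyFeature(rep(0, 4), rep(0, 4), rep(0, 8), dep, dep),
        "OTHER")
    # present in all PRE but not all replicates of either side: OTHER
    expect_identical(
        classifyFeature(c(2, 0, 3, 1), c(0, 0, 0, 0), c(1, 1), dep, dep),
        "OTHER")
})

test_that("dominance uses the depth-normalized moderated log fold-change", {
    dep <- rep(1000, 4)
    pre <- c(100, 90, 110, 95)
    post <- c(1, 0, 0, 0)
    # pooled logFC with prior 0.5: log2((395.5/4001)/(1.5/4001)) ~ 8.04 > 5
    lfc <- estimateLogFC(sum(pre), 4000, sum(post), 4000, prior_count = 0.5)
    expect_gt(lfc, 5)
    expect_identical(
        classifyFeature(pre, post, c(40, 30), dep, dep), "PRE_DOMINANT")
    # mirrored POST dominance
    expect_identical(
        classifyFeature(post, pre, c(40, 30), dep, dep), "POST_DOMINANT")
    # below the threshold: shared
    expect_identical(
        classifyFeature(c(20, 25, 22, 21), c(10, 9, 11, 12), c(15, 14),
                        dep, dep),
        "SHARED_FULL")
})

test_that("catalog is a partition invariant to column order and scaling", {
    d <- smallDesign()
    sim <- simulateDataset(d, realisticConfig(seed = 5))
    te <- sim$te
    cat1 <- buildCatalog(te)
    # partition: per-subject type counts sum to the feature total
    cs <- catalogSummary(cat1)
    for (s in subjects(te)) {
        expect_identical(sum(cs$n[cs$subject == s]), nrow(te))
    }
    # unmixed- and titration-specific are mutually exclusive
    expect_identical(
        sum(cat1$feature_type == "UNMIXED_SPECIFIC" &
            cat1$feature_type == "TITRATION_SPECIFIC"), 0L)
    # column permutation leaves the catalog unchanged
    perm <- sample(ncol(te))
    te_p <- TitrationExperiment(
        counts(te)[, perm],
        data.frame(sample_id = colnames(te)[perm],
                   as.data.frame(SummarizedExperiment::colData(te))[perm, ],
                   row.names = NULL),
        titrationDesign(te))
    cat_p <- buildCatalog(te_p)
    key <- order(cat1$feature_id, cat1$subject)
    key_p <- order(cat_p$feature_id, cat_p$subject)
    expect_identical(as.character(cat1$feature_type[key]),
                     as.character(cat_p$feature_type[key_p]))
    # uniform scaling of a replicate's counts cannot change presence rules
    m2 <- counts(te)
    m2[, 3] <- m2[, 3] * 7
    te_s <- TitrationExperiment(
        m2, data.frame(sample_id = colnames(te),
                       as.data.frame(SummarizedExperiment::colData(te)),
                       row.names = NULL),
        titrationDesign(te))
    cat_s <- buildCatalog(te_s)
    specific <- c("PRE_SPECIFIC", "POST_SPECIFIC", "UNMIXED_SPECIFIC",
                  "TITRATION_SPECIFIC", "OTHER")
    sel <- cat1$feature_type[key] %in% specific
    expect_identical(as.character(cat1$feature_type[key][sel]),
                     as.character(cat_s$feature_type[key][sel]))
})

test_that("noiseless construction recovers every class label", {
    d <- smallDesign(factors = c(1, 2, 3, 4, 5))
    sim <- noiselessDataset(d, cleanConfig(depthMean = 1e4))
    cat1 <- buildCatalog(sim$te)
    truth <- sim$truth$classes
    for (s in subjects(sim$te)) {
        cs <- cat1[cat1$subject == s, ]
        m <- match(truth$feature_id, cs$feature_id)
        expect_identical(as.character(cs$feature_type[m]), truth$class)
    }
})

test_that("eligible feature sets implement the routing rules", {
    cat1 <- S4Vectors::DataFrame(
        feature_id = paste0("f", 1:6), subject = "S1",
        feature_type = c("SHARED_FULL", "PRE_DOMINANT",
                         "TITRATION_SPECIFIC", "PRE_SPECIFIC",
                         "POST_SPECIFIC", "OTHER"),
        n_pre_present = 4L, n_post_present = 4L, n_titration_present = 2L,
        q_pre = 0.1, q_post = 0.1)
    cat1 <- new("FeatureCatalog", cat1)
    expect_setequal(eligibleRelabundFeatures(cat1, "S1"),
                    c("f1", "f4", "f5"))
    expect_setequal(eligibleLogFCFeatures(cat1, "S1"), c("f2", "f4"))
    expect_identical(eligibleLogFCFeatures(cat1, "S2"), character(0))
    # brute-force filter agreement
    bf <- cat1$feature_id[cat1$feature_type %in%
                          c("SHARED_FULL", "PRE_SPECIFIC", "POST_SPECIFIC")]
    expect_setequal(eligibleRelabundFeatures(cat1, "S1"), as.character(bf))
})
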