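test_that("moderated log fold-change estimator follows its formula", {
    expect_equal(estimateLogFC(20, 1000, 10, 1000, prior_count = 0), 1)
    expect_equal(estimateLogFC(7, 500, 7, 500, prior_count = 2), 0)
    expect_equal(estimateLogFC(0, 1000, 10, 1000, prior_count = 0.5),
                 log2((0.5 / 1001) / (10.5 / 1001)))
    expect_error(estimateLogFC(0, 1000, 10, 1000, prior_count = 0),
                 "positive prior")
    expect_error(estimateLogFC(1, 0, 1, 10), "positive")
    # antisymmetry
    expect_equal(estimateLogFC(30, 2000, 12, 1500),
                 -estimateLogFC(12, 1500, 30, 2000))
})

test_that("mixture-level pairs enumerate k(k-1)/2 oriented pairs", {
    p36 <- titrationPairs(paperDesign())
    expect_identical(nrow(p36), 36L)           # 9 levels
    expect_true(all(p36$theta_l > p36$theta_m))
    expect_false(any(paste(p36$level_l) == paste(p36$level_m)))
    d2 <- TitrationDesign("S1", integer(0))
    expect_identical(nrow(titrationPairs(d2)), 1L)   # PRE vs POST only
    d0 <- TitrationDesign("S1", c(3, 5), includeUnmixed = FALSE)
    expect_identical(nrow(titrationPairs(d0)), 1L)
})

test_that("per-feature fits match the closed-form least squares", {
    f <- featureLogFCFit(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
    expect_equal(f$slope, 1)
    expect_equal(f$bias, 0)
    expect_equal(f$r_squared, 1)
    f2 <- featureLogFCFit(2 * c(1, 2, 3), c(1, 2, 3))
    expect_equal(f2$slope, 2)
    expect_equal(f2$bias, 1)
    expect_equal(f2$r_squared, 1)
    # noisy case against the normal-equations oracle
    set.seed(15)
    for (i in 1:10) {
        x <- rnorm(12)
        y <- 1.3 * x + rnorm(12, sd = 0.4)
        f <- featureLogFCFit(y, x)
        o <- olsOracle(x, y)
        expect_equal(f$slope, o$slope, tolerance = 1e-12)
        expect_equal(f$intercept, o$intercept, tolerance = 1e-12)
        expect_equal(f$r_squared, o$r_squared, tolerance = 1e-12)
    }
    # degenerate inputs are skipped with a flag
    expect_true(featureLogFCFit(c(1, 2), c(1, 2))$skipped)
    expect_true(featureLogFCFit(c(1, 2, 3), c(2, 2, 2))$skipped)
})

test_that("noiseless PRE-specific features give slope 1 and R^2 1", {
    d <- smallDesign(factors = c(1, 2, 3, 4, 5))
    sim <- noiselessDataset(d, cleanConfig(depthMean = 1e4))
    cat1 <- buildCatalog(sim$te)
    lfc <- assessLogFC(sim$te, cat1, prior_count = 0)
    expect_gt(nrow(lfc$features), 5)
    expect_true(all(lfc$features$bias < 1e-6))
    expect_true(all(lfc$features$r_squared > 1 - 1e-9))
})

test_that("PRE-specific expected logFC is shared across features", {
    d <- smallDesign(n_subjects = 1, factors = c(1, 2, 3))
    sim <- noiselessDataset(d, cleanConfig(depthMean = 1e4))
    cat1 <- buildCatalog(sim$te)
    lfc <- assessLogFC(sim$te, cat1)
    ps <- cat1$feature_id[cat1$feature_type == "PRE_SPECIFIC"]
    rec <- lfc$records[lfc$records$feature_id %in% as.character(ps), ]
    by_pair <- split(rec$expected_logfc,
                     paste(rec$level_l, rec$level_m))
    for (v in by_pair) {
        v <- v[is.finite(v)]
        if (length(v)) expect_lt(max(v) - min(v), 1e-12)
    }
    # pairs against unmixed POST have undefined expectation and are dropped
    post_pairs <- rec[rec$level_l == "POST", ]
    expect_true(all(is.na(post_pairs$expected_logfc)))
})

test_that("prior count has limited influence on the bias metric", {
    d <- smallDesign(n_subjects = 2, factors = c(1, 2, 3, 4))
    sim <- simulateDataset(d, cleanConfig(depthMean = 1e5, seed = 77))
    cat1 <- buildCatalog(sim$te)
    med_bias <- vapply(c(0.1, 0.5, 1, 2), function(pc) {
        lfc <- assessLogFC(sim$te, cat1, prior_count = pc)
        stats::median(lfc$features$bias, na.rm = TRUE)
    }, numeric(1))
    expect_lt(diff(range(med_bias)) / stats::median(med_bias), 0.2)
})

test_that("subjects without eligible features are reported, not errors", {
    d <- TitrationDesign("S1", c(1, 2, 3))
    cfg <- SimulationConfig(nShared = 20, nPreSpecific = 0,
                            nPostSpecific = 5, nPreDominant = 0,
                            nPostDominant = 0, minProportion = 2e-4,
                            sdlog = 1, depthMean = 1e4,
                            falsePositiveRate = 0, falseNegativeRate = 0,
                            seed = 9)
    sim <- noiselessDataset(d, cfg)
    cat1 <- buildCatalog(sim$te)
    lfc <- assessLogFC(sim$te, cat1)
    expect_identical(lfc$excluded_subjects, "S1")
    expect_identical(nrow(lfc$records), 0L)
})
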