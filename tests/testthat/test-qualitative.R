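test_that("sparsity equals the zero-cell fraction", {
    expect_equal(sparsity(matrix(c(0, 2, 1, 3), 2)), 0.25)
    expect_equal(sparsity(matrix(0, 3, 3)), 1)
    expect_error(sparsity(matrix(numeric(0), 0, 0)), "empty")
    # brute-force oracle on a random 50x50 matrix
    set.seed(9)
    m <- matrix(rpois(2500, 0.7), 50)
    n0 <- 0L
    for (i in 1:50) for (j in 1:50) if (m[i, j] == 0) n0 <- n0 + 1L
    expect_equal(sparsity(m), n0 / 2500)
})

test_that("pi_min is the mixture of the minimum unmixed proportions", {
    expect_equal(piMin(0.5, 1e-4, 2e-4), 1.5e-4)
    expect_equal(piMin(0, 1e-4, 0.9), 1e-4)
    expect_equal(piMin(2^-15, 1e-4, 1e-2),
                 2^-15 * 1e-2 + (1 - 2^-15) * 1e-4)
    expect_error(piMin(0.5, 0, 0), "undefined")
})

test_that("binomial absence test matches its closed form", {
    expect_equal(binomialAbsenceTest(0, 1000, 0.001), 0.999^1000,
                 tolerance = 1e-12)
    expect_equal(binomialAbsenceTest(0, 50, 0), 1)
    expect_equal(binomialAbsenceTest(0, 10, 0.5), 2^-10, tolerance = 1e-12)
    # closed form (1-q)^N on a 100-point grid at C_obs = 0
    set.seed(2)
    q <- runif(100, 0, 0.05)
    n <- sample(100:10000, 100, replace = TRUE)
    expect_equal(binomialAbsenceTest(rep(0, 100), n, q), (1 - q)^n,
                 tolerance = 1e-12)
    expect_error(binomialAbsenceTest(5, 3, 0.1), "lie in")
})

test_that("Bayesian test: equal-prior identity and quadrature agreement", {
    # C_obs = 0: tails are 1 under both hypotheses, p = prior null mass
    expect_equal(as.numeric(bayesTitrationTest(0, 1e4, 1e-4)), 0.5)
    expect_equal(as.numeric(
        bayesTitrationTest(0, 500, 0.01, prior_null_mass = 0.3)), 0.3)
    # agreement with numerical integration within 3 MC standard errors
    grid <- expand.grid(c_obs = c(1, 3, 10, 50),
                        n = c(1e3, 1e4),
                        pi_min = c(1e-4, 5e-3))
    for (i in seq_len(nrow(grid))) {
        g <- grid[i, ]
        p <- bayesTitrationTest(g$c_obs, g$n, g$pi_min, n_draws = 1e5,
                                seed = 100 + i)
        oracle <- bayesQuadratureOracle(g$c_obs, g$n, g$pi_min)
        tol <- max(3 * attr(p, "mc_se"), 1e-6)
        expect_lt(abs(as.numeric(p) - oracle), tol)
    }
    # strong signal: 50 counts at depth 1e4 against pi_min = 1e-4
    expect_lt(as.numeric(
        bayesTitrationTest(50, 1e4, 1e-4, seed = 1)), 0.05)
    expect_error(bayesTitrationTest(1, 100, 0), "inside")
    expect_error(bayesTitrationTest(200, 100, 1e-3), "exceed")
})

test_that("Bayesian test is monotone non-increasing in the observed count", {
    p <- vapply(0:20, function(co)
        as.numeric(bayesTitrationTest(co, 5000, 2e-3, n_draws = 2e4,
                                      seed = 77)),
        numeric(1))
    expect_true(all(diff(p) <= 1e-12))
})

test_that("rejections are stable across beta prior parameterizations", {
    # analogue of the framework's prior-robustness check
    set.seed(31)
    c_obs <- rpois(60, 4) + 1
    n <- sample(5000:20000, 60, replace = TRUE)
    pi_min <- 2e-4
    rej <- lapply(list(c(1, 1), c(2, 5), c(5, 2)), function(ab) {
        p <- vapply(seq_along(c_obs), function(i)
            as.numeric(bayesTitrationTest(c_obs[i], n[i], pi_min,
                                          alpha = ab[1], beta = ab[2],
                                          n_draws = 2e4, seed = 500 + i)),
            numeric(1))
        bhAdjust(p) < 0.05
    })
    change12 <- mean(rej[[1]] != rej[[2]])
    change13 <- mean(rej[[1]] != rej[[3]])
    expect_lt(change12, 0.10)
    expect_lt(change13, 0.10)
})

test_that("BH adjustment matches the brute-force step-up", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(bhAdjust(0.2), 0.2)
    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
    expect_error(bhAdjust(c(0.5, 1.2)), "lie in")
    set.seed(6)
    for (i in 1:25) {
        p <- runif(sample(1:40, 1))
        expect_equal(bhAdjust(p), bhOracle(p))
    }
})

test_that("artifactual feature proportion aggregates by replicate or feature", {
    tests <- data.frame(
        feature_id = c("a", "a", "b", "b", "c", "c", "d", "d", "e", "e"),
        subject = "S1",
        sample_id = paste0("t", 1:10),
        test_kind = "binomial",
        adj_p = c(0.2, 0.01, 0.5, 0.6, 0.04, 0.2, 0.9, 0.9, 0.03, 0.9))
    afp_r <- artifactualFeatureProportion(tests, unit = "replicate")
    all_r <- afp_r[afp_r$subject == "all" & afp_r$test_kind == "all", ]
    expect_equal(all_r$proportion, 0.3)
    expect_identical(all_r$n_total, 10L)
    # feature unit: any flagged replicate flags the feature
    afp_f <- artifactualFeatureProportion(tests, unit = "feature")
    all_f <- afp_f[afp_f$subject == "all" & afp_f$test_kind == "all", ]
    expect_equal(all_f$proportion, 3 / 5)
    # empty input: undefined proportion, not zero
    empty <- artifactualFeatureProportion(tests[0, ])
    expect_true(is.nan(empty$proportion))
    expect_identical(empty$n_total, 0L)
})

test_that("qualitative assessment runs the right test on the right features", {
    d <- smallDesign()
    sim <- simulateDataset(d, realisticConfig(seed = 21))
    cat1 <- buildCatalog(sim$te)
    q <- assessQualitative(sim$te, cat1, n_draws = 2000, seed = 4)
    expect_true(all(q$test_kind %in% c("binomial", "bayesian")))
    # binomial tests target unmixed-specific features only
    um <- unique(cat1$feature_id[cat1$feature_type == "UNMIXED_SPECIFIC"])
    expect_true(all(q$feature_id[q$test_kind == "binomial"] %in% um))
    ts <- unique(cat1$feature_id[cat1$feature_type == "TITRATION_SPECIFIC"])
    expect_true(all(q$feature_id[q$test_kind == "bayesian"] %in% ts))
    # Bayesian tests only fire on replicates with observed counts
    expect_true(all(q$c_obs[q$test_kind == "bayesian"] > 0))
    expect_true(all(q$p >= 0 & q$p <= 1))
    expect_true(all(q$adj_p >= q$p - 1e-12))
    # deterministic given the seed
    q2 <- assessQualitative(sim$te, cat1, n_draws = 2000, seed = 4)
    expect_identical(q, q2)
})
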