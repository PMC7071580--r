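test_that("titration factors map to the log2 dilution series", {
    expect_identical(thetaFromFactor(1), 0.5)
    expect_identical(thetaFromFactor(0), 1)
    expect_equal(thetaFromFactor(15), 1 / 32768)
    expect_equal(thetaFromFactor(c(1, 2, 5)), c(0.5, 0.25, 1 / 32))
    expect_error(thetaFromFactor(-1), "non-negative")
})

test_that("sample enumeration reproduces the reference design counts", {
    # 45 samples: 5 subjects x (7 titrations + 2 unmixed)
    d45 <- TitrationDesign(paste0("S", 1:5), c(1, 2, 3, 4, 5, 10, 15),
                           pcrReplicates = 1, nNTC = 0)
    e45 <- enumerateSamples(d45)
    expect_identical(nrow(e45), 45L)
    expect_identical(sum(e45$sample_type == "TITRATION"), 35L)
    # 192 PCR assays: 4 replicates + 12 NTC wells
    e192 <- enumerateSamples(paperDesign())
    expect_identical(nrow(e192), 192L)
    expect_identical(sum(e192$sample_type == "NTC"), 12L)
    # PRE + POST only
    d2 <- TitrationDesign("S1", integer(0), pcrReplicates = 1)
    expect_identical(nrow(enumerateSamples(d2)), 2L)
})

test_that("enumeration is deterministic with stable ordering", {
    d <- smallDesign(reps = 2, ntc = 1)
    e1 <- enumerateSamples(d)
    e2 <- enumerateSamples(d)
    expect_identical(e1, e2)
    expect_false(anyDuplicated(e1$sample_id) > 0)
    # within a subject theta is non-increasing
    for (s in subjects(d)) {
        th <- e1$theta[!is.na(e1$subject) & e1$subject == s]
        expect_true(all(diff(th) <= 0))
    }
    # count formula exact
    expect_identical(nrow(e1),
                     2L * (4L + 2L) * 2L + 1L)
})

test_that("mixture expectation follows the two-sample formula", {
    expect_equal(expectedProportion(0.2, 0.4, 0.5), 0.3)
    expect_equal(expectedProportion(0.2, 0.4, 0), 0.2)
    expect_equal(expectedProportion(0.1, 0.9, 2^-15), 0.1000244140625)
    expect_error(expectedProportion(-0.1, 0.5, 0.5), "must lie")
    expect_error(expectedProportion(0.1, 0.5, 1.5), "must lie")
    # bounded by the unmixed proportions
    set.seed(42)
    for (i in 1:50) {
        qp <- runif(1); qq <- runif(1); th <- runif(1)
        v <- expectedProportion(qp, qq, th)
        expect_gte(v, min(qp, qq))
        expect_lte(v, max(qp, qq))
    }
})

test_that("mixture expectation is affine and preserves normalization", {
    set.seed(7)
    for (rep in 1:10) {
        n <- sample(5:40, 1)
        q_pre <- rexp(n); q_pre <- q_pre / sum(q_pre)
        q_post <- rexp(n); q_post <- q_post / sum(q_post)
        th <- runif(1)
        expect_equal(sum(expectedProportion(q_pre, q_post, th)), 1,
                     tolerance = 1e-9)
    }
})

test_that("expected log fold-change matches direct evaluation", {
    expect_equal(expectedLogFC(0.2, 0.4, 0.5, 0), log2(0.3 / 0.2))
    expect_equal(expectedLogFC(0.37, 0.11, 0.25, 0.25), 0)
    expect_equal(expectedLogFC(0.3, 0.3, 0.9, 0.1), 0)
    expect_error(expectedLogFC(0, 0, 0.5, 0.25), "both mixture values zero")
})

test_that("PRE-specific expectation is the count-free special case", {
    expect_equal(expectedLogFCPreSpecific(0.5, 0.25), log2(0.5 / 0.75))
    expect_equal(expectedLogFCPreSpecific(0.3, 0.3), 0)
    expect_equal(expectedLogFCPreSpecific(0.5, 0), -1)
    expect_error(expectedLogFCPreSpecific(1, 0.5), "undefined")
    # agrees with the general formula at q_post = 0
    set.seed(11)
    for (i in 1:25) {
        th <- sort(runif(2, 0, 0.99))
        qp <- runif(1, 0.01, 1)
        expect_equal(expectedLogFC(qp, 0, th[2], th[1]),
                     expectedLogFCPreSpecific(th[2], th[1]),
                     tolerance = 1e-12)
    }
})

test_that("effective theta models unequal prokaryotic DNA proportions", {
    expect_equal(effectiveTheta(0.5, 0.5, 1.0), 2 / 3)
    expect_equal(effectiveTheta(c(0, 1), 0.3, 0.9), c(0, 1))
    th <- runif(20)
    expect_equal(effectiveTheta(th, 0.7, 0.7), th)
    expect_error(effectiveTheta(0.5, 0, 1), "must lie")
})

test_that("amplicon overlap arithmetic", {
    expect_identical(ampliconOverlap(300, 464), 136)
    expect_error(ampliconOverlap(0, 464), "positive")
})

test_that("design validity is enforced", {
    expect_error(TitrationDesign(character(0)), "non-empty")
    expect_error(TitrationDesign("S1", c(1, 1)), "unique")
    expect_error(TitrationDesign("S1", c(-1, 2)), "non-negative")
    expect_error(TitrationDesign("S1", 1:3, pcrReplicates = 0), "positive")
    d <- defaultDesign()
    expect_identical(titrationFactors(d), c(1L, 2L, 3L, 4L, 5L, 10L, 15L))
    expect_identical(length(subjects(d)), 5L)
})
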