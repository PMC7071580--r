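writeTSVFixture <- function(m, path = tempfile(fileext = ".tsv")) {
    writeCountTable(m, path)
    path
}

test_that("TSV count tables parse with depths and ids intact", {
    m <- matrix(c(0, 2, 1, 3), nrow = 2,
                dimnames = list(c("f1", "f2"), c("a", "b")))
    p <- writeTSVFixture(m)
    got <- readCountTable(p)
    expect_identical(got, m)
    expect_identical(unname(colSums(got)), c(2, 4))
})

test_that("TSV round-trip is the identity", {
    set.seed(3)
    m <- matrix(rpois(60, 4), nrow = 10,
                dimnames = list(sprintf("f%02d", 1:10),
                                sprintf("s%d", 1:6)))
    m[2, ] <- 0  # empty feature retained
    got <- readCountTable(writeTSVFixture(m))
    expect_identical(got, m)
    expect_identical(readCountTable(writeTSVFixture(m), drop_empty = TRUE),
                     m[rowSums(m) > 0, ])
})

test_that("BIOM-JSON v1.0 tables match their TSV equivalent", {
    set.seed(4)
    m <- matrix(rpois(24, 2), nrow = 6,
                dimnames = list(sprintf("f%d", 1:6), sprintf("s%d", 1:4)))
    b <- biomformat::make_biom(m)
    bp <- tempfile(fileext = ".biom")
    biomformat::write_biom(b, bp)
    got <- readCountTable(bp, format = "biom")
    expect_equal(got[rownames(m), colnames(m)], m)
})

test_that("malformed count tables are rejected with informative errors", {
    expect_error(readCountTable(tempfile()), "not found")
    p <- tempfile(); writeLines(character(0), p)
    expect_error(readCountTable(p), "empty|parse")
    # negative cell named by feature and sample
    p2 <- tempfile()
    writeLines(c("feature_id\ts1\ts2", "f1\t3\t-1", "f2\t0\t2"), p2)
    expect_error(readCountTable(p2), "f1.*s2")
    # non-integer cell
    p3 <- tempfile()
    writeLines(c("feature_id\ts1", "f1\t1.5"), p3)
    expect_error(readCountTable(p3), "non-integer")
    # duplicate feature ids
    p4 <- tempfile()
    writeLines(c("feature_id\ts1", "f1\t1", "f1\t2"), p4)
    expect_error(readCountTable(p4), "duplicate")
})

test_that("metadata reader enforces schema", {
    meta <- enumerateSamples(smallDesign())
    meta$theta <- NULL
    p <- tempfile(fileext = ".csv")
    writeSampleMetadata(meta, p)
    got <- readSampleMetadata(p)
    expect_identical(got$sample_id, meta$sample_id)
    expect_identical(got$titration_factor, meta$titration_factor)
    bad <- meta[, setdiff(colnames(meta), "subject")]
    p2 <- tempfile(); writeSampleMetadata(bad, p2)
    expect_error(readSampleMetadata(p2), "subject")
})

test_that("dataset validation joins table, metadata and design", {
    d <- smallDesign(reps = 2)
    sim <- noiselessDataset(d, cleanConfig(depthMean = 1e3), round_counts = TRUE)
    m <- counts(sim$te)
    cd <- as.data.frame(SummarizedExperiment::colData(sim$te))
    meta <- data.frame(sample_id = rownames(cd), cd, row.names = NULL)
    expect_true(validateDataset(m, meta, d)$ok)
    # extra column in table absent from metadata: hard error naming it
    m2 <- cbind(m, X = 0)
    expect_error(validateDataset(m2, meta, d), "X")
    # dropping a replicate: reported, not an error
    drop <- colnames(m)[1]
    rep <- validateDataset(m[, colnames(m) != drop], meta, d)
    expect_false(rep$ok)
    expect_identical(nrow(rep$missing_samples), 1L)
    expect_match(rep$messages, "missing sample", all = FALSE)
})

test_that("table summaries compute sparsity, abundance and drop-out", {
    d <- TitrationDesign("S1", integer(0), pcrReplicates = 1)
    m <- matrix(c(0, 2, 1, 3), nrow = 2,
                dimnames = list(c("f1", "f2"), c("s_pre", "s_post")))
    meta <- data.frame(sample_id = c("s_pre", "s_post"),
                       subject = "S1", sample_type = c("PRE", "POST"),
                       titration_factor = NA_integer_, pcr_replicate = 1L,
                       raw_read_count = c(4L, 8L))
    te <- TitrationExperiment(m, meta, d)
    sm <- summarizeTable(te)
    expect_identical(sm$n_features, 2L)
    expect_equal(sm$sparsity, 0.25)
    expect_equal(sm$total_abundance$median, 3)
    expect_equal(sm$dropout_rate$min, 0.5)   # depth 2 of 4 raw
    expect_equal(sm$dropout_rate$max, 0.5)   # depth 4 of 8 raw
    # raw reads below depth is a validation error
    meta$raw_read_count <- c(1L, 8L)
    te2 <- TitrationExperiment(m, meta, d)
    expect_error(summarizeTable(te2), "raw_read_count")
})

test_that("NTC samples are excluded from summaries", {
    d <- smallDesign(reps = 1, ntc = 2)
    sim <- simulateDataset(d, realisticConfig(depthMean = 1e3))
    sm <- summarizeTable(sim$te)
    expect_gt(sm$total_abundance$min, 0)  # NTC zero columns not counted
})

test_that("individual sparsity removes subject-absent features", {
    d <- TitrationDesign(c("S1", "S2"), integer(0), pcrReplicates = 1)
    m <- matrix(c(0, 2, 0, 0,   # S1: f2 only
                  5, 1, 4, 2),  # S2: all
                nrow = 4,
                dimnames = list(paste0("f", 1:4),
                                c("S1_PRE", "S2_PRE")))
    # pad with POST columns so the join is design-complete
    m <- cbind(m, S1_POST = c(0, 1, 0, 0), S2_POST = c(1, 1, 1, 1))
    meta <- data.frame(sample_id = colnames(m),
                       subject = c("S1", "S2", "S1", "S2"),
                       sample_type = c("PRE", "PRE", "POST", "POST"),
                       titration_factor = NA_integer_, pcr_replicate = 1L)
    te <- TitrationExperiment(m, meta, d)
    # S1 sub-table keeps only f2: cells (2, 1) -> sparsity 0
    expect_equal(individualSparsity(te, "S1"), 0)
    expect_error(individualSparsity(te, "S9"), "no samples")
})
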