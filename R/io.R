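#' Read a feature-by-sample count table
#'
#' Reads a wide TSV count table (first column feature ids, header row of
#' sample ids, tab-separated non-negative integer cells) or a BIOM-JSON
#' (v1.0) table. Zero rows and columns are retained: they carry sparsity
#' information. Cells must be non-negative integers; violations are parse
#' errors naming the offending row/column.
#'
#' @param path path to the file.
#' @param format \code{"tsv"} (default) or \code{"biom"} (BIOM-JSON v1.0;
#'   HDF5 BIOM is not supported).
#' @param drop_empty drop features with zero counts in every sample
#'   (default \code{FALSE}).
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
readCountTable <- function(path, format = c("tsv", "biom"),
                           drop_empty = FALSE) {
    format <- match.arg(format)
    if (!file.exists(path))
        stop("count table not found: ", path)
    if (format == "tsv") {
        df <- tryCatch(
            utils::read.delim(path, check.names = FALSE,
                              stringsAsFactors = FALSE),
            error = function(e) stop("cannot parse '", path, "': ",
                                     conditionMessage(e)))
        if (nrow(df) == 0L || ncol(df) < 2L)
            stop("count table '", path, "' is empty or has no sample columns")
        feat <- as.character(df[[1L]])
        m <- as.matrix(df[, -1L, drop = FALSE])
        storage.mode(m) <- "numeric"
        rownames(m) <- feat
    } else {
        b <- biomformat::read_biom(path)
        m <- as(biomformat::biom_data(b), "matrix")
    }
    .validateCountMatrix(m, path)
    if (drop_empty)
        m <- m[rowSums(m) > 0, , drop = FALSE]
    m
}

.validateCountMatrix <- function(m, path = "<matrix>") {
    if (anyDuplicated(rownames(m)))
        stop("duplicate feature ids in '", path, "': ",
             paste(unique(rownames(m)[duplicated(rownames(m))]),
                   collapse = ", "))
    if (anyDuplicated(colnames(m)))
        stop("duplicate sample ids in '", path, "'")
    bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
    if (nrow(bad)) {
        stop("non-integer or negative count in '", path, "' at feature '",
             rownames(m)[bad[1L, 1L]], "', sample '",
             colnames(m)[bad[1L, 2L]], "'")
    }
    invisible(m)
}

#' Write a count table as wide TSV
#'
#' Inverse of \code{\link{readCountTable}}; UTF-8, LF line endings.
#'
#' @param m count matrix (features x samples) or a
#'   \linkS4class{TitrationExperiment}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCountTable <- function(m, path) {
    if (is(m, "TitrationExperiment")) m <- counts(m)
    df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    con <- file(path, open = "wb")
    on.exit(close(con))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n", fileEncoding = "UTF-8")
    invisible(path)
}

#' Read sample metadata
#'
#' Reads a CSV with columns \code{sample_id}, \code{subject},
#' \code{sample_type}, \code{titration_factor}, \code{pcr_replicate} and
#' optionally \code{raw_read_count}.
#'
#' @param path path to the CSV file.
#' @return \code{data.frame} keyed by \code{sample_id}.
#' @export
readSampleMetadata <- function(path) {
    if (!file.exists(path))
        stop("sample metadata not found: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "subject", "sample_type", "titration_factor",
              "pcr_replicate")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("metadata misses column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(df$sample_id))
        stop("duplicate sample_id in metadata")
    if (!all(df$sample_type %in% SAMPLE_TYPES))
        stop("sample_type must be one of ",
             paste(SAMPLE_TYPES, collapse = "/"))
    df$titration_factor <- as.integer(df$titration_factor)
    df
}

#' Write sample metadata as CSV
#'
#' @param meta metadata \code{data.frame} (see
#'   \code{\link{readSampleMetadata}}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSampleMetadata <- function(meta, path) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    utils::write.csv(meta, con, row.names = FALSE, quote = FALSE, eol = "\n")
    invisible(path)
}

#' Validate a count table and metadata against a design
#'
#' Joins a count table and its sample metadata against the expected sample
#' enumeration of a \linkS4class{TitrationDesign}. Samples present in the
#' table but missing from the metadata are a hard error; design samples
#' missing from the table and metadata rows without counts are reported as
#' warnings in the returned report.
#'
#' @param m count matrix (features x samples).
#' @param meta metadata \code{data.frame} with a \code{sample_id} column.
#' @param design a \linkS4class{TitrationDesign}.
#' @return list with elements \code{ok} (logical), \code{missing_samples}
#'   (design sample ids absent from the table, by subject/factor/replicate),
#'   \code{extra_samples} (table samples not in the design enumeration) and
#'   \code{messages}.
#' @export
validateDataset <- function(m, meta, design) {
    unmapped <- setdiff(colnames(m), meta$sample_id)
    if (length(unmapped))
        stop("samples present in the count table but absent from metadata: ",
             paste(unmapped, collapse = ", "))
    meta_key <- paste(meta$subject, meta$sample_type, meta$titration_factor,
                      meta$pcr_replicate)
    enum <- enumerateSamples(design)
    enum_key <- paste(enum$subject, enum$sample_type, enum$titration_factor,
                      enum$pcr_replicate)
    have <- meta$sample_id %in% colnames(m)
    missing <- enum[!(enum_key %in% meta_key[have]), , drop = FALSE]
    extra <- meta$sample_id[have][!(meta_key[have] %in% enum_key)]
    msgs <- character()
    if (nrow(missing))
        msgs <- c(msgs, sprintf(
            "missing sample: subject=%s type=%s factor=%s replicate=%d",
            missing$subject, missing$sample_type,
            ifelse(is.na(missing$titration_factor), "NA",
                   missing$titration_factor),
            missing$pcr_replicate))
    if (length(extra))
        msgs <- c(msgs, paste("sample not in design enumeration:", extra))
    list(ok = length(msgs) == 0L,
         missing_samples = missing,
         extra_samples = extra,
         messages = msgs)
}

#' Count table summary statistics
#'
#' Table-level summary: total features, sparsity (proportion of zero
#' cells), per-sample total abundance (median and range) and, when raw read
#' counts are available in the metadata, the per-sample drop-out rate
#' \code{1 - depth / raw_read_count} (the fraction of raw reads not
#' represented in the count table). No-template-control samples are
#' excluded from all statistics.
#'
#' @param te a \linkS4class{TitrationExperiment}.
#' @return list with \code{n_features}, \code{sparsity},
#'   \code{total_abundance} (median/min/max), and \code{dropout_rate}
#'   (median/min/max, or \code{NULL} when raw read counts are absent).
#' @export
summarizeTable <- function(te) {
    stopifnot(is(te, "TitrationExperiment"))
    cd <- SummarizedExperiment::colData(te)
    keep <- cd$sample_type != "NTC"
    m <- counts(te)[, keep, drop = FALSE]
    depth <- colSums(m)
    out <- list(
        n_features = nrow(m),
        sparsity = sparsity(m),
        total_abundance = list(median = stats::median(depth),
                               min = min(depth), max = max(depth)))
    raw <- cd$raw_read_count[keep]
    if (!is.null(raw) && !all(is.na(raw))) {
        if (any(raw < depth, na.rm = TRUE))
            stop("raw_read_count smaller than count table depth for sample(s): ",
                 paste(colnames(m)[which(raw < depth)], collapse = ", "))
        dr <- 1 - depth / raw
        out$dropout_rate <- list(median = stats::median(dr, na.rm = TRUE),
                                 min = min(dr, na.rm = TRUE),
                                 max = max(dr, na.rm = TRUE))
    } else {
        out$dropout_rate <- NULL
    }
    out
}

#' Sparsity restricted to one subject
#'
#' Sparsity of the sub-table of a subject's samples after removing features
#' never observed in any of that subject's samples. Because community
#' composition differs between subjects, individual-level sparsity is the
#' more interpretable quantity; it is bounded above by overall sparsity
#' when subjects have disjoint feature support.
#'
#' @param te a \linkS4class{TitrationExperiment}.
#' @param subject subject identifier.
#' @param include_ntc include NTC samples (default \code{FALSE}).
#' @return proportion of zero cells in the subject sub-table.
#' @export
individualSparsity <- function(te, subject, include_ntc = FALSE) {
    cd <- SummarizedExperiment::colData(te)
    keep <- !is.na(cd$subject) & cd$subject == subject
    if (!include_ntc) keep <- keep & cd$sample_type != "NTC"
    if (!any(keep))
        stop("no samples for subject '", subject, "'")
    m <- counts(te)[, keep, drop = FALSE]
    m <- m[rowSums(m) > 0, , drop = FALSE]
    if (nrow(m) == 0L) return(NA_real_)
    sparsity(m)
}
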