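#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a CtExperiment
#'
#' Bundle a Ct matrix (genes x samples), a sample sheet and optional
#' per-gene amplification efficiencies into a validated
#' \linkS4class{CtExperiment}.
#'
#' @param ct Numeric matrix of threshold-cycle values, genes in rows
#'   (rownames = gene ids), samples in columns (colnames = sample ids).
#'   Non-detects are `NA`.
#' @param sampleData `data.frame` or `DataFrame` with one row per sample
#'   (matched to `colnames(ct)` by its `sample_id` column or rownames) and
#'   columns `tissue` (leaf/stem/root/other), `subset`
#'   (developmental/cold/drought/custom), `group` (label within the
#'   subset, e.g. `ck`, `4h`) and `replicate` (positive integer).
#' @param efficiencies Optional named numeric vector or two-column
#'   `data.frame` (`gene`, `efficiency_percent`) of per-gene amplification
#'   efficiencies in percent. Genes without a value default to 100
#'   (perfect doubling); this defaulting is messaged. Values outside
#'   `effWindow` trigger a warning but are kept.
#' @param detectionCeiling Ct ceiling in cycles; values above it are set
#'   to `NA` when `maskAboveCeiling = TRUE`. Default 40.
#' @param maskAboveCeiling Mask Ct above the ceiling as missing?
#'   Default `TRUE`.
#' @param effWindow Length-2 numeric, the efficiency validity window in
#'   percent. Default `c(90, 110)`.
#' @return A [CtExperiment-class] object.
#' @examples
#' ct <- matrix(c(20.1, 21.0, 19.8, 20.5), 2, 2,
#'              dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' sheet <- data.frame(sample_id = c("s1", "s2"), tissue = "leaf",
#'                     subset = "cold", group = c("ck", "4h"),
#'                     replicate = 1L)
#' CtExperiment(ct, sheet)
#' @export
CtExperiment <- function(ct, sampleData, efficiencies = NULL,
                         detectionCeiling = 40, maskAboveCeiling = TRUE,
                         effWindow = c(90, 110)) {
    ct <- .asMatrixCheck(ct, "ct")
    if (anyDuplicated(rownames(ct)))
        stop("duplicated gene id(s): ",
             paste(unique(rownames(ct)[duplicated(rownames(ct))]),
                   collapse = ", "), call. = FALSE)
    if (anyDuplicated(colnames(ct)))
        stop("duplicated sample id(s): ",
             paste(unique(colnames(ct)[duplicated(colnames(ct))]),
                   collapse = ", "), call. = FALSE)
    sampleData <- as.data.frame(sampleData)
    if ("sample_id" %in% colnames(sampleData))
        rownames(sampleData) <- sampleData$sample_id
    miss <- setdiff(colnames(ct), rownames(sampleData))
    if (length(miss))
        stop("sample sheet lacks sample(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
    sampleData <- sampleData[colnames(ct), , drop = FALSE]
    for (col in c("tissue", "subset", "group"))
        sampleData[[col]] <- as.character(sampleData[[col]])
    if (maskAboveCeiling && any(ct > detectionCeiling, na.rm = TRUE))
        ct[!is.na(ct) & ct > detectionCeiling] <- NA_real_

    eff <- rep(100, nrow(ct))
    names(eff) <- rownames(ct)
    if (!is.null(efficiencies)) {
        if (is.data.frame(efficiencies))
            efficiencies <- setNames(efficiencies$efficiency_percent,
                                     efficiencies$gene)
        known <- intersect(names(efficiencies), rownames(ct))
        eff[known] <- efficiencies[known]
        defaulted <- setdiff(rownames(ct), names(efficiencies))
        if (length(defaulted))
            message("efficiency defaulted to 100% for: ",
                    paste(defaulted, collapse = ", "))
        out <- known[eff[known] < effWindow[1] | eff[known] > effWindow[2]]
        if (length(out))
            warning("efficiency outside [", effWindow[1], ", ",
                    effWindow[2], "]% for: ",
                    paste(out, collapse = ", "), call. = FALSE)
    }
    se <- SummarizedExperiment(
        assays = list(ct = ct),
        rowData = DataFrame(efficiency_percent = unname(eff),
                            row.names = rownames(ct)),
        colData = DataFrame(sampleData))
    new("CtExperiment", se)
}

#' @describeIn CtExperiment Ct value matrix (genes x samples).
#' @param x A `CtExperiment`.
#' @export
ctValues <- function(x) {
    stopifnot(is(x, "CtExperiment"))
    assay(x, "ct")
}

#' @describeIn CtExperiment Per-gene amplification efficiency in percent.
#' @export
efficiencyPercent <- function(x) {
    stopifnot(is(x, "CtExperiment"))
    setNames(rowData(x)$efficiency_percent, rownames(x))
}

#' @describeIn CtExperiment Per-gene fold amplification per cycle,
#'   `1 + efficiency_percent / 100` (2 at 100%).
#' @export
eFold <- function(x) 1 + efficiencyPercent(x) / 100

#' @describeIn CtExperiment Sample sheet as a `data.frame`.
#' @export
sampleInfo <- function(x) {
    stopifnot(is(x, "CtExperiment"))
    as.data.frame(colData(x))
}

#' Restrict a CtExperiment to an analysis subset
#'
#' The study design partitions samples into condition subsets
#' (developmental / cold / drought); `"total"` denotes their union, i.e.
#' all samples. Returns the experiment restricted to the requested
#' subset's samples.
#'
#' @param x A [CtExperiment-class].
#' @param subset Subset label, one of the labels present in
#'   `sampleInfo(x)$subset` or `"total"`.
#' @param genes Optional character vector restricting the genes as well.
#' @return A `CtExperiment` containing only the selected samples (and
#'   genes).
#' @export
subsetSamples <- function(x, subset = "total", genes = NULL) {
    stopifnot(is(x, "CtExperiment"))
    keep <- if (identical(subset, "total")) rep(TRUE, ncol(x))
            else colData(x)$subset == subset
    if (!any(keep))
        stop("no samples in subset '", subset, "'", call. = FALSE)
    out <- x[, keep]
    if (!is.null(genes)) {
        .assertGenes(out, genes)
        out <- out[genes, ]
    }
    out
}

#' Analysis groups of a subset
#'
#' Group labels used for model-based scoring: within a condition subset
#' the groups are its time points / levels; for `"total"` the condition
#' subsets themselves act as groups (developmental vs cold vs drought),
#' since the union has no single within-subset grouping.
#'
#' @param x A [CtExperiment-class] already restricted (or not) to a
#'   subset.
#' @param subset Subset label as in [subsetSamples()].
#' @return Named character vector: group label per sample of the subset.
#' @export
analysisGroups <- function(x, subset = "total") {
    sx <- subsetSamples(x, subset)
    cd <- colData(sx)
    g <- if (identical(subset, "total")) as.character(cd$subset)
         else as.character(cd$group)
    setNames(g, colnames(sx))
}

setMethod("show", "CtExperiment", function(object) {
    cat("CtExperiment with", nrow(object), "genes x", ncol(object),
        "samples\n")
    cat("  subsets:",
        paste(sort(unique(colData(object)$subset)), collapse = ", "), "\n")
    cat("  missing Ct:", sum(is.na(assay(object, "ct"))), "\n")
    invisible(callNextMethod())
})
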