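#' @include AllClasses.R
NULL

# Shared CSV-matrix reader: header `gene,<sample>...`, strict numeric
# parsing with an optional missing-value token (ABI instruments export
# non-detects as "Undetermined").
.readMatrixCsv <- function(path, what, naToken = NULL) {
    raw <- read.csv(path, check.names = FALSE, colClasses = "character")
    if (ncol(raw) < 2L)
        stop(what, " CSV needs a gene column plus >=1 sample column",
             call. = FALSE)
    genes <- raw[[1L]]
    samples <- colnames(raw)[-1L]
    if (anyDuplicated(genes))
        stop("duplicated gene id(s) in ", what, ": ",
             paste(unique(genes[duplicated(genes)]), collapse = ", "),
             call. = FALSE)
    if (anyDuplicated(samples))
        stop("duplicated sample id(s) in ", what, ": ",
             paste(unique(samples[duplicated(samples)]), collapse = ", "),
             call. = FALSE)
    m <- matrix(NA_real_, length(genes), length(samples),
                dimnames = list(genes, samples))
    for (j in seq_along(samples)) {
        cells <- trimws(raw[[j + 1L]])
        isNA <- cells == "" | is.na(cells)
        if (!is.null(naToken)) isNA <- isNA | cells == naToken
        vals <- suppressWarnings(as.numeric(cells))
        bad <- which(!isNA & is.na(vals))
        if (length(bad))
            stop("non-numeric cell in ", what, " at gene '",
                 genes[bad[1L]], "', sample '", samples[j], "': \"",
                 cells[bad[1L]], "\"", call. = FALSE)
        vals[isNA] <- NA_real_
        m[, j] <- vals
    }
    m
}

#' Read a Ct matrix from CSV
#'
#' Expected layout: header row `gene,<sample_id>,...`; one row per gene;
#' cells numeric, empty, or equal to the missing-value token (default
#' `"Undetermined"`, the ABI instrument convention).
#'
#' @param path CSV file path.
#' @param naToken Cell content treated as a non-detect. Default
#'   `"Undetermined"`.
#' @return Numeric matrix of Ct values (genes x samples) with `NA` for
#'   missing entries; ordering as in the file.
#' @seealso [CtExperiment()] to combine with a sample sheet.
#' @export
readCtMatrix <- function(path, naToken = "Undetermined") {
    .readMatrixCsv(path, "Ct matrix", naToken = naToken)
}

#' Read an expression (TPM) matrix from CSV
#'
#' Same layout as [readCtMatrix()]; all values must be non-negative.
#'
#' @param path CSV file path.
#' @return Numeric matrix of TPM values (genes x samples).
#' @export
readExpressionMatrix <- function(path) {
    m <- .readMatrixCsv(path, "expression matrix")
    if (any(m < 0, na.rm = TRUE))
        stop("expression values must be non-negative", call. = FALSE)
    m
}

#' Read a sample sheet from CSV
#'
#' Required columns: `sample_id`, `tissue`, `subset`, `group`,
#' `replicate`. Labels are validated against the known tissue and subset
#' vocabularies.
#'
#' @param path CSV file path.
#' @return A `data.frame` with the five required columns, rownames =
#'   sample ids.
#' @export
readSampleSheet <- function(path) {
    d <- read.csv(path, check.names = FALSE, colClasses = "character")
    needed <- c("sample_id", "tissue", "subset", "group", "replicate")
    miss <- setdiff(needed, colnames(d))
    if (length(miss))
        stop("sample sheet lacks column(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
    if (anyDuplicated(d$sample_id))
        stop("duplicated sample_id(s): ",
             paste(unique(d$sample_id[duplicated(d$sample_id)]),
                   collapse = ", "), call. = FALSE)
    badT <- setdiff(unique(d$tissue), .VALID_TISSUES)
    if (length(badT))
        stop("unknown tissue label(s): ", paste(badT, collapse = ", "),
             call. = FALSE)
    badS <- setdiff(unique(d$subset), .VALID_SUBSETS)
    if (length(badS))
        stop("unknown subset label(s): ", paste(badS, collapse = ", "),
             call. = FALSE)
    d$replicate <- as.integer(d$replicate)
    if (any(is.na(d$replicate)) || any(d$replicate < 1L))
        stop("replicate must be a positive integer", call. = FALSE)
    rownames(d) <- d$sample_id
    d
}

#' Read per-gene amplification efficiencies from CSV
#'
#' Required columns: `gene`, `efficiency_percent`. Values outside the
#' validity window (default 90--110%) are kept with a warning, matching
#' the convention that standard-curve efficiencies should fall between
#' 90% and 110%.
#'
#' @param path CSV file path.
#' @param effWindow Validity window in percent, default `c(90, 110)`.
#' @return Named numeric vector of efficiencies in percent.
#' @export
readEfficiencies <- function(path, effWindow = c(90, 110)) {
    d <- read.csv(path, check.names = FALSE)
    miss <- setdiff(c("gene", "efficiency_percent"), colnames(d))
    if (length(miss))
        stop("efficiency table lacks column(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
    if (anyDuplicated(d$gene))
        stop("duplicated gene id(s) in efficiency table", call. = FALSE)
    e <- setNames(as.numeric(d$efficiency_percent), d$gene)
    if (any(!is.finite(e) | e <= 0))
        stop("efficiencies must be positive numbers", call. = FALSE)
    out <- names(e)[e < effWindow[1] | e > effWindow[2]]
    if (length(out))
        warning("efficiency outside [", effWindow[1], ", ", effWindow[2],
                "]% for: ", paste(out, collapse = ", "), call. = FALSE)
    e
}

#' Write matrices and tables back to CSV
#'
#' Writers mirroring the readers; full precision (up to 15 significant
#' digits) so a write/read round trip reproduces the values.
#'
#' @param m Matrix (genes x samples) for the matrix writers.
#' @param path Output CSV path.
#' @param naToken Token written for missing Ct values.
#' @return The path, invisibly.
#' @export
writeCtMatrix <- function(m, path, naToken = "Undetermined") {
    d <- data.frame(gene = rownames(m),
                    format(m, digits = 15, trim = TRUE, scientific = FALSE),
                    check.names = FALSE)
    for (j in seq_len(ncol(m)) + 1L) d[[j]][is.na(m[, j - 1L])] <- naToken
    write.csv(d, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeCtMatrix
#' @export
writeExpressionMatrix <- function(m, path) {
    d <- data.frame(gene = rownames(m),
                    format(m, digits = 15, trim = TRUE, scientific = FALSE),
                    check.names = FALSE)
    write.csv(d, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeCtMatrix
#' @param sheet Sample sheet `data.frame` (see [readSampleSheet()]).
#' @export
writeSampleSheet <- function(sheet, path) {
    cols <- c("sample_id", "tissue", "subset", "group", "replicate")
    write.csv(sheet[, cols], path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeCtMatrix
#' @param eff Named numeric vector of efficiencies in percent.
#' @export
writeEfficiencies <- function(eff, path) {
    write.csv(data.frame(gene = names(eff),
                         efficiency_percent = unname(eff)),
              path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
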