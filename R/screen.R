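#' @include AllClasses.R
NULL

#' Candidate-gene expression statistics from a TPM matrix
#'
#' Computes, per gene: the mean TPM over all samples (MV), the sample SD
#' (n - 1 denominator), the coefficient of variation CV = SD / MV, the
#' mean TPM of each tissue group, and the between-tissue log2 fold change
#' `log2FC = log2(max group mean / min group mean)`. Genes with MV = 0
#' have an undefined CV and are flagged `low_expression` outright.
#'
#' @param tpm Numeric matrix of TPM values (genes x samples).
#' @param tissue Character vector (or factor), tissue label per sample
#'   (parallel to `colnames(tpm)`), e.g. from a sample sheet.
#' @return `DataFrame` with columns `mv`, `sd`, `cv`, one `mean_<tissue>`
#'   column per tissue, and `log2fc`.
#' @seealso [screenCandidates()] to apply the thresholds.
#' @export
screenStats <- function(tpm, tissue) {
    tpm <- .asMatrixCheck(tpm, "tpm")
    if (any(tpm < 0, na.rm = TRUE))
        stop("TPM values must be non-negative", call. = FALSE)
    tissue <- as.character(tissue)
    if (length(tissue) != ncol(tpm))
        stop("tissue must have one label per sample", call. = FALSE)
    if (ncol(tpm) < 2L)
        stop("need at least two samples", call. = FALSE)
    mv <- rowMeans(tpm)
    sdv <- apply(tpm, 1L, sd)
    cv <- ifelse(mv > 0, sdv / mv, NA_real_)
    tl <- sort(unique(tissue))
    gm <- vapply(tl, function(t)
        rowMeans(tpm[, tissue == t, drop = FALSE]), numeric(nrow(tpm)))
    gm <- matrix(gm, nrow = nrow(tpm),
                 dimnames = list(rownames(tpm), tl))
    hi <- apply(gm, 1L, max); lo <- apply(gm, 1L, min)
    log2fc <- ifelse(hi == 0, 0,
                     ifelse(lo == 0, Inf, log2(hi / lo)))
    out <- DataFrame(mv = mv, sd = sdv, cv = cv, row.names = rownames(tpm))
    for (t in tl) out[[paste0("mean_", t)]] <- gm[, t]
    out$log2fc <- log2fc
    out
}

#' Screen candidate reference genes by expression thresholds
#'
#' Two-stage screen on [screenStats()] output, following the usual
#' RNA-seq pre-selection of RT-qPCR reference candidates:
#' stage 1 keeps genes expressed at `minTpm` or more (mean TPM), with
#' between-tissue `log2FC <= maxLog2fcStage1` and `CV <= cvStage1`,
#' ranked by ascending CV and truncated to `topK`; stage 2 tightens to
#' `CV < cvStage2` and `log2FC < maxLog2fcStage2` (strict comparisons).
#' Defaults are the conventional cutoffs: 5 TPM, log2FC 2 then 0.2, CV
#' 0.5 then 0.3.
#'
#' @param stats `DataFrame` from [screenStats()], or a TPM matrix (then
#'   `tissue` is required and stats are computed first).
#' @param tissue Tissue labels, only used when `stats` is a matrix.
#' @param minTpm Minimum expression in TPM. Default 5.
#' @param minTpmRule `"mean"` (default) applies `minTpm` to the mean TPM;
#'   `"all"` requires every sample to reach it (needs the TPM matrix).
#' @param maxLog2fcStage1,cvStage1 Stage-1 thresholds (inclusive).
#'   Defaults 2 and 0.5.
#' @param maxLog2fcStage2,cvStage2 Stage-2 thresholds (strict). Defaults
#'   0.2 and 0.3.
#' @param topK Stage-1 list truncation. Default 50.
#' @return A [ScreenReport-class] with flags added to the stats table
#'   (`low_expression`, `high_fold_change`, `stage1`, `stage2`).
#' @export
screenCandidates <- function(stats, tissue = NULL, minTpm = 5,
                             minTpmRule = c("mean", "all"),
                             maxLog2fcStage1 = 2, cvStage1 = 0.5,
                             maxLog2fcStage2 = 0.2, cvStage2 = 0.3,
                             topK = 50L) {
    minTpmRule <- match.arg(minTpmRule)
    tpm <- NULL
    if (is.matrix(stats)) {
        tpm <- stats
        if (is.null(tissue))
            stop("tissue labels required when passing a TPM matrix",
                 call. = FALSE)
        stats <- screenStats(tpm, tissue)
    }
    exprOk <- if (minTpmRule == "mean") stats$mv >= minTpm
              else {
                  if (is.null(tpm))
                      stop("minTpmRule = 'all' needs the TPM matrix",
                           call. = FALSE)
                  apply(tpm >= minTpm, 1L, all)
              }
    stats$low_expression <- !exprOk | stats$mv == 0
    stats$high_fold_change <- stats$log2fc > maxLog2fcStage1
    cvOk1 <- !is.na(stats$cv) & stats$cv <= cvStage1
    s1 <- rownames(stats)[!stats$low_expression &
                          !stats$high_fold_change & cvOk1]
    s1 <- s1[order(stats[s1, "cv"], s1)]
    if (length(s1) > topK) s1 <- s1[seq_len(topK)]
    s2 <- s1[stats[s1, "cv"] < cvStage2 &
             stats[s1, "log2fc"] < maxLog2fcStage2]
    if (!length(s2))
        warning("no gene survives the strict stage-2 screen",
                call. = FALSE)
    stats$stage1 <- rownames(stats) %in% s1
    stats$stage2 <- rownames(stats) %in% s2
    new("ScreenReport", stats = stats, stage1 = s1, stage2 = s2,
        thresholds = list(minTpm = minTpm, minTpmRule = minTpmRule,
                          maxLog2fcStage1 = maxLog2fcStage1,
                          cvStage1 = cvStage1,
                          maxLog2fcStage2 = maxLog2fcStage2,
                          cvStage2 = cvStage2, topK = topK))
}
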