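#' @include CtExperiment.R results-methods.R
NULL

#' BestKeeper index
#'
#' The per-sample geometric mean of raw Ct over the included genes. A
#' sample missing any included gene's Ct is dropped from the index (and
#' logged).
#'
#' @param x A [CtExperiment-class] or numeric Ct matrix.
#' @param subset Sample-subset label.
#' @param genes Genes to build the index from (>= 2 required).
#' @return Named numeric vector, one index value per retained sample.
#' @examples
#' bestKeeperIndex(rbind(g1 = 20, g2 = 24))  # sqrt(480)
#' @export
bestKeeperIndex <- function(x, subset = "total", genes = NULL) {
    ct <- .ctOf(x, subset, genes)
    if (is.null(colnames(ct)))
        colnames(ct) <- paste0("s", seq_len(ncol(ct)))
    if (nrow(ct) < 2L)
        stop("BestKeeper index needs at least 2 included genes",
             call. = FALSE)
    ok <- colSums(is.na(ct)) == 0L
    if (!all(ok))
        message(sum(!ok), " sample(s) with missing Ct dropped from the ",
                "BestKeeper index")
    apply(ct[, ok, drop = FALSE], 2L, geoMean)
}

#' BestKeeper descriptive stability analysis
#'
#' Per-gene descriptive statistics on raw Ct (arithmetic and geometric
#' mean, min, max, sample SD, CV% = SD / mean x 100), the Pearson
#' correlation r of each gene's Ct with the BestKeeper index, and a
#' composite ranking: genes are ranked by ascending SD, ascending CV%
#' and descending r, and the geometric mean of the three rank positions
#' gives the final order. Genes whose Ct SD exceeds 1 cycle are flagged
#' and excluded from the index construction (the conventional SD > 1
#' rejection) but remain in the report and ranking so the composite is
#' comparable across the whole panel.
#'
#' A zero-variance gene has an undefined r; being perfectly stable it is
#' assigned the best r rank (ties averaged among such genes).
#'
#' @inheritParams bestKeeperIndex
#' @param sdCutoff Exclusion threshold on the Ct SD, strict (`> 1` is
#'   excluded). Default 1.
#' @param indexOnQualified Build the index from SD-qualified genes only
#'   (default `TRUE`); `FALSE` uses all genes.
#' @param dispersion `"sd"` (default) uses the n - 1 sample standard
#'   deviation; `"mad"` uses the mean absolute deviation from the
#'   arithmetic mean, the dispersion some BestKeeper descriptions use.
#' @return A [BestKeeperResult-class] (`method = "bestkeeper"`; the
#'   score is the rank composite).
#' @export
bestKeeper <- function(x, subset = "total", genes = NULL, sdCutoff = 1,
                       indexOnQualified = TRUE,
                       dispersion = c("sd", "mad")) {
    dispersion <- match.arg(dispersion)
    ct <- .ctOf(x, subset, genes)
    if (nrow(ct) < 3L || ncol(ct) < 3L)
        stop("BestKeeper needs at least 3 genes and 3 samples",
             call. = FALSE)
    disp <- function(v) {
        v <- v[!is.na(v)]
        if (dispersion == "sd") sd(v) else mean(abs(v - mean(v)))
    }
    meanCt <- rowMeans(ct, na.rm = TRUE)
    geoCt <- apply(ct, 1L, geoMean, na.rm = TRUE)
    sdCt <- apply(ct, 1L, disp)
    cvPct <- sdCt / meanCt * 100
    excluded <- sdCt > sdCutoff
    idxGenes <- if (indexOnQualified) rownames(ct)[!excluded]
                else rownames(ct)
    if (length(idxGenes) >= 2L) {
        idx <- bestKeeperIndex(ct[idxGenes, , drop = FALSE])
        r <- vapply(rownames(ct), function(g) {
            v <- ct[g, names(idx)]
            ok <- !is.na(v)
            if (sum(ok) < 3L || sd(v[ok]) == 0) NA_real_
            else cor(v[ok], idx[ok])
        }, numeric(1L))
    } else {
        warning("fewer than 2 SD-qualified genes; index and r skipped",
                call. = FALSE)
        idx <- setNames(numeric(0), character(0))
        r <- setNames(rep(NA_real_, nrow(ct)), rownames(ct))
    }
    rankSd <- rankAsc(sdCt)
    rankCv <- rankAsc(cvPct)
    # descending r; undefined r (zero-variance = perfectly stable) best
    rKey <- ifelse(is.na(r), Inf, r)
    rankR <- rankDesc(rKey)
    composite <- (rankSd * rankCv * rankR)^(1 / 3)
    finalRank <- rankAsc(composite)
    tab <- DataFrame(gene = rownames(ct), mean_ct = meanCt,
                     geo_mean_ct = geoCt, min = apply(ct, 1L, min,
                                                      na.rm = TRUE),
                     max = apply(ct, 1L, max, na.rm = TRUE),
                     sd = sdCt, cv_percent = cvPct, r = r,
                     excluded = excluded, rank_sd = rankSd,
                     rank_cv = rankCv, rank_r = rankR,
                     composite = composite, rank = finalRank,
                     row.names = rownames(ct))
    new("BestKeeperResult",
        method = "bestkeeper",
        subset = if (is(x, "CtExperiment")) subset else "custom",
        scores = setNames(composite, rownames(ct)),
        ranks = setNames(finalRank, rownames(ct)),
        details = tab, bkTable = tab,
        index = idx, indexGenes = idxGenes)
}
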