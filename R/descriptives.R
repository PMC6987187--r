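#' @include CtExperiment.R
NULL

#' Per-gene descriptive statistics of Ct values
#'
#' Boxplot-style summaries of each gene's Ct distribution over a sample
#' subset: median, quartiles (linear-interpolation rule, `type = 7`),
#' interquartile range, min/max, and Tukey-style outliers (beyond
#' 1.5 x IQR from the box) and extremes (beyond 3 x IQR). With a zero
#' IQR any point off the common value is both an outlier and an extreme.
#'
#' @param x A [CtExperiment-class] or a numeric Ct matrix.
#' @param subset Subset label (see [subsetSamples()]); ignored when `x`
#'   is a plain matrix.
#' @param minN Minimum number of non-missing Ct values per gene for
#'   quartiles to be reported; genes below it get `NA` quartiles and a
#'   warning. Default 4.
#' @return `DataFrame` with one row per gene: `n`, `median`, `q1`, `q3`,
#'   `iqr`, `min`, `max`, and comma-separated `outliers` and `extremes`
#'   sample ids.
#' @examples
#' m <- matrix(c(20, 21, 22, 23), 1, 4,
#'             dimnames = list("g1", paste0("s", 1:4)))
#' ctDescriptives(m)
#' @export
ctDescriptives <- function(x, subset = "total", minN = 4L) {
    ct <- if (is(x, "CtExperiment")) ctValues(subsetSamples(x, subset))
          else .asMatrixCheck(x, "ct")
    res <- lapply(rownames(ct), function(g) {
        v <- ct[g, ]
        ok <- !is.na(v)
        n <- sum(ok)
        if (n < minN) {
            warning("gene '", g, "' has fewer than ", minN,
                    " Ct values; quartiles undefined", call. = FALSE)
            return(DataFrame(gene = g, n = n, median = NA_real_,
                             q1 = NA_real_, q3 = NA_real_, iqr = NA_real_,
                             min = if (n) min(v[ok]) else NA_real_,
                             max = if (n) max(v[ok]) else NA_real_,
                             outliers = "", extremes = ""))
        }
        q <- quantile(v[ok], c(.25, .5, .75), type = 7, names = FALSE)
        iqr <- q[3] - q[1]
        lo <- q[1] - 1.5 * iqr; hi <- q[3] + 1.5 * iqr
        loX <- q[1] - 3 * iqr;  hiX <- q[3] + 3 * iqr
        out <- names(v)[ok][v[ok] < lo | v[ok] > hi]
        ext <- names(v)[ok][v[ok] < loX | v[ok] > hiX]
        DataFrame(gene = g, n = n, median = q[2], q1 = q[1], q3 = q[3],
                  iqr = iqr, min = min(v[ok]), max = max(v[ok]),
                  outliers = paste(out, collapse = ","),
                  extremes = paste(ext, collapse = ","))
    })
    out <- do.call(rbind, res)
    rownames(out) <- out$gene
    out
}

#' Amplification efficiency from a standard-curve slope
#'
#' A dilution-series standard curve plots Ct against log10 template
#' amount; its slope determines the per-cycle amplification efficiency as
#' `E = (10^(-1/slope) - 1) * 100` percent. A slope of
#' `-1/log10(2) = -3.3219` corresponds to perfect doubling (100%).
#'
#' @param slope Standard-curve slope (Ct per log10 dilution); must be
#'   negative.
#' @return Efficiency in percent.
#' @examples
#' efficiencyFromSlope(-1 / log10(2))  # 100
#' @export
efficiencyFromSlope <- function(slope) {
    if (any(!is.finite(slope)) || any(slope >= 0))
        stop("standard-curve slope must be finite and negative",
             call. = FALSE)
    (10^(-1 / slope) - 1) * 100
}
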