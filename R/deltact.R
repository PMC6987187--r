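#' @include CtExperiment.R results-methods.R
NULL

# resolve a Ct matrix from either a CtExperiment or a plain matrix
.ctOf <- function(x, subset = "total", genes = NULL) {
    if (is(x, "CtExperiment")) {
        ct <- ctValues(subsetSamples(x, subset, genes = genes))
    } else {
        ct <- .asMatrixCheck(x, "ct")
        if (!is.null(genes)) {
            .assertGenes(ct, genes)
            ct <- ct[genes, , drop = FALSE]
        }
    }
    ct
}

#' Pairwise SD matrix of Ct differences
#'
#' For every gene pair (j, k), the sample standard deviation (n - 1
#' denominator) of `Ct_j - Ct_k` over the samples where both genes were
#' detected. This is the building block of the comparative delta-Ct
#' stability method: a pair of stable genes keeps a constant Ct offset,
#' so the SD of their difference is small.
#'
#' @param x A [CtExperiment-class] or numeric Ct matrix.
#' @param subset Sample-subset label (see [subsetSamples()]).
#' @param genes Optional gene restriction.
#' @param minComplete Minimum pairwise-complete samples per pair; pairs
#'   below it get `NA`. Default 3.
#' @return Symmetric gene x gene matrix of SDs; zero diagonal.
#' @export
pairwiseDctSd <- function(x, subset = "total", genes = NULL,
                          minComplete = 3L) {
    ct <- .ctOf(x, subset, genes)
    k <- nrow(ct)
    out <- matrix(0, k, k, dimnames = list(rownames(ct), rownames(ct)))
    if (k < 2L) return(out)
    for (j in seq_len(k - 1L)) for (l in (j + 1L):k) {
        out[j, l] <- out[l, j] <-
            pairSD(ct[j, ] - ct[l, ], minN = minComplete)
    }
    out
}

#' Comparative delta-Ct stability scores
#'
#' Each gene's score is the mean, over all partner genes, of the SD of
#' the pairwise Ct differences ([pairwiseDctSd()]). Lower average SD
#' means the gene keeps a more constant offset to the rest of the panel,
#' i.e. more stable expression. Sample-wide loading effects (cDNA input)
#' cancel in the differences, so the score is invariant to per-sample
#' Ct shifts.
#'
#' @inheritParams pairwiseDctSd
#' @return A [StabilityResult-class] (`method = "delta_ct"`). Genes with
#'   no usable partner pair are dropped with a warning.
#' @examples
#' ct <- rbind(g1 = c(20, 21, 20, 21), g2 = c(25, 25, 25, 25),
#'             g3 = c(30, 31, 32, 33))
#' colnames(ct) <- paste0("s", 1:4)
#' stabilityScores(deltaCtStability(ct))
#' @export
deltaCtStability <- function(x, subset = "total", genes = NULL,
                             minComplete = 3L) {
    m <- pairwiseDctSd(x, subset, genes, minComplete)
    diag(m) <- NA_real_
    usable <- rowSums(!is.na(m)) > 0L
    if (!all(usable)) {
        warning("gene(s) without any usable pair dropped: ",
                paste(rownames(m)[!usable], collapse = ", "),
                call. = FALSE)
        m <- m[usable, usable, drop = FALSE]
        diag(m) <- NA_real_
    }
    if (nrow(m) < 2L)
        stop("delta-Ct scoring needs at least 2 usable genes",
             call. = FALSE)
    scores <- rowMeans(m, na.rm = TRUE)
    .StabilityResult("delta_ct", if (is(x, "CtExperiment")) subset
                                 else "custom", scores)
}
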