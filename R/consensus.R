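#' @include results-methods.R
NULL

#' Comprehensive consensus ranking across the four stability methods
#'
#' Aggregates the rank positions from the comparative delta-Ct, geNorm,
#' NormFinder and BestKeeper analyses by their geometric mean and ranks
#' genes by it (ascending; ties averaged, display order by gene id). The
#' recommended reference-gene set is the top `optimalN` genes, with
#' `optimalN` normally taken from the geNorm pairwise variation.
#'
#' @param results List of four [StabilityResult-class] objects (one per
#'   method, same gene set and subset). A [GeNormResult-class] among
#'   them supplies `optimalN` when not given explicitly.
#' @param optimalN Number of genes for the recommended set; defaults to
#'   the geNorm result's [optimalN()], or 2 if absent.
#' @return A [ConsensusResult-class].
#' @examples
#' ct <- matrix(20 + rnorm(100, sd = 0.3), 5, 20,
#'              dimnames = list(paste0("g", 1:5), paste0("s", 1:20)))
#' gn <- geNorm(ct)
#' res <- consensusRank(list(deltaCtStability(ct), gn,
#'                           normFinder(ct, groups = rep(c("a", "b"), 10)),
#'                           bestKeeper(ct)))
#' recommendedSet(res)
#' @export
consensusRank <- function(results, optimalN = NULL) {
    if (!is.list(results) || length(results) < 2L ||
        !all(vapply(results, is, logical(1L), "StabilityResult")))
        stop("results must be a list of StabilityResult objects",
             call. = FALSE)
    methods <- vapply(results, methodName, character(1L))
    if (anyDuplicated(methods))
        stop("duplicated method(s): ",
             paste(unique(methods[duplicated(methods)]), collapse = ", "),
             call. = FALSE)
    names(results) <- methods
    genes <- sort(names(stabilityRanks(results[[1L]])))
    for (r in results[-1L]) {
        g <- sort(names(stabilityRanks(r)))
        extra <- setdiff(genes, g)
        if (length(extra) || length(setdiff(g, genes)))
            stop("methods were run on different gene sets; missing: ",
                 paste(union(extra, setdiff(g, genes)), collapse = ", "),
                 call. = FALSE)
    }
    rankMat <- vapply(results, function(r) stabilityRanks(r)[genes],
                      numeric(length(genes)))
    rankMat <- matrix(rankMat, nrow = length(genes),
                      dimnames = list(genes, methods))
    gm <- apply(rankMat, 1L, geoMean)
    finalRank <- rankAsc(gm)
    if (is.null(optimalN)) {
        gnIdx <- which(vapply(results, is, logical(1L), "GeNormResult"))
        optimalN <- if (length(gnIdx)) optimalN(results[[gnIdx[1L]]])
                    else 2L
    }
    optimalN <- as.integer(optimalN)
    if (optimalN < 1L || optimalN > length(genes))
        stop("optimalN out of range", call. = FALSE)
    ord <- order(gm, genes)
    rec <- genes[ord][seq_len(optimalN)]
    tab <- DataFrame(gene = genes[ord], rankMat[ord, , drop = FALSE],
                     geomean = gm[ord], rank = finalRank[ord],
                     recommended = genes[ord] %in% rec,
                     row.names = genes[ord])
    colnames(tab)[seq_along(methods) + 1L] <- paste0("rank_", methods)
    new("ConsensusResult", table = tab, geomeans = gm,
        ranks = setNames(finalRank, genes), recommendedSet = rec,
        optimalN = optimalN,
        subset = subsetLabel(results[[1L]]))
}
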