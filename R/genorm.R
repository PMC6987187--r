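#' @include CtExperiment.R results-methods.R deltact.R
NULL

#' Relative quantities from Ct values
#'
#' Converts Ct to relative expression quantities per gene:
#' `Q = E_fold ^ (min(Ct) - Ct)`, where `E_fold` is the fold
#' amplification per cycle (2 at 100% efficiency) and the minimum is the
#' gene's lowest Ct over the selected samples. The best-expressed sample
#' of each gene thus has Q = 1 and all Q lie in (0, 1]; the anchor
#' cancels in every downstream ratio and only serves numeric range
#' safety. Missing T give missing Q.
#'
#' @param x A [CtExperiment-class] or numeric Ct matrix.
#' @param subset Sample-subset label (see [subsetSamples()]).
#' @param genes Optional gene restriction.
#' @param efficiencyCorrection Use the per-gene efficiencies stored in
#'   `x` (`FALSE`, the default, assumes perfect doubling, `E_fold = 2`).
#' @param efold Optional named per-gene `E_fold` vector overriding both.
#' @return Gene x sample matrix of relative quantities.
#' @examples
#' q <- relativeQuantities(rbind(g = c(20, 21, 22)))
#' stopifnot(all(q == c(1, 0.5, 0.25)))
#' @export
relativeQuantities <- function(x, subset = "total", genes = NULL,
                               efficiencyCorrection = FALSE,
                               efold = NULL) {
    ct <- .ctOf(x, subset, genes)
    if (is.null(colnames(ct)))
        colnames(ct) <- paste0("s", seq_len(ncol(ct)))
    e <- rep(2, nrow(ct))
    names(e) <- rownames(ct)
    if (efficiencyCorrection && is(x, "CtExperiment"))
        e[] <- eFold(x)[rownames(ct)]
    if (!is.null(efold)) {
        known <- intersect(names(efold), names(e))
        e[known] <- efold[known]
    }
    anchor <- apply(ct, 1L, min, na.rm = TRUE)
    e ^ (anchor - ct)
}

#' geNorm M values
#'
#' For each gene j, M_j is the arithmetic mean over all other genes k of
#' the SD (over samples) of the pairwise log2 expression ratio
#' `log2(Q_j / Q_k)`. Lower M means the gene's expression ratio to the
#' rest of the panel varies less, i.e. higher stability. With perfect
#' doubling the log2 ratios reduce to Ct differences, so the
#' first-iteration M values coincide with the comparative delta-Ct
#' scores.
#'
#' @param q Gene x sample matrix of relative quantities (see
#'   [relativeQuantities()]).
#' @param genes Optional gene restriction.
#' @param minComplete Minimum pairwise-complete samples per pair; pairs
#'   below it are skipped with a warning. Default 3.
#' @return Named numeric vector of M values.
#' @export
geNormM <- function(q, genes = NULL, minComplete = 3L) {
    q <- .asMatrixCheck(q, "q")
    if (!is.null(genes)) {
        .assertGenes(q, genes)
        q <- q[genes, , drop = FALSE]
    }
    k <- nrow(q)
    if (k < 2L) stop("geNorm needs at least 2 genes", call. = FALSE)
    lq <- log2(q)
    v <- matrix(NA_real_, k, k, dimnames = list(rownames(q), rownames(q)))
    skipped <- FALSE
    for (j in seq_len(k - 1L)) for (l in (j + 1L):k) {
        s <- pairSD(lq[j, ] - lq[l, ], minN = minComplete)
        if (is.na(s)) skipped <- TRUE
        v[j, l] <- v[l, j] <- s
    }
    if (skipped)
        warning("gene pair(s) with too few complete samples skipped",
                call. = FALSE)
    rowMeans(v, na.rm = TRUE)
}

#' Full geNorm analysis: iterative ranking and pairwise variation
#'
#' Runs the complete geNorm procedure on a Ct data set: relative
#' quantities, M values with stepwise exclusion of the least stable gene
#' (highest M; ties broken by gene-id lexicographic order, logged) until
#' two genes remain, the stability ranking (reverse exclusion order, the
#' final indistinguishable pair tied at rank 1.5), normalization factors
#' over the top-n genes, the pairwise-variation series V(n/n+1) and the
#' optimal reference-gene count: the smallest n whose V(n/n+1) falls
#' below `vCutoff` (default 0.15); when no V does, all genes are deemed
#' required and the result is flagged.
#'
#' @inheritParams relativeQuantities
#' @param vCutoff Pairwise-variation cutoff. Default 0.15.
#' @param minComplete Minimum pairwise-complete samples per gene pair.
#' @return A [GeNormResult-class].
#' @examples
#' ct <- rbind(g1 = c(20, 21, 20, 21), g2 = c(25, 25, 25, 25),
#'             g3 = c(30, 31, 32, 33))
#' colnames(ct) <- paste0("s", 1:4)
#' res <- geNorm(ct)
#' optimalN(res)
#' @export
geNorm <- function(x, subset = "total", genes = NULL,
                   efficiencyCorrection = FALSE, efold = NULL,
                   vCutoff = 0.15, minComplete = 3L) {
    q <- relativeQuantities(x, subset, genes,
                            efficiencyCorrection = efficiencyCorrection,
                            efold = efold)
    k <- nrow(q)
    if (k < 3L) stop("geNorm ranking needs at least 3 genes",
                     call. = FALSE)
    remaining <- rownames(q)
    excl <- character(0)
    traj <- list()
    scoreAtExit <- setNames(numeric(k), rownames(q))
    while (length(remaining) > 2L) {
        m <- geNormM(q, genes = remaining, minComplete = minComplete)
        traj[[length(traj) + 1L]] <- m
        worst <- names(m)[m == max(m)]
        if (length(worst) > 1L) {
            worst <- sort(worst)[1L]
            message("M-value tie broken lexicographically: ", worst)
        }
        scoreAtExit[worst] <- m[worst]
        excl <- c(excl, worst)
        remaining <- setdiff(remaining, worst)
    }
    mFinal <- geNormM(q, genes = remaining, minComplete = minComplete)
    traj[[length(traj) + 1L]] <- mFinal
    scoreAtExit[remaining] <- mFinal
    ranks <- setNames(numeric(k), rownames(q))
    ranks[remaining] <- 1.5
    if (length(excl))
        ranks[rev(excl)] <- 3:k
    ordered <- c(sort(remaining), rev(excl))
    pv <- .pairwiseVariation(q, ordered, vCutoff)
    details <- DataFrame(gene = rownames(q),
                         M = unname(scoreAtExit),
                         rank = unname(ranks),
                         row.names = rownames(q))
    new("GeNormResult",
        method = "genorm",
        subset = if (is(x, "CtExperiment")) subset else "custom",
        scores = scoreAtExit, ranks = ranks, details = details,
        mTrajectory = traj, exclusionOrder = excl,
        vSeries = pv$v, optimalN = pv$optimalN,
        vBelowCutoff = pv$below, vCutoff = vCutoff)
}

# V(n/n+1) along an ordered gene list (most stable first)
.pairwiseVariation <- function(q, ordered, vCutoff) {
    k <- length(ordered)
    v <- setNames(rep(NA_real_, k - 2L),
                  paste0(2:(k - 1L), "/", 3:k))
    lq <- log2(q[ordered, , drop = FALSE])
    for (n in 2:(k - 1L)) {
        nfA <- colMeans(lq[seq_len(n), , drop = FALSE])      # log2 NF_n
        nfB <- colMeans(lq[seq_len(n + 1L), , drop = FALSE]) # log2 NF_n+1
        v[n - 1L] <- pairSD(nfA - nfB, minN = 3L)
    }
    hit <- which(v < vCutoff)
    if (length(hit))
        list(v = v, optimalN = as.integer(hit[1L] + 1L), below = TRUE)
    else
        list(v = v, optimalN = as.integer(k), below = FALSE)
}

#' Pairwise variation series for a given ranking
#'
#' Standalone access to the V(n/n+1) computation used by [geNorm()]:
#' `NF_n` is the per-sample geometric mean of the relative quantities of
#' the n top-ranked genes, and `V(n/n+1)` is the SD over samples of
#' `log2(NF_n / NF_(n+1))`. A V below the cutoff means the (n+1)-th gene
#' no longer changes the normalization factor appreciably.
#'
#' @param q Gene x sample relative-quantity matrix.
#' @param ordered Character, genes ordered most stable first (e.g. from
#'   [geNorm()]).
#' @param vCutoff Cutoff for the optimal-n decision. Default 0.15.
#' @return List with `v` (named series), `optimalN`, and `below`
#'   (FALSE when no V fell below the cutoff).
#' @export
pairwiseVariation <- function(q, ordered, vCutoff = 0.15) {
    q <- .asMatrixCheck(q, "q")
    .assertGenes(q, ordered)
    if (length(ordered) < 3L)
        stop("pairwise variation needs at least 3 ranked genes",
             call. = FALSE)
    .pairwiseVariation(q, ordered, vCutoff)
}
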