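#' @include CtExperiment.R results-methods.R genorm.R
NULL

#' Relative target-gene quantification (2^-ddCt)
#'
#' Quantifies a target gene relative to a reference-gene set and a
#' control (calibrator) group via the 2^-ddCt scheme, generalized to
#' multi-gene normalizers and non-ideal amplification efficiencies:
#' per sample, the target's relative quantity is divided by the
#' normalization factor (geometric mean of the reference genes' relative
#' quantities); within each tissue the resulting values are scaled by
#' the control group's mean so the control averages exactly 1. With
#' perfect doubling and a single reference this is the textbook
#' 2^-ddCt computation.
#'
#' @param x A [CtExperiment-class], or a numeric Ct matrix together with
#'   `tissue` and `group` vectors.
#' @param target Target gene id.
#' @param referenceSet Character, one or more reference gene ids.
#' @param controlGroup Group label of the calibrator condition (e.g.
#'   `"ck"`).
#' @param subset Sample-subset label (see [subsetSamples()]).
#' @param tissue,group Per-sample labels, required for plain-matrix
#'   input; ignored for a `CtExperiment` (taken from its sample sheet).
#' @param efficiencyCorrection,efold Efficiency handling as in
#'   [relativeQuantities()].
#' @return A [ValidationResult-class] with replicate-level and
#'   tissue-x-group mean relative quantities.
#' @examples
#' ct <- rbind(tgt = c(26, 24), ref = c(20, 20))
#' colnames(ct) <- c("c1", "t1")
#' res <- ddctQuantify(ct, "tgt", "ref", controlGroup = "ck",
#'                     tissue = c("leaf", "leaf"), group = c("ck", "trt"))
#' resultTable(res)  # treated RQ = 4
#' @export
ddctQuantify <- function(x, target, referenceSet, controlGroup,
                         subset = "total", tissue = NULL, group = NULL,
                         efficiencyCorrection = FALSE, efold = NULL) {
    stopifnot(length(target) == 1L, length(referenceSet) >= 1L)
    if (is(x, "CtExperiment")) {
        sx <- subsetSamples(x, subset)
        tissue <- setNames(as.character(colData(sx)$tissue), colnames(sx))
        group <- setNames(as.character(colData(sx)$group), colnames(sx))
        ct <- ctValues(sx)
    } else {
        ct <- .asMatrixCheck(x, "ct")
        if (is.null(tissue) || is.null(group))
            stop("tissue and group labels required for matrix input",
                 call. = FALSE)
        tissue <- setNames(as.character(tissue), colnames(ct))
        group <- setNames(as.character(group), colnames(ct))
    }
    .assertGenes(ct, c(target, referenceSet))
    q <- relativeQuantities(ct, genes = unique(c(target, referenceSet)),
                            efficiencyCorrection = FALSE, efold = {
        e <- NULL
        if (efficiencyCorrection && is(x, "CtExperiment")) e <- eFold(x)
        if (!is.null(efold)) e <- efold
        e
    })
    lTarget <- log2(q[target, ])
    lNf <- colMeans(log2(q[referenceSet, , drop = FALSE]))
    delta <- lTarget - lNf
    drop <- is.na(delta)
    if (any(drop)) {
        warning(sum(drop), " sample(s) with missing target/reference Ct ",
                "dropped", call. = FALSE)
        delta <- delta[!drop]
        tissue <- tissue[names(delta)]
        group <- group[names(delta)]
    }
    normLabel <- paste(referenceSet, collapse = "+")
    per <- NULL
    for (t in sort(unique(tissue))) {
        inT <- names(delta)[tissue == t]
        ctrl <- inT[group[inT] == controlGroup]
        if (!length(ctrl))
            stop("empty control group '", controlGroup, "' in tissue '",
                 t, "'", call. = FALSE)
        rq0 <- 2^delta[inT]
        rq <- rq0 / mean(rq0[ctrl])
        per <- rbind(per, DataFrame(sample = inT, tissue = t,
                                    group = unname(group[inT]),
                                    normalizer = normLabel,
                                    rq = unname(rq)))
    }
    agg <- do.call(rbind, lapply(split(seq_len(nrow(per)),
                                       paste(per$tissue, per$group)),
        function(i) DataFrame(tissue = per$tissue[i[1L]],
                              group = per$group[i[1L]],
                              normalizer = normLabel,
                              rq_mean = mean(per$rq[i]),
                              rq_sd = if (length(i) > 1L) sd(per$rq[i])
                                      else NA_real_,
                              n = length(i))))
    rownames(agg) <- NULL
    new("ValidationResult", table = agg, perSample = per,
        target = target, referenceSet = referenceSet,
        controlGroup = controlGroup)
}

#' Compare normalizer choices on a target gene
#'
#' Runs [ddctQuantify()] under several normalizer sets (typically the
#' top-ranked gene, the recommended multi-gene combination, and the
#' least stable gene) and summarizes how far the resulting expression
#' profiles diverge: for every pair of normalizers, the maximum and mean
#' absolute log2 ratio of the tissue-x-group mean relative quantities.
#' An unstable normalizer with a condition-specific shift shows up as a
#' systematic fold bias in that condition.
#'
#' @inheritParams ddctQuantify
#' @param normalizers Named list of character vectors, each a reference
#'   set (e.g. `list(top1 = "g1", top3 = c("g1","g2","g3"),
#'   worst = "g9")`). Can be derived from a [ConsensusResult-class].
#' @return List with `results` (named [ValidationResult-class] list),
#'   `table` (combined tidy summary) and `divergence` (per normalizer
#'   pair: `max_abs_log2`, `mean_abs_log2`).
#' @export
compareNormalizers <- function(x, target, normalizers, controlGroup,
                               subset = "total", tissue = NULL,
                               group = NULL,
                               efficiencyCorrection = FALSE,
                               efold = NULL) {
    if (!is.list(normalizers) || is.null(names(normalizers)))
        stop("normalizers must be a named list of gene sets",
             call. = FALSE)
    results <- lapply(normalizers, function(refs)
        ddctQuantify(x, target, refs, controlGroup, subset = subset,
                     tissue = tissue, group = group,
                     efficiencyCorrection = efficiencyCorrection,
                     efold = efold))
    tabs <- lapply(names(results), function(nm) {
        t <- resultTable(results[[nm]])
        t$normalizer <- nm
        t
    })
    combined <- do.call(rbind, tabs)
    nms <- names(results)
    div <- NULL
    if (length(nms) >= 2L) {
        for (a in seq_len(length(nms) - 1L)) for (b in (a + 1L):length(nms)) {
            ta <- tabs[[a]]; tb <- tabs[[b]]
            key <- paste(ta$tissue, ta$group)
            m <- match(key, paste(tb$tissue, tb$group))
            lr <- abs(log2(ta$rq_mean / tb$rq_mean[m]))
            div <- rbind(div, DataFrame(normalizer_a = nms[a],
                                        normalizer_b = nms[b],
                                        max_abs_log2 = max(lr),
                                        mean_abs_log2 = mean(lr)))
        }
        rownames(div) <- NULL
    }
    list(results = results, table = combined, divergence = div)
}
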