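#' @include CtExperiment.R results-methods.R genorm.R
NULL

#' NormFinder-style model-based stability values
#'
#' Decomposes per-sample-centered log2 expression into intragroup
#' (within-condition) variance and intergroup (between-condition) effects
#' and scores each gene by a stability value (SV) that adds the shrunken
#' absolute intergroup effect to the sampling-error contribution of the
#' intragroup variance; lower SV means more stable. The estimator:
#'
#' 1. center log2 relative quantities per sample across genes (this
#'    removes loading effects);
#' 2. per gene x group, compute the mean and the residual variance
#'    (n - 1);
#' 3. bias-correct the intragroup variances for the centering step
#'    (requires more than two genes);
#' 4. estimate the dispersion of intergroup effects across the panel and
#'    shrink each gene's group effect towards zero accordingly;
#' 5. SV = mean over groups of |shrunken effect| plus the intragroup
#'    sampling SE `sqrt(sigma2 / n_g)` (unshrunken, so that a panel with
#'    no detectable intergroup dispersion still ranks genes by their
#'    noise).
#'
#' With a single group (or when every group is too small) the SV reduces
#' to the intragroup SD.
#'
#' @inheritParams relativeQuantities
#' @param groups Named character vector, group label per sample. For a
#'   [CtExperiment-class] this defaults to [analysisGroups()] of the
#'   chosen subset (condition subsets act as groups for `"total"`).
#'   `NULL` with a plain matrix means single-group mode.
#' @return A [NormFinderResult-class] (`method = "normfinder"`).
#' @examples
#' set.seed(1)
#' ct <- matrix(20 + rnorm(60, sd = 0.2), 5, 12,
#'              dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
#' nf <- normFinder(ct, groups = rep(c("a", "b"), each = 6))
#' stabilityRanks(nf)
#' @export
normFinder <- function(x, subset = "total", genes = NULL, groups = NULL,
                       efficiencyCorrection = FALSE, efold = NULL) {
    q <- relativeQuantities(x, subset, genes,
                            efficiencyCorrection = efficiencyCorrection,
                            efold = efold)
    if (is.null(groups) && is(x, "CtExperiment"))
        groups <- analysisGroups(x, subset)
    lq <- log2(q)
    k <- nrow(lq)
    if (k <= 2L)
        stop("NormFinder requires more than 2 genes (the variance ",
             "correction is undefined otherwise)", call. = FALSE)
    ok <- colSums(is.na(lq)) == 0L
    if (!all(ok)) {
        warning(sum(!ok), " sample(s) with missing Ct dropped for ",
                "NormFinder", call. = FALSE)
        lq <- lq[, ok, drop = FALSE]
    }
    if (is.null(groups)) {
        grp <- rep("all", ncol(lq))
    } else {
        grp <- as.character(groups[colnames(lq)])
        if (any(is.na(grp)))
            stop("groups must cover every analyzed sample", call. = FALSE)
    }
    ng <- table(grp)
    small <- names(ng)[ng < 2L]
    if (length(small)) {
        warning("group(s) with fewer than 2 samples dropped: ",
                paste(small, collapse = ", "), call. = FALSE)
        keep <- !grp %in% small
        if (!any(keep))
            stop("no usable samples left", call. = FALSE)
        lq <- lq[, keep, drop = FALSE]
        grp <- grp[keep]
        if (!length(unique(grp))) grp <- rep("all", ncol(lq))
    }
    glev <- sort(unique(grp))
    G <- length(glev)
    singleGroup <- G == 1L

    # 1. remove per-sample loading: center each column across genes
    z <- sweep(lq, 2L, colMeans(lq))

    zbar <- s2 <- matrix(NA_real_, k, G,
                         dimnames = list(rownames(lq), glev))
    n_g <- setNames(integer(G), glev)
    for (g in glev) {
        zg <- z[, grp == g, drop = FALSE]
        n_g[g] <- ncol(zg)
        zbar[, g] <- rowMeans(zg)
        s2[, g] <- apply(zg, 1L, var)
    }
    # 3. bias-corrected intragroup variances (centering induces a
    #    -sigma2bar/k term; the 1 - 2/k factor undoes the own-gene share)
    sigma2 <- matrix(NA_real_, k, G, dimnames = dimnames(s2))
    for (g in glev) {
        s2barG <- mean(s2[, g]) * k / (k - 1)
        sigma2[, g] <- pmax(0, (s2[, g] - s2barG / k) / (1 - 2 / k))
    }

    if (singleGroup) {
        sv <- sqrt(sigma2[, 1L])
        dtilde <- matrix(0, k, G, dimnames = dimnames(sigma2))
        gamma2 <- 0
    } else {
        # 4. intergroup effects and their shrinkage
        d <- zbar - rowMeans(zbar)
        se2 <- sweep(sigma2, 2L, n_g, "/")   # sigma2_ig / n_g
        gamma2 <- max(0, sum(d^2) / ((k - 1) * (G - 1)) - mean(se2))
        denom <- gamma2 + se2
        shrink <- ifelse(denom > 0, gamma2 / denom, 0)
        dtilde <- d * shrink
        # 5. stability value: shrunken |group effect| plus the intragroup
        # sampling SE. The SE is deliberately not multiplied by the
        # shrinkage factor: when the panel shows no intergroup dispersion
        # (gamma2 at its zero floor) a shrunken SE would collapse every
        # SV to zero and noisy genes would tie with quiet ones.
        sv <- rowMeans(abs(dtilde) + sqrt(se2))
    }
    details <- DataFrame(gene = rownames(lq), SV = unname(sv),
                         rank = unname(rankAsc(sv)),
                         row.names = rownames(lq))
    new("NormFinderResult",
        method = "normfinder",
        subset = if (is(x, "CtExperiment")) subset else "custom",
        scores = sv, ranks = rankAsc(sv), details = details,
        groupEffects = dtilde, groupVariances = sigma2,
        groupSizes = n_g, gamma2 = gamma2, singleGroup = singleGroup)
}
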