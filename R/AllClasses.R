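#' @importFrom methods setClass setGeneric setMethod setValidity new is
#'   validObject callNextMethod slot
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData rowData<- colData colData<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats sd cor median quantile rnorm runif setNames var
#' @importFrom utils read.csv write.csv head
NULL

.VALID_TISSUES <- c("leaf", "stem", "root", "other")
.VALID_SUBSETS <- c("developmental", "cold", "drought", "custom")

#' CtExperiment: threshold-cycle values with sample and assay metadata
#'
#' A \linkS4class{SummarizedExperiment} whose single assay `"ct"` holds
#' RT-qPCR threshold-cycle (Ct) values (genes in rows, samples in columns).
#' `colData` carries the sample sheet (`tissue`, `subset`, `group`,
#' `replicate`) and `rowData` the per-gene amplification efficiency in
#' percent (`efficiency_percent`, 100 = perfect doubling per cycle).
#'
#' Finite Ct entries must be strictly positive; non-detects are `NA`.
#' Values above a detection ceiling (default 40 cycles) can be masked to
#' `NA` at construction.
#'
#' @name CtExperiment-class
#' @aliases CtExperiment-class
#' @exportClass CtExperiment
setClass("CtExperiment", contains = "SummarizedExperiment")

setValidity("CtExperiment", function(object) {
    msg <- character(0)
    if (!"ct" %in% assayNames(object))
        msg <- c(msg, "assay 'ct' is required")
    else {
        ct <- assay(object, "ct")
        if (!is.numeric(ct))
            msg <- c(msg, "assay 'ct' must be numeric")
        else if (any(!is.na(ct) & (ct <= 0 | is.infinite(ct))))
            msg <- c(msg, "finite Ct values must be strictly positive")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids (rownames) must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids (colnames) must be present and unique")
    needed <- c("tissue", "subset", "group", "replicate")
    miss <- setdiff(needed, colnames(colData(object)))
    if (length(miss))
        msg <- c(msg, paste0("colData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    else {
        cd <- colData(object)
        badT <- setdiff(unique(as.character(cd$tissue)), .VALID_TISSUES)
        if (length(badT))
            msg <- c(msg, paste0("unknown tissue label(s): ",
                                 paste(badT, collapse = ", ")))
        badS <- setdiff(unique(as.character(cd$subset)), .VALID_SUBSETS)
        if (length(badS))
            msg <- c(msg, paste0("unknown subset label(s): ",
                                 paste(badS, collapse = ", ")))
        if (any(!is.finite(cd$replicate)) || any(cd$replicate < 1))
            msg <- c(msg, "replicate must be a positive integer")
    }
    if ("efficiency_percent" %in% colnames(rowData(object))) {
        e <- rowData(object)$efficiency_percent
        if (any(!is.finite(e)) || any(e <= 0))
            msg <- c(msg, "efficiency_percent must be finite and positive")
    }
    if (length(msg)) msg else TRUE
})

#' One method's per-gene stability scores and ranks
#'
#' Container for the output of a single stability estimator run on one
#' sample subset: the per-gene score (lower = more stable) and the rank
#' positions (1 = best, ties averaged).
#'
#' @slot method One of `"delta_ct"`, `"genorm"`, `"normfinder"`,
#'   `"bestkeeper"`.
#' @slot subset Sample-subset label the scores refer to (e.g. `"cold"`,
#'   `"total"`).
#' @slot scores Named numeric vector of per-gene scores.
#' @slot ranks Named numeric vector of rank positions.
#' @slot details Method-specific per-gene table.
#'
#' @name StabilityResult-class
#' @exportClass StabilityResult
setClass("StabilityResult",
    representation(method = "character", subset = "character",
                   scores = "numeric", ranks = "numeric",
                   details = "DataFrame"))

setValidity("StabilityResult", function(object) {
    msg <- character(0)
    if (length(object@method) != 1L ||
        !object@method %in% c("delta_ct", "genorm", "normfinder",
                              "bestkeeper"))
        msg <- c(msg, "method must be one of delta_ct/genorm/normfinder/bestkeeper")
    if (length(object@scores) != length(object@ranks) ||
        !identical(names(object@scores), names(object@ranks)))
        msg <- c(msg, "scores and ranks must be parallel named vectors")
    n <- length(object@ranks)
    if (n && !isTRUE(all.equal(sum(object@ranks), n * (n + 1) / 2)))
        msg <- c(msg, "ranks must be a permutation of 1..n up to tie-averaging")
    if (length(msg)) msg else TRUE
})

#' geNorm result: M values, exclusion order and pairwise variation
#'
#' Adds to \linkS4class{StabilityResult} the full geNorm output: the M
#' trajectory over the iterative-exclusion rounds, the exclusion order
#' (least stable first), the pairwise-variation series V(n/n+1) and the
#' optimal reference-gene count under the 0.15 rule. The final two genes
#' cannot be separated by geNorm and share rank 1.5.
#'
#' @slot mTrajectory List of named numeric vectors, M values per round.
#' @slot exclusionOrder Character, genes in order of removal.
#' @slot vSeries Named numeric, V(n/n+1) for n = 2..(n_genes - 1).
#' @slot optimalN Integer, smallest n with V(n/n+1) below the cutoff.
#' @slot vBelowCutoff Logical, FALSE if no V fell below the cutoff (then
#'   `optimalN` is the full gene count).
#' @slot vCutoff The cutoff used (default 0.15).
#'
#' @name GeNormResult-class
#' @exportClass GeNormResult
setClass("GeNormResult", contains = "StabilityResult",
    representation(mTrajectory = "list", exclusionOrder = "character",
                   vSeries = "numeric", optimalN = "integer",
                   vBelowCutoff = "logical", vCutoff = "numeric"))

setValidity("GeNormResult", function(object) {
    msg <- character(0)
    if (any(object@vSeries < 0, na.rm = TRUE))
        msg <- c(msg, "V values must be non-negative")
    n <- length(object@scores)
    if (length(object@optimalN) == 1L &&
        (object@optimalN < 2L || object@optimalN > max(n, 2L)))
        msg <- c(msg, "optimalN must lie in [2, n_genes]")
    if (length(msg)) msg else TRUE
})

#' NormFinder result: variance decomposition diagnostics
#'
#' Adds per-gene-by-group intragroup variance estimates and shrunken
#' intergroup effects to the stability scores.
#'
#' @slot groupEffects Matrix (gene x group) of shrunken intergroup
#'   effects (log2 scale).
#' @slot groupVariances Matrix (gene x group) of intragroup variance
#'   estimates (floored at zero).
#' @slot groupSizes Named integer, samples per group.
#' @slot gamma2 Estimated intergroup-effect dispersion.
#' @slot singleGroup TRUE when scored without a group structure
#'   (score = intragroup SD).
#'
#' @name NormFinderResult-class
#' @exportClass NormFinderResult
setClass("NormFinderResult", contains = "StabilityResult",
    representation(groupEffects = "matrix", groupVariances = "matrix",
                   groupSizes = "integer", gamma2 = "numeric",
                   singleGroup = "logical"))

setValidity("NormFinderResult", function(object) {
    msg <- character(0)
    if (any(object@groupVariances < 0, na.rm = TRUE))
        msg <- c(msg, "intragroup variances must be non-negative")
    if (any(object@scores < 0, na.rm = TRUE))
        msg <- c(msg, "stability values must be non-negative")
    if (length(msg)) msg else TRUE
})

#' BestKeeper result: descriptive Ct statistics and index correlations
#'
#' Adds the per-gene descriptive table (mean/geometric-mean/min/max/SD/CV%
#' of raw Ct, Pearson r against the BestKeeper index, the SD > 1 exclusion
#' flag, the three index-wise rank positions and their geometric-mean
#' composite) and the per-sample index itself.
#'
#' @slot bkTable Per-gene table (see [bestKeeper()]).
#' @slot index Named numeric, per-sample BestKeeper index (geometric mean
#'   Ct over qualifying genes).
#' @slot indexGenes Genes the index was built from (SD <= 1).
#'
#' @name BestKeeperResult-class
#' @exportClass BestKeeperResult
setClass("BestKeeperResult", contains = "StabilityResult",
    representation(bkTable = "DataFrame", index = "numeric",
                   indexGenes = "character"))

#' Candidate-screen report
#'
#' Per-gene expression statistics (mean TPM, SD, CV, tissue-group means,
#' log2 fold change between extreme tissue means) plus the two candidate
#' lists: stage 1 (lenient thresholds, CV-ranked) and stage 2 (strict).
#'
#' @slot stats Per-gene statistics table.
#' @slot stage1 Character, stage-1 pass list ranked by ascending CV
#'   (truncated to `top_k`).
#' @slot stage2 Character, strict candidate list (subset of stage 1).
#' @slot thresholds Named list of the thresholds applied.
#'
#' @name ScreenReport-class
#' @exportClass ScreenReport
setClass("ScreenReport",
    representation(stats = "DataFrame", stage1 = "character",
                   stage2 = "character", thresholds = "list"))

setValidity("ScreenReport", function(object) {
    msg <- character(0)
    if (!all(object@stage2 %in% object@stage1))
        msg <- c(msg, "stage-2 candidates must be a subset of stage 1")
    if (!all(object@stage1 %in% rownames(object@stats)))
        msg <- c(msg, "stage-1 candidates must come from the input genes")
    if (length(msg)) msg else TRUE
})

#' Consensus ranking across the four stability methods
#'
#' @slot table Per-gene table: the four method ranks, their geometric
#'   mean, and the final comprehensive rank.
#' @slot geomeans Named numeric, geometric mean of the four ranks.
#' @slot ranks Named numeric, final comprehensive ranks.
#' @slot recommendedSet Top `optimalN` genes of the final ranking.
#' @slot optimalN Reference-gene count used for the recommendation.
#' @slot subset Sample-subset label.
#'
#' @name ConsensusResult-class
#' @exportClass ConsensusResult
setClass("ConsensusResult",
    representation(table = "DataFrame", geomeans = "numeric",
                   ranks = "numeric", recommendedSet = "character",
                   optimalN = "integer", subset = "character"))

setValidity("ConsensusResult", function(object) {
    msg <- character(0)
    if (length(object@recommendedSet) != object@optimalN)
        msg <- c(msg, "recommended set size must equal optimalN")
    if (length(msg)) msg else TRUE
})

#' 2^-ddCt validation result
#'
#' Relative quantities (RQ) of a target gene per tissue and group, under a
#' named normalizer (single reference gene or geometric-mean combination),
#' expressed relative to the control group of each tissue.
#'
#' @slot table Tidy per-tissue/group summary: `tissue`, `group`,
#'   `normalizer`, `rq_mean`, `rq_sd`, `n`.
#' @slot perSample Replicate-level RQs.
#' @slot target Target gene id.
#' @slot referenceSet Reference gene id(s) used for normalization.
#' @slot controlGroup Control (calibrator) group label.
#'
#' @name ValidationResult-class
#' @exportClass ValidationResult
setClass("ValidationResult",
    representation(table = "DataFrame", perSample = "DataFrame",
                   target = "character", referenceSet = "character",
                   controlGroup = "character"))

setValidity("ValidationResult", function(object) {
    if (any(object@perSample$rq <= 0, na.rm = TRUE))
        "relative quantities must be positive" else TRUE
})
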