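#' @include AllClasses.R
NULL

#' Per-gene stability scores
#'
#' Extract the per-gene stability score from a stability result. Lower
#' scores always mean more stable expression, whatever the method
#' (mean pairwise-SD for the comparative delta-Ct method, the geNorm M
#' value, the NormFinder stability value, or the BestKeeper rank
#' composite).
#'
#' @param x A [StabilityResult-class] (or subclass) object.
#' @return Named numeric vector, one score per gene.
#' @export
setGeneric("stabilityScores", function(x) standardGeneric("stabilityScores"))

#' Per-gene stability ranks
#'
#' Rank positions (1 = most stable) corresponding to [stabilityScores()].
#' Ties carry average ranks.
#'
#' @param x A [StabilityResult-class] (or subclass) object.
#' @return Named numeric vector of rank positions.
#' @export
setGeneric("stabilityRanks", function(x) standardGeneric("stabilityRanks"))

#' @rdname stabilityScores
#' @export
setGeneric("methodName", function(x) standardGeneric("methodName"))

#' @rdname stabilityScores
#' @export
setGeneric("subsetLabel", function(x) standardGeneric("subsetLabel"))

#' Result table
#'
#' A per-gene table view of a result object, suitable for export as CSV.
#'
#' @param x A result object.
#' @return A [S4Vectors::DataFrame-class].
#' @export
setGeneric("resultTable", function(x) standardGeneric("resultTable"))

#' Optimal number of reference genes
#'
#' The smallest number n of top-ranked reference genes whose pairwise
#' variation V(n/n+1) falls below the cutoff (default 0.15); see
#' [pairwiseVariation()].
#'
#' @param x A [GeNormResult-class] or [ConsensusResult-class].
#' @return Integer scalar.
#' @export
setGeneric("optimalN", function(x) standardGeneric("optimalN"))

#' @rdname optimalN
#' @export
setGeneric("vSeries", function(x) standardGeneric("vSeries"))

#' @rdname optimalN
#' @export
setGeneric("exclusionOrder", function(x) standardGeneric("exclusionOrder"))

#' Recommended reference-gene set
#'
#' The top genes of the consensus ranking, as many as the geNorm pairwise
#' variation says are needed.
#'
#' @param x A [ConsensusResult-class].
#' @return Character vector of gene identifiers.
#' @export
setGeneric("recommendedSet", function(x) standardGeneric("recommendedSet"))
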