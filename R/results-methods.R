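#' @include AllClasses.R AllGenerics.R
NULL

# shared constructor used by the four estimators
.StabilityResult <- function(method, subset, scores, details = NULL) {
    ranks <- rankAsc(scores)
    if (is.null(details))
        details <- DataFrame(gene = names(scores), score = unname(scores),
                             rank = unname(ranks),
                             row.names = names(scores))
    new("StabilityResult", method = method, subset = subset,
        scores = scores, ranks = ranks, details = details)
}

#' @rdname stabilityScores
#' @export
setMethod("stabilityScores", "StabilityResult", function(x) x@scores)

#' @rdname stabilityRanks
#' @export
setMethod("stabilityRanks", "StabilityResult", function(x) x@ranks)

#' @rdname stabilityScores
#' @export
setMethod("methodName", "StabilityResult", function(x) x@method)

#' @rdname stabilityScores
#' @export
setMethod("subsetLabel", "StabilityResult", function(x) x@subset)

#' @rdname resultTable
#' @export
setMethod("resultTable", "StabilityResult", function(x) {
    ord <- order(x@ranks, names(x@scores))
    DataFrame(gene = names(x@scores)[ord],
              score = unname(x@scores)[ord],
              rank = unname(x@ranks)[ord])
})

setMethod("show", "StabilityResult", function(object) {
    cat(class(object), "(", object@method, ", subset = ", object@subset,
        "): ", length(object@scores), " genes\n", sep = "")
    tab <- resultTable(object)
    cat("  most stable: ",
        paste(head(tab$gene, 3), collapse = ", "), "\n", sep = "")
    cat("  least stable: ", tab$gene[nrow(tab)], "\n", sep = "")
})

#' @rdname optimalN
#' @export
setMethod("optimalN", "GeNormResult", function(x) x@optimalN)

#' @rdname optimalN
#' @export
setMethod("vSeries", "GeNormResult", function(x) x@vSeries)

#' @rdname optimalN
#' @export
setMethod("exclusionOrder", "GeNormResult", function(x) x@exclusionOrder)

setMethod("show", "GeNormResult", function(object) {
    callNextMethod()
    cat("  optimal n = ", object@optimalN,
        if (!object@vBelowCutoff) " (no V below cutoff)" else "",
        "; V cutoff ", object@vCutoff, "\n", sep = "")
})

#' @rdname resultTable
#' @export
setMethod("resultTable", "BestKeeperResult", function(x) x@bkTable)

#' @rdname resultTable
#' @export
setMethod("resultTable", "ScreenReport", function(x) x@stats)

setMethod("show", "ScreenReport", function(object) {
    cat("ScreenReport:", nrow(object@stats), "genes;",
        length(object@stage1), "pass stage 1;",
        length(object@stage2), "strict candidates\n")
})

#' @describeIn ScreenReport-class Stage-1 pass list (CV-ranked).
#' @param x A `ScreenReport`.
#' @export
stage1Candidates <- function(x) {
    stopifnot(is(x, "ScreenReport")); x@stage1
}

#' @describeIn ScreenReport-class Strict stage-2 candidate list.
#' @export
stage2Candidates <- function(x) {
    stopifnot(is(x, "ScreenReport")); x@stage2
}

#' @rdname resultTable
#' @export
setMethod("resultTable", "ConsensusResult", function(x) x@table)

#' @rdname recommendedSet
#' @export
setMethod("recommendedSet", "ConsensusResult", function(x) x@recommendedSet)

#' @rdname optimalN
#' @export
setMethod("optimalN", "ConsensusResult", function(x) x@optimalN)

#' @rdname stabilityRanks
#' @export
setMethod("stabilityRanks", "ConsensusResult", function(x) x@ranks)

setMethod("show", "ConsensusResult", function(object) {
    cat("ConsensusResult (subset = ", object@subset, "): ",
        length(object@ranks), " genes\n", sep = "")
    cat("  recommended set (n = ", object@optimalN, "): ",
        paste(object@recommendedSet, collapse = ", "), "\n", sep = "")
})

#' @rdname resultTable
#' @export
setMethod("resultTable", "ValidationResult", function(x) x@table)

setMethod("show", "ValidationResult", function(object) {
    cat("ValidationResult: target ", object@target, " vs {",
        paste(object@referenceSet, collapse = ", "),
        "}, control = ", object@controlGroup, "\n", sep = "")
    cat("  ", nrow(object@table), " tissue x group cells\n", sep = "")
})
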