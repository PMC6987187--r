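# Internal numeric helpers shared across the stability estimators.

# geometric mean; NA propagates unless na.rm
geoMean <- function(x, na.rm = FALSE) {
    if (na.rm) x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    exp(mean(log(x)))
}

# ascending ranks, 1 = best, ties averaged, NA kept
rankAsc <- function(x) rank(x, ties.method = "average", na.last = "keep")

# descending ranks (used for BestKeeper's r column)
rankDesc <- function(x) rank(-x, ties.method = "average", na.last = "keep")

# sample SD over pairwise-complete values; NA if fewer than minN
pairSD <- function(x, minN = 3L) {
    x <- x[!is.na(x)]
    if (length(x) < minN) NA_real_ else sd(x)
}

.assertGenes <- function(x, genes) {
    miss <- setdiff(genes, rownames(x))
    if (length(miss))
        stop("gene(s) not found in the Ct matrix: ",
             paste(miss, collapse = ", "), call. = FALSE)
}

.asMatrixCheck <- function(m, what) {
    if (!is.matrix(m) || !is.numeric(m))
        stop(what, " must be a numeric matrix", call. = FALSE)
    if (is.null(rownames(m)))
        stop(what, " must have rownames (gene ids)", call. = FALSE)
    if (is.null(colnames(m)))
        colnames(m) <- paste0("s", seq_len(ncol(m)))
    m
}
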