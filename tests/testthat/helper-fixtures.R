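# Shared in-code fixtures.

# the 3-gene / 4-sample toy with hand-computable pairwise SDs
toyCt <- function() {
    ct <- rbind(g1 = c(20, 21, 20, 21),
                g2 = c(25, 25, 25, 25),
                g3 = c(30, 31, 32, 33))
    colnames(ct) <- paste0("s", 1:4)
    ct
}

# random Ct matrix with optional per-sample loading and group labels
randomCt <- function(nGenes = 6, nSamples = 12, sd = 0.5, seed = 1) {
    set.seed(seed)
    ct <- matrix(rnorm(nGenes * nSamples, mean = 25, sd = sd),
                 nGenes, nSamples,
                 dimnames = list(sprintf("g%02d", seq_len(nGenes)),
                                 sprintf("s%02d", seq_len(nSamples))))
    ct
}

# minimal valid sample sheet for a set of sample ids
toySheet <- function(samples, subset = "cold",
                     groups = rep("ck", length(samples))) {
    data.frame(sample_id = samples, tissue = "leaf", subset = subset,
               group = groups,
               replicate = seq_along(samples), row.names = samples)
}
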