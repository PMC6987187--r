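# build a mock StabilityResult with prescribed ranks
mockResult <- function(method, ranks) {
    scores <- ranks / 10
    qpcrStab:::.StabilityResult(method, "custom",
                                setNames(scores, names(ranks)))
}

test_that("the consensus geomean aggregates the four ranks", {
    genes <- c("a", "b", "c")
    res <- list(
        mockResult("delta_ct", c(a = 1, b = 2, c = 3)),
        mockResult("genorm", c(a = 2, b = 1, c = 3)),
        mockResult("normfinder", c(a = 1, b = 2, c = 3)),
        mockResult("bestkeeper", c(a = 3, b = 1, c = 2)))
    cons <- consensusRank(res, optimalN = 2)
    gm <- cons@geomeans
    expect_equal(unname(gm["a"]), (1 * 2 * 1 * 3)^(1 / 4), tolerance = 1e-9)
    expect_equal(unname(gm["a"]), 1.5651, tolerance = 1e-4)
    expect_equal(unname(gm["b"]), (2 * 1 * 2 * 1)^(1 / 4))
    expect_equal(unname(gm["c"]), (3 * 3 * 3 * 2)^(1 / 4), tolerance = 1e-9)
    expect_equal(unname(stabilityRanks(cons)["c"]), 3)
    expect_identical(recommendedSet(cons), c("b", "a"))
})

test_that("a unanimous bottom gene takes the last comprehensive rank", {
    n <- 15
    genes <- sprintf("g%02d", 1:n)
    base <- setNames(seq_len(n), genes)
    res <- lapply(c("delta_ct", "genorm", "normfinder", "bestkeeper"),
                  function(m) mockResult(m, base))
    cons <- consensusRank(res, optimalN = 5)
    expect_equal(unname(stabilityRanks(cons)["g15"]), 15)
    expect_equal(unname(cons@geomeans["g15"]), 15)
})

test_that("mismatched gene sets raise an error naming the gene", {
    res <- list(mockResult("delta_ct", c(a = 1, b = 2, c = 3)),
                mockResult("genorm", c(a = 1, b = 2, d = 3)))
    expect_error(consensusRank(res, optimalN = 2), "missing: .*[cd]")
})

test_that("relabeling genes permutes the consensus identically", {
    set.seed(51)
    genes <- sprintf("g%02d", 1:8)
    mk <- function(nms) lapply(c("delta_ct", "genorm", "normfinder",
                                 "bestkeeper"), function(m) {
        r <- setNames(sample(8), nms)
        mockResult(m, r)
    })
    res <- mk(genes)
    cons <- consensusRank(res, optimalN = 3)
    # rename genes via a fixed permutation of labels
    map <- setNames(sprintf("h%02d", c(3, 1, 4, 2, 8, 6, 7, 5)), genes)
    res2 <- lapply(res, function(r) {
        s <- stabilityScores(r)
        names(s) <- unname(map[names(s)])
        qpcrStab:::.StabilityResult(methodName(r), "custom", s)
    })
    cons2 <- consensusRank(res2, optimalN = 3)
    expect_equal(unname(cons2@geomeans[map[genes]]),
                 unname(cons@geomeans[genes]))
    expect_setequal(recommendedSet(cons2),
                    unname(map[recommendedSet(cons)]))
})

test_that("a gene dominating in all methods cannot rank below a dominated one", {
    set.seed(52)
    for (i in 1:10) {
        genes <- sprintf("g%02d", 1:6)
        rks <- replicate(4, setNames(sample(6), genes), simplify = FALSE)
        # force g01 to dominate g02 everywhere
        rks <- lapply(rks, function(r) {
            if (r["g01"] > r["g02"]) { tmp <- r["g01"]; r["g01"] <- r["g02"]; r["g02"] <- tmp }
            r
        })
        res <- mapply(mockResult,
                      c("delta_ct", "genorm", "normfinder", "bestkeeper"),
                      rks, SIMPLIFY = FALSE)
        cons <- consensusRank(unname(res), optimalN = 2)
        expect_lte(stabilityRanks(cons)["g01"], stabilityRanks(cons)["g02"])
    }
})
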