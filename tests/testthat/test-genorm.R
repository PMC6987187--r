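test_that("relative quantities anchor at each gene's best expression", {
    q <- relativeQuantities(rbind(g = c(20, 21, 22)))
    expect_equal(unname(q[1, ]), c(1, 0.5, 0.25))
    q2 <- relativeQuantities(rbind(g = c(20, 21)), efold = c(g = 1.9))
    expect_equal(unname(q2[1, ]), c(1, 1 / 1.9), tolerance = 1e-6)
    q3 <- relativeQuantities(rbind(g = rep(23.4, 5)))
    expect_true(all(q3 == 1))
    # missing Ct propagates
    q4 <- relativeQuantities(rbind(g = c(20, NA, 22)))
    expect_true(is.na(q4[1, 2]))
})

test_that("M values equal a brute-force log-ratio oracle and delta-Ct", {
    ct <- toyCt()
    q <- relativeQuantities(ct)
    m <- geNormM(q)
    # independent oracle: mean over partners of SD of log2 ratios
    lr <- log2(q)
    oracle <- sapply(1:3, function(j)
        mean(sapply(setdiff(1:3, j), function(k) sd(lr[j, ] - lr[k, ]))))
    expect_equal(unname(m), oracle, tolerance = 1e-12)
    expect_equal(unname(m), c(0.8660, 0.9342, 1.2229), tolerance = 1e-4)
    # with perfect doubling, M == delta-Ct scores
    expect_equal(m, stabilityScores(deltaCtStability(ct)),
                 tolerance = 1e-9)
    # permutation invariance
    expect_equal(geNormM(q[, c(3, 1, 4, 2)]), m, tolerance = 1e-12)
    # proportional genes have M = 0
    qp <- rbind(a = c(1, .5, .25, .8), b = 0.4 * c(1, .5, .25, .8))
    expect_equal(unname(geNormM(qp)), c(0, 0))
})

test_that("iterative exclusion ranks the toy panel correctly", {
    res <- geNorm(toyCt())
    expect_identical(exclusionOrder(res), "g3")
    expect_equal(stabilityRanks(res),
                 c(g1 = 1.5, g2 = 1.5, g3 = 3))
    expect_lt(abs(unname(vSeries(res)["2/3"]) - 0.3967), 1e-4)
})

test_that("identical genes are excluded by lexicographic tie-break", {
    ct <- rbind(g1 = c(20, 21, 22, 23), g2 = c(20, 21, 22, 23),
                g3 = c(20, 21, 22, 23), g4 = c(20, 21, 22, 23))
    colnames(ct) <- paste0("s", 1:4)
    expect_message(res <- geNorm(ct), "tie broken lexicographically: g1")
    expect_identical(exclusionOrder(res), c("g1", "g2"))
    expect_true(all(stabilityScores(res) == 0))
})

test_that("a gene with large planted group shifts is excluded first", {
    sim <- simulateCt(simCtConfig(
        nGenes = 6L,
        sigma = setNames(rep(0.1, 6), sprintf("g%02d", 1:6)),
        mu = setNames(seq(20, 30, length.out = 6), sprintf("g%02d", 1:6)),
        delta = local({
            d <- matrix(0, 6, 10,
                        dimnames = list(sprintf("g%02d", 1:6),
                                        qpcrStab:::.groupKeys(list(
                            developmental = c("ck", "15d", "30d"),
                            cold = c("ck", "4h", "8h", "12h"),
                            drought = c("ck", "5d", "10d")))))
            d["g04", c("cold:8h", "cold:12h")] <- 3
            d
        }),
        target = NULL), seed = 21)
    res <- geNorm(sim$experiment, "cold")
    expect_identical(exclusionOrder(res)[1], "g04")
})

test_that("M and V are invariant to per-sample Ct shifts", {
    ct <- randomCt(5, 12, seed = 7)
    shift <- runif(12, -2, 2)
    r1 <- geNorm(ct)
    r2 <- geNorm(sweep(ct, 2, -shift))
    expect_equal(stabilityScores(r1), stabilityScores(r2),
                 tolerance = 1e-9)
    expect_equal(vSeries(r1), vSeries(r2), tolerance = 1e-9)
})

test_that("pairwise variation flags panels that never reach the cutoff", {
    set.seed(30)
    ct <- matrix(25 + rnorm(4 * 20, sd = 1.2), 4, 20,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:20)))
    res <- geNorm(ct)
    expect_false(res@vBelowCutoff)
    expect_equal(optimalN(res), 4L)
})
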