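test_that("the index is the per-sample geometric mean of Ct", {
    expect_equal(unname(bestKeeperIndex(rbind(g1 = 20, g2 = 24))),
                 sqrt(480), tolerance = 1e-4)
    ct <- rbind(g1 = c(20, 22), g2 = c(20, 22), g3 = c(20, 22))
    colnames(ct) <- c("s1", "s2")
    expect_equal(unname(bestKeeperIndex(ct)), c(20, 22))
    expect_error(bestKeeperIndex(rbind(g1 = c(20, 21))), "at least 2")
    # samples missing any included gene are dropped
    ct[2, 2] <- NA
    expect_message(i <- bestKeeperIndex(ct), "dropped")
    expect_identical(names(i), "s1")
})

test_that("descriptive statistics and the SD > 1 boundary are exact", {
    ct <- rbind(a = c(20, 21, 22), b = c(25, 25.2, 25.4),
                c = c(30, 30.1, 30.2))
    colnames(ct) <- paste0("s", 1:3)
    bk <- bestKeeper(ct)
    tab <- resultTable(bk)
    expect_equal(unname(tab["a", "mean_ct"]), 21)
    expect_equal(unname(tab["a", "sd"]), 1)
    expect_equal(unname(tab["a", "cv_percent"]), 100 / 21, tolerance = 1e-6)
    # SD exactly 1 is NOT excluded (rule is strictly greater than one)
    expect_false(tab["a", "excluded"])
})

test_that("SD > 1 genes leave the index but stay in the ranking", {
    set.seed(41)
    ct <- rbind(a = 20 + rnorm(12, sd = .1), b = 24 + rnorm(12, sd = .15),
                c = 28 + rnorm(12, sd = .2), d = 26 + rnorm(12, sd = 2))
    colnames(ct) <- paste0("s", 1:12)
    bk <- bestKeeper(ct)
    tab <- resultTable(bk)
    expect_true(tab["d", "excluded"])
    expect_false("d" %in% bk@indexGenes)
    expect_equal(sort(unname(stabilityRanks(bk))), 1:4)
    expect_equal(unname(stabilityRanks(bk)["d"]), 4)
})

test_that("composite is the geometric mean of the three rank positions", {
    set.seed(42)
    ct <- matrix(25 + rnorm(6 * 15, sd = .4), 6, 15,
                 dimnames = list(paste0("g", 1:6), paste0("s", 1:15)))
    tab <- resultTable(bestKeeper(ct))
    expect_equal(tab$composite,
                 (tab$rank_sd * tab$rank_cv * tab$rank_r)^(1 / 3),
                 tolerance = 1e-12)
    expect_true(all(tab$composite >=
                    pmin(tab$rank_sd, tab$rank_cv, tab$rank_r) - 1e-12))
    expect_true(all(tab$composite <=
                    pmax(tab$rank_sd, tab$rank_cv, tab$rank_r) + 1e-12))
})

test_that("perfectly co-varying genes correlate 1 with the index", {
    v <- c(20, 20.5, 21, 21.5, 22)
    ct <- rbind(a = v, b = v + 2, c = v + 4)
    colnames(ct) <- paste0("s", 1:5)
    tab <- resultTable(bestKeeper(ct))
    expect_equal(unname(tab$r), rep(1, 3), tolerance = 1e-6)
})

test_that("a zero-variance gene gets the best correlation rank", {
    set.seed(43)
    ct <- rbind(a = rep(22, 10), b = 25 + rnorm(10, sd = .3),
                c = 28 + rnorm(10, sd = .3))
    colnames(ct) <- paste0("s", 1:10)
    tab <- resultTable(bestKeeper(ct))
    expect_true(is.na(tab["a", "r"]))
    expect_equal(unname(tab["a", "rank_r"]), 1)
})

test_that("shifting one gene by a constant changes neither SD nor r", {
    set.seed(44)
    ct <- matrix(24 + rnorm(5 * 12, sd = .3), 5, 12,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
    t1 <- resultTable(bestKeeper(ct))
    ct2 <- ct; ct2["g2", ] <- ct2["g2", ] + 3
    t2 <- resultTable(bestKeeper(ct2))
    expect_equal(unname(t1["g2", "sd"]), unname(t2["g2", "sd"]), tolerance = 1e-12)
    # the index itself reweights slightly when a member gene shifts, so r
    # is only near-invariant
    expect_lt(abs(unname(t1["g2", "r"]) - unname(t2["g2", "r"])), 0.1)
    expect_equal(unname(t2["g2", "mean_ct"]), unname(t1["g2", "mean_ct"]) + 3)
})
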