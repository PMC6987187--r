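test_that("the classic single-reference worked example gives RQ = 4", {
    ct <- rbind(tgt = c(26, 24), ref = c(20, 20))
    colnames(ct) <- c("ctrl", "trt")
    res <- ddctQuantify(ct, "tgt", "ref", controlGroup = "ck",
                        tissue = c("leaf", "leaf"),
                        group = c("ck", "treated"))
    tab <- resultTable(res)
    expect_equal(tab$rq_mean[tab$group == "treated"], 4)
    expect_equal(tab$rq_mean[tab$group == "ck"], 1)
})

test_that("target identical to the reference gives RQ = 1 everywhere", {
    set.seed(61)
    v <- 24 + rnorm(12, sd = 0.5)
    ct <- rbind(tgt = v, ref = v)
    colnames(ct) <- paste0("s", 1:12)
    res <- ddctQuantify(ct, "tgt", "ref", controlGroup = "ck",
                        tissue = rep(c("leaf", "root"), each = 6),
                        group = rep(c("ck", "t1", "t2"), 4))
    expect_equal(res@perSample$rq, rep(1, 12))
})

test_that("multi-reference normalization equals the mean-Ct identity", {
    # with perfect doubling, the geometric-mean NF equals using the
    # arithmetic mean of the reference Cts as one pseudo-reference
    set.seed(62)
    ct <- rbind(tgt = 24 + rnorm(8, sd = .4),
                r1 = 20 + rnorm(8, sd = .2),
                r2 = 22 + rnorm(8, sd = .2),
                r3 = 18 + rnorm(8, sd = .2))
    colnames(ct) <- paste0("s", 1:8)
    tissue <- rep("leaf", 8)
    group <- rep(c("ck", "trt"), each = 4)
    multi <- ddctQuantify(ct, "tgt", c("r1", "r2", "r3"), "ck",
                          tissue = tissue, group = group)
    pseudo <- rbind(tgt = ct["tgt", ],
                    ref = colMeans(ct[c("r1", "r2", "r3"), ]))
    single <- ddctQuantify(pseudo, "tgt", "ref", "ck",
                           tissue = tissue, group = group)
    expect_equal(multi@perSample$rq, single@perSample$rq,
                 tolerance = 1e-9)
})

test_that("control-group mean RQ is exactly 1 and shared shifts cancel", {
    set.seed(63)
    ct <- rbind(tgt = 24 + rnorm(12, sd = .3),
                r1 = 20 + rnorm(12, sd = .1),
                r2 = 21 + rnorm(12, sd = .1))
    colnames(ct) <- paste0("s", 1:12)
    tissue <- rep(c("leaf", "root"), each = 6)
    group <- rep(c("ck", "ck", "trt"), 4)
    res <- ddctQuantify(ct, "tgt", c("r1", "r2"), "ck",
                        tissue = tissue, group = group)
    per <- res@perSample
    for (t in unique(tissue))
        expect_equal(mean(per$rq[per$tissue == t & per$group == "ck"]), 1)
    # per-sample shifts shared by target and references cancel exactly
    shift <- runif(12, -2, 2)
    res2 <- ddctQuantify(sweep(ct, 2, -shift), "tgt", c("r1", "r2"),
                         "ck", tissue = tissue, group = group)
    expect_equal(res2@perSample$rq, per$rq, tolerance = 1e-9)
    # empty control errors
    expect_error(ddctQuantify(ct, "tgt", "r1", "nope",
                              tissue = tissue, group = group),
                 "empty control")
})

test_that("normalizer comparison flags a shift-biased reference", {
    set.seed(64)
    n <- 18
    group <- rep(c("ck", "c1", "c2"), each = 6)
    good1 <- 20 + rnorm(n, sd = .05)
    good2 <- 22 + rnorm(n, sd = .05)
    bad <- 21 + rnorm(n, sd = .05)
    bad[group == "c2"] <- bad[group == "c2"] + 2   # planted +2-cycle shift
    tgt <- 26 + rnorm(n, sd = .05)
    ct <- rbind(tgt = tgt, good1 = good1, good2 = good2, bad = bad)
    colnames(ct) <- paste0("s", 1:n)
    cmp <- compareNormalizers(ct, "tgt",
                              list(top = c("good1", "good2"),
                                   worst = "bad"),
                              "ck", tissue = rep("leaf", n), group = group)
    tab <- cmp$table
    rqTop <- tab$rq_mean[tab$normalizer == "top" & tab$group == "c2"]
    rqBad <- tab$rq_mean[tab$normalizer == "worst" & tab$group == "c2"]
    # a reference inflated by 2 cycles inflates apparent expression ~4x
    expect_gt(rqBad / rqTop, 3)
    expect_lt(rqBad / rqTop, 5.5)
    expect_gt(cmp$divergence$max_abs_log2, 1.5)
    # identical normalizers diverge by zero
    cmp2 <- compareNormalizers(ct, "tgt",
                               list(a = "good1", b = "good1"), "ck",
                               tissue = rep("leaf", n), group = group)
    expect_equal(cmp2$divergence$max_abs_log2, 0, tolerance = 1e-12)
})
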