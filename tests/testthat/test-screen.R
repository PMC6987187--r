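test_that("screen statistics match hand computations", {
    tpm <- rbind(flat = rep(10, 6),
                 split = c(10, 10, 50, 50, 10, 10),
                 noisy = c(8, 12, 8, 12, 8, 12))
    colnames(tpm) <- paste0("s", 1:6)
    tissue <- rep(c("leaf", "stem", "root"), each = 2)
    st <- screenStats(tpm, tissue)
    expect_equal(unname(st["flat", "mv"]), 10)
    expect_equal(unname(st["flat", "cv"]), 0)
    expect_equal(unname(st["flat", "log2fc"]), 0)
    # tissue means 10 and 50 -> log2(5)
    expect_equal(unname(st["split", "log2fc"]), log2(5), tolerance = 1e-6)
    # n-1 SD on (8,12) pattern
    one <- screenStats(rbind(g = c(8, 12)), c("leaf", "leaf"))
    expect_equal(unname(one$mv), 10)
    expect_equal(unname(one$sd), sqrt(8), tolerance = 1e-4)
    expect_equal(unname(one$cv), sqrt(8) / 10, tolerance = 1e-4)
})

test_that("two-stage thresholds assign genes as specified", {
    tpm <- rbind(flat = rep(10, 6),
                 low = rep(3, 6),
                 split = c(10, 10, 50, 50, 10, 10))
    colnames(tpm) <- paste0("s", 1:6)
    tissue <- rep(c("leaf", "stem", "root"), each = 2)
    rep1 <- screenCandidates(screenStats(tpm, tissue))
    expect_identical(stage1Candidates(rep1), "flat")
    expect_identical(stage2Candidates(rep1), "flat")
    st <- resultTable(rep1)
    expect_true(st["low", "low_expression"])
    expect_true(st["split", "high_fold_change"])

    # CV 0.4 / log2FC 0.1 / MV 100: stage 1 yes, stage 2 no
    set.seed(8)
    z <- runif(30); z <- (z - mean(z)) / sd(z)   # bounded, keeps TPM positive
    tpm2 <- rbind(mid = 100 * (1 + 0.4 * z) * rep(c(2^0.05, 1, 2^-0.05),
                                                  each = 10))
    tissue2 <- rep(c("leaf", "stem", "root"), each = 10)
    expect_warning(rep2 <- screenCandidates(screenStats(tpm2, tissue2)),
                   "no gene survives")
    expect_identical(stage1Candidates(rep2), "mid")
    expect_length(stage2Candidates(rep2), 0)

    # vacuous thresholds keep every gene
    rep3 <- screenCandidates(screenStats(tpm, tissue), minTpm = 0,
                             maxLog2fcStage1 = Inf, cvStage1 = Inf,
                             maxLog2fcStage2 = Inf, cvStage2 = Inf)
    expect_setequal(stage1Candidates(rep3), rownames(tpm))
    expect_setequal(stage2Candidates(rep3), rownames(tpm))
})

test_that("tightening thresholds never grows a stage list", {
    sim <- simulateTpm(simTpmConfig(), seed = 11)
    st <- screenStats(sim$tpm, sim$sheet$tissue)
    loose <- screenCandidates(st, minTpm = 1, cvStage1 = 0.7,
                              maxLog2fcStage1 = 3, cvStage2 = 0.4,
                              maxLog2fcStage2 = 0.3)
    for (tighter in list(
        list(minTpm = 30), list(cvStage1 = 0.2),
        list(maxLog2fcStage1 = 0.08), list(cvStage2 = 0.11),
        list(maxLog2fcStage2 = 0.06))) {
        args <- utils::modifyList(
            list(stats = st, minTpm = 1, cvStage1 = 0.7,
                 maxLog2fcStage1 = 3, cvStage2 = 0.4,
                 maxLog2fcStage2 = 0.3), tighter)
        tight <- suppressWarnings(do.call(screenCandidates, args))
        expect_true(all(stage1Candidates(tight) %in%
                        stage1Candidates(loose)))
        expect_true(all(stage2Candidates(tight) %in%
                        stage2Candidates(loose)))
    }
})

test_that("screening is scale invariant when the TPM floor is scaled", {
    sim <- simulateTpm(simTpmConfig(), seed = 12)
    st1 <- screenStats(sim$tpm, sim$sheet$tissue)
    st2 <- screenStats(sim$tpm * 7, sim$sheet$tissue)
    expect_equal(st1$cv, st2$cv)
    expect_equal(st1$log2fc, st2$log2fc)
    r1 <- suppressWarnings(screenCandidates(st1))
    r2 <- suppressWarnings(screenCandidates(st2, minTpm = 35))
    expect_identical(stage1Candidates(r1), stage1Candidates(r2))
    expect_identical(stage2Candidates(r1), stage2Candidates(r2))
})
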