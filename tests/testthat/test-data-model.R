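test_that("Ct matrix CSV round trip preserves values and missingness", {
    ct <- toyCt()
    ct["g2", "s3"] <- NA
    f <- withr::local_tempfile(fileext = ".csv")
    writeCtMatrix(ct, f)
    back <- readCtMatrix(f)
    expect_identical(dimnames(back), dimnames(ct))
    expect_equal(back, ct)
    expect_true(is.na(back["g2", "s3"]))

    # expression matrix and efficiency/sheet round trips
    tpm <- abs(ct) * 3.7
    writeExpressionMatrix(tpm, f)
    expect_equal(readExpressionMatrix(f), tpm)
    sheet <- toySheet(colnames(ct))
    writeSampleSheet(sheet, f)
    expect_identical(readSampleSheet(f), sheet)
    eff <- c(g1 = 94.1, g2 = 101.35, g3 = 107.2)
    writeEfficiencies(eff, f)
    expect_equal(readEfficiencies(f), eff)
})

test_that("Ct CSV parsing maps tokens and reports structural errors", {
    f <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("gene,s1,s2", "g1,20.1,Undetermined", "g2,,19.8"), f)
    m <- readCtMatrix(f)
    expect_true(is.na(m["g1", "s2"]) && is.na(m["g2", "s1"]))
    expect_equal(m["g1", "s1"], 20.1)

    writeLines(c("gene,s1", "g1,20", "g1,21"), f)
    expect_error(readCtMatrix(f), "duplicated gene id.*g1")
    writeLines(c("gene,s1,s2", "g1,20,oops"), f)
    expect_error(readCtMatrix(f), "gene 'g1', sample 's2'")
})

test_that("sample sheet and efficiency validation catch bad labels", {
    f <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("sample_id,tissue,subset,group,replicate",
                 "S1,leaf,cold,4h,1"), f)
    sheet <- readSampleSheet(f)
    expect_identical(sheet["S1", "subset"], "cold")
    expect_identical(sheet["S1", "group"], "4h")

    writeLines(c("sample_id,tissue,subset,group,replicate",
                 "S1,petal,cold,4h,1"), f)
    expect_error(readSampleSheet(f), "unknown tissue.*petal")

    writeLines(c("gene,efficiency_percent", "X,150"), f)
    expect_warning(e <- readEfficiencies(f), "outside \\[90, 110\\]")
    expect_equal(unname(e), 150)
})

test_that("CtExperiment validates structure and defaults efficiencies", {
    ct <- toyCt()
    sheet <- toySheet(colnames(ct))
    expect_message(
        x <- CtExperiment(ct, sheet, efficiencies = c(g1 = 94.1)),
        "defaulted to 100")
    expect_s4_class(x, "CtExperiment")
    # fold amplification per cycle: 94.1% -> 1.941, default -> 2
    expect_equal(unname(eFold(x)[c("g1", "g2")]), c(1.941, 2))
    # ceiling masking
    ct2 <- ct; ct2["g1", "s1"] <- 41
    x2 <- CtExperiment(ct2, sheet)
    expect_true(is.na(ctValues(x2)["g1", "s1"]))
    # structural errors
    expect_error(CtExperiment(ct[, 1:2], sheet[1, , drop = FALSE]),
                 "lacks sample")
    bad <- sheet; bad$subset <- "weather"
    expect_error(CtExperiment(ct, bad), "unknown subset")
})

test_that("ctDescriptives matches an interpolated-quantile oracle", {
    m <- matrix(c(20, 21, 22, 23), 1, 4,
                dimnames = list("g1", paste0("s", 1:4)))
    d <- ctDescriptives(m)
    # brute-force type-7 quantiles: sorted x, h = (n-1)p + 1
    bf <- function(x, p) {
        x <- sort(x); h <- (length(x) - 1) * p + 1
        lo <- floor(h); x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
    }
    expect_equal(d$median, unname(bf(m[1, ], .5)))
    expect_equal(d$q1, unname(bf(m[1, ], .25)))
    expect_equal(d$q3, unname(bf(m[1, ], .75)))
    expect_equal(d$iqr, d$q3 - d$q1)
    expect_identical(d$outliers, "")

    # zero-IQR case: the stray point is both outlier and extreme
    m2 <- matrix(c(20, 20, 20, 20, 40), 1, 5,
                 dimnames = list("g1", paste0("s", 1:5)))
    d2 <- ctDescriptives(m2)
    expect_identical(d2$outliers, "s5")
    expect_identical(d2$extremes, "s5")

    # constant vector
    m3 <- matrix(rep(25, 6), 1, 6, dimnames = list("g1", paste0("s", 1:6)))
    d3 <- ctDescriptives(m3)
    expect_equal(d3$iqr, 0)
    expect_equal(d3$min, d3$max)
    expect_equal(d3$min, d3$median)

    # too few values: NA quartiles with a warning
    m4 <- matrix(c(20, 21, 22), 1, 3, dimnames = list("g1", paste0("s", 1:3)))
    expect_warning(d4 <- ctDescriptives(m4), "fewer than 4")
    expect_true(is.na(d4$median))
})

test_that("ctDescriptives is invariant to sample order", {
    ct <- randomCt(4, 10, seed = 3)
    d1 <- ctDescriptives(ct)
    perm <- sample(ncol(ct))
    d2 <- ctDescriptives(ct[, perm])
    for (col in c("median", "q1", "q3", "iqr", "min", "max"))
        expect_equal(d1[[col]], d2[[col]])
})

test_that("standard-curve efficiency follows the dilution-slope formula", {
    expect_equal(efficiencyFromSlope(-1 / log10(2)), 100)
    expect_equal(efficiencyFromSlope(-3.5), 93.06977, tolerance = 1e-6)
    expect_equal(efficiencyFromSlope(-1), 900)
    expect_error(efficiencyFromSlope(3.3), "negative")
    # strictly decreasing in |slope|
    slopes <- -seq(1.5, 6, by = 0.25)
    effs <- efficiencyFromSlope(slopes)
    expect_true(all(diff(effs[order(abs(slopes))]) < 0))
})

test_that("the shipped synthetic fixture loads into a valid experiment", {
    ct <- readCtMatrix(system.file("extdata", "synthetic_ct.csv",
                                   package = "qpcrStab"))
    sheet <- readSampleSheet(system.file("extdata",
                                         "synthetic_samples.csv",
                                         package = "qpcrStab"))
    eff <- readEfficiencies(system.file("extdata",
                                        "synthetic_efficiencies.csv",
                                        package = "qpcrStab"))
    x <- CtExperiment(ct, sheet, efficiencies = eff)
    expect_identical(dim(x), c(5L, 12L))
    expect_setequal(unique(sampleInfo(x)$group), c("ck", "4h", "12h"))
})
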