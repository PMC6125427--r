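test_that("fold change follows the negative-reciprocal convention", {
    expect_equal(foldChange(20, 10), 2)
    expect_equal(foldChange(10, 20), -2)
    expect_equal(foldChange(10, 10), 1)
    expect_error(foldChange(-1, 5), "positive")

    # antisymmetry away from the ratio-1 boundary, and |FC| >= 1 always
    set.seed(31)
    a <- runif(200, 0.1, 50); b <- runif(200, 0.1, 50)
    fc <- foldChange(a, b)
    expect_true(all(abs(fc) >= 1))
    off <- a / b != 1
    expect_equal(foldChange(b, a)[off], -fc[off])
})

test_that("DE calls respect inclusive FC and strict alpha boundaries", {
    expect_equal(callDE(1.3, 0.049), "up")
    expect_equal(callDE(2.0, 0.05), "none")
    expect_equal(callDE(-1.31, 0.01), "down")
    expect_equal(callDE(-1.3, 0.049), "down")
    expect_equal(callDE(1.29, 0.001), "none")
    expect_equal(callDE(2, NA), "none")

    # monotonicity: lowering p or raising |fc| never turns DE into none
    set.seed(17)
    fc <- sample(c(runif(100, 1, 4), -runif(100, 1, 4)))
    p <- runif(200)
    d1 <- callDE(fc, p)
    d2 <- callDE(fc * ifelse(fc > 0, 1.5, 1.5), p / 2)
    expect_true(all(!(d1 != "none" & d2 == "none")))
})

test_that("vectorised t-tests agree with stats::t.test", {
    set.seed(23)
    d <- twoGroupDesign(4, 5)
    tr <- allNullTruth(40, seed = 23)
    x <- simulateExpression(tr, d, seed = 23)
    v <- exprValues(x)
    grp <- sampleGroups(x)
    for (variant in c("welch", "pooled")) {
        r <- compareGroups(x, "g2", "g1", testVariant = variant)
        expected <- apply(v, 1, function(row)
            t.test(row[grp == "g2"], row[grp == "g1"],
                   var.equal = (variant == "pooled"))$p.value)
        expect_equal(unname(pValues(r)), unname(expected),
                     tolerance = 1e-12)
    }
    # log2-scale option
    r <- compareGroups(x, "g2", "g1", testScale = "log2")
    expected <- apply(log2(v), 1, function(row)
        t.test(row[grp == "g2"], row[grp == "g1"])$p.value)
    expect_equal(unname(pValues(r)), unname(expected), tolerance = 1e-12)
    # orientation flips the FC sign but not the p-value
    r2 <- compareGroups(x, "g1", "g2")
    r1 <- compareGroups(x, "g2", "g1")
    expect_equal(unname(foldChanges(r2)), unname(-foldChanges(r1)))
    expect_equal(unname(pValues(r2)), unname(pValues(r1)))
})

test_that("degenerate inputs are handled deterministically", {
    d <- twoGroupDesign(3, 3)
    v <- rbind(PS_1 = c(10, 10, 10, 40, 40, 40),   # zero var, clear shift
               PS_2 = c(10, 10, 10, 10, 10, 10))   # zero var, no shift
    colnames(v) <- paste0("s", 1:6)
    x <- GravityExperiment(v, d,
        setNames(rep(c("g1", "g2"), each = 3), colnames(v)))
    expect_warning(r <- compareGroups(x, "g2", "g1"), "undefined")
    expect_equal(unname(foldChanges(r)[1]), 4)
    expect_equal(unname(directions(r)[1]), "up")
    expect_true(is.na(pValues(r)[2]))
    expect_equal(unname(directions(r)[2]), "none")
    expect_error(compareGroups(x, "g2", "nope"), "unknown group")
})

test_that("group size below two is rejected", {
    d <- twoGroupDesign(1, 5)
    v <- matrix(runif(12, 1, 2), 2,
                dimnames = list(c("a", "b"), paste0("s", 1:6)))
    x <- GravityExperiment(v, d,
        setNames(c("g1", rep("g2", 5)), colnames(v)))
    expect_error(compareGroups(x, "g2", "g1"), "at least 2 samples")
})

test_that("DE counting equals a brute-force re-count", {
    set.seed(41)
    ids <- sprintf("PS_%03d", 1:150)
    dirs <- randomDirections(ids)
    r <- makeResult(dirs)
    ann <- data.frame(probeset_id = ids,
        gene_symbol = ifelse(runif(150) < 0.8, toupper(ids), NA),
        stringsAsFactors = FALSE)
    got <- countDE(r, ann)
    annotated <- setNames(!is.na(ann$gene_symbol), ids)
    expect_equal(unname(got["upAll"]), sum(dirs == "up"))
    expect_equal(unname(got["downAll"]), sum(dirs == "down"))
    expect_equal(unname(got["upAnnot"]),
                 sum(dirs == "up" & annotated[names(dirs)]))
    expect_equal(unname(got["downAnnot"]),
                 sum(dirs == "down" & annotated[names(dirs)]))
    expect_error(countDE(r, ann[-1, ]), "missing from annotation")
})

test_that("null simulation keeps the t-test near its nominal level", {
    # one large two-group null comparison at the study's group sizes
    d <- twoGroupDesign(6, 8)
    tr <- allNullTruth(5000, seed = 3)
    x <- simulateExpression(tr, d, seed = 3)
    # pooled t on the log2 (normal) scale is the exactly calibrated
    # configuration under the log-normal generator
    rp <- compareGroups(x, "g2", "g1", testVariant = "pooled",
                        testScale = "log2")
    expect_gt(mean(pValues(rp) < 0.05), 0.04)
    expect_lt(mean(pValues(rp) < 0.05), 0.06)
    # the Welch default is slightly conservative at n = 6/8: close to, but
    # never above, the nominal level
    r <- compareGroups(x, "g2", "g1")
    rate <- mean(pValues(r) < 0.05)
    expect_gt(rate, 0.03)
    expect_lt(rate, 0.055)
    # the FC gate can only reduce the call rate
    expect_lte(mean(directions(r) != "none"), rate)
})
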