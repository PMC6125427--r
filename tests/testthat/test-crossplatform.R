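test_that("double-sensitive pairing equals brute-force intersection", {
    a <- makeSet(setNames(c("up", "down", "none"), c("A", "B", "C")))
    b <- makeSet(setNames(c("down", "none", "up"), c("A", "B", "C")))
    pairs <- doubleSensitive(a, b)
    expect_equal(pairs$transcript_id, "A")
    expect_false(pairs$concordant)

    empty <- doubleSensitive(
        makeSet(setNames(c("up", "none"), c("A", "B"))),
        makeSet(setNames(c("none", "down"), c("A", "B"))))
    expect_equal(nrow(empty), 0)

    set.seed(67)
    for (i in 1:40) {
        ids <- sprintf("PS_%03d", seq_len(sample(20:100, 1)))
        da <- randomDirections(ids); db <- randomDirections(ids)
        pairs <- doubleSensitive(makeSet(da), makeSet(db))
        expect_setequal(pairs$transcript_id, bfDoubleSensitive(da, db))
        expect_lte(nrow(pairs),
                   min(sum(da != "none"), sum(db != "none")))
        cc <- concordanceCounts(pairs)
        expect_equal(cc, bfConcordance(da, db, pairs$transcript_id))
        expect_equal(sum(cc), nrow(pairs))
    }
    expect_error(doubleSensitive(a, makeSet(setNames("up", "Z"))),
                 "universe")
})

test_that("adaptation classification is total over the nine direction pairs", {
    combos <- expand.grid(early = c("up", "down", "none"),
                          late = c("up", "down", "none"),
                          stringsAsFactors = FALSE)
    got <- classifyAdaptation(combos$early, combos$late)
    want <- mapply(bfClassify, combos$early, combos$late)
    expect_equal(got, unname(want))
    expect_setequal(unique(got),
        c("continuous", "adapted", "late_response", "no_response"))
    # worked examples
    expect_equal(classifyAdaptation("up", "up"), "continuous")
    expect_equal(classifyAdaptation("up", "none"), "adapted")
    expect_equal(classifyAdaptation("up", "down"), "adapted")
    expect_equal(classifyAdaptation("none", "down"), "late_response")
    expect_equal(classifyAdaptation("none", "none"), "no_response")
})

test_that("adaptation summary partitions the universe and reports percent", {
    universe <- sprintf("PS_%d", 1:10)
    early <- makeSet(setNames(c("up", "up", "down"), c("PS_1", "PS_2",
        "PS_3")), universe = universe)
    late <- makeSet(setNames("up", "PS_1"), universe = universe)
    s <- adaptationSummary(early, late, universe)
    expect_equal(unname(s$counts["continuous"]), 1L)
    expect_equal(unname(s$counts["adapted"]), 2L)
    expect_equal(unname(s$counts["no_response"]), 7L)
    expect_equal(sum(s$counts), length(universe))
    expect_equal(s$adaptationPct, 66.67)

    none <- makeSet(setNames(character(), character()),
                    universe = universe)
    s0 <- adaptationSummary(none, none, universe)
    expect_equal(unname(s0$counts["no_response"]), 10L)
    expect_true(is.na(s0$adaptationPct))

    expect_error(adaptationSummary(early, late, universe[-1]),
                 "does not cover")

    # invariance under relabeling of transcript IDs
    relabel <- setNames(sprintf("Q_%d", 10:1), universe)
    re <- function(gs) {
        rownames(gs@members) <- unname(relabel[rownames(gs@members)])
        gs@universe <- unname(relabel[gs@universe])
        gs
    }
    s2 <- adaptationSummary(re(early), re(late), unname(relabel[universe]))
    expect_equal(s2$counts, s$counts)
    expect_equal(s2$adaptationPct, s$adaptationPct)
})

test_that("planted time-course classes are classified correctly", {
    tr <- generateTruth(600, classProportions =
        c(null = 0.5, micro_sensitive_adapting = 0.3,
          micro_sensitive_continuous = 0.1, late_responder = 0.1),
        effectFoldRange = c(2.5, 3), seed = 83)
    nm <- noiseModel(residualLog2SD = 0.15)
    early <- simulateExpression(tr, loadDesign("PFC"), nm, seed = 83)
    late <- simulateExpression(tr, loadDesign("TEXUS"), nm, seed = 84)
    eSet <- exclusionFilter(compareGroups(early, "mug", "bl"),
        compareGroups(early, "bl", "gc"), "same_direction")
    lSet <- exclusionFilter(compareGroups(late, "mug", "bl"),
        compareGroups(late, "bl", "gc"), "same_direction")
    s <- adaptationSummary(eSet, lSet, rownames(truthTable(tr)))
    cat <- setNames(s$records$category, s$records$transcript_id)
    planted <- truthExpectedSets(tr)
    expect_gt(mean(cat[planted$micro_sensitive_adapting] == "adapted"),
              0.85)
    expect_gt(mean(cat[planted$micro_sensitive_continuous] ==
                   "continuous"), 0.85)
    expect_gt(mean(cat[planted$late_responder] == "late_response"), 0.85)
})
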