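test_that("exclusion filter reproduces the direction truth table", {
    # all nine (experimental, control) direction pairs, both modes
    ids <- sprintf("PS_%d", 1:9)
    pairs <- expand.grid(e = c("up", "down", "none"),
                         c = c("up", "down", "none"),
                         stringsAsFactors = FALSE)
    expDirs <- setNames(pairs$e, ids)
    ctlDirs <- setNames(pairs$c, ids)
    for (mode in c("same_direction", "any_direction")) {
        got <- exclusionFilter(makeResult(expDirs), makeResult(ctlDirs),
                               mode)
        expect_setequal(setTranscripts(got),
                        bfExclusion(expDirs, ctlDirs, mode))
    }
    # worked examples
    e <- setNames(c("up", "down"), c("A", "B"))
    cSame <- setNames(c("up", "none"), c("A", "B"))
    expect_setequal(setTranscripts(exclusionFilter(makeResult(e),
        makeResult(cSame), "same_direction")), "B")
    cOpp <- setNames(c("down", "none"), c("A", "B"))
    expect_setequal(setTranscripts(exclusionFilter(makeResult(e),
        makeResult(cOpp), "any_direction")), "B")
    expect_setequal(setTranscripts(exclusionFilter(makeResult(e),
        makeResult(cOpp), "same_direction")), c("A", "B"))

    expect_error(exclusionFilter(makeResult(e),
        makeResult(setNames("up", "Z")), "same_direction"),
        "universe")
})

test_that("filter output is a subset and any-direction is the stricter mode", {
    set.seed(53)
    for (i in 1:25) {
        ids <- sprintf("PS_%03d", seq_len(sample(20:120, 1)))
        e <- makeResult(randomDirections(ids))
        c <- makeResult(randomDirections(ids))
        any <- setTranscripts(exclusionFilter(e, c, "any_direction"))
        same <- setTranscripts(exclusionFilter(e, c, "same_direction"))
        expect_true(all(any %in% deTranscripts(e)))
        expect_true(all(any %in% same))
    }
})

test_that("platform set builders match brute-force rule transcription", {
    set.seed(59)
    for (i in 1:40) {
        ids <- sprintf("PS_%03d", seq_len(sample(20:150, 1)))
        blGc <- randomDirections(ids); blIf <- randomDirections(ids)
        ifGc <- randomDirections(ids); mugBl <- randomDirections(ids)
        got <- pfcGravisets(list(
            bl_vs_gc = makeResult(blGc), bl_vs_if = makeResult(blIf),
            if_vs_gc = makeResult(ifGc), mug_vs_bl = makeResult(mugBl)))
        want <- bfPfcSets(blGc, blIf, ifGc, mugBl)
        for (nm in names(want))
            expect_setequal(setTranscripts(got[[nm]]), want[[nm]])

        gotT <- texusGravisets(list(bl_vs_gc = makeResult(blGc),
                                    mug_vs_bl = makeResult(mugBl)))
        wantT <- bfTexusSets(blGc, mugBl)
        for (nm in names(wantT))
            expect_setequal(setTranscripts(gotT[[nm]]), wantT[[nm]])
    }
    expect_error(pfcGravisets(list()), "missing comparison")
    expect_error(texusGravisets(list(bl_vs_gc = makeResult(
        setNames("up", "A")))), "missing comparison")
})

test_that("SKF attribution partitions candidates by direction agreement", {
    # worked examples: same direction = enhanced, opposite = attenuated,
    # a ground-control drug response disqualifies
    micro <- setNames(c("up", "up", "up", "down"), c("A", "B", "C", "D"))
    skf <- setNames(c("up", "down", "up", "up"), c("A", "B", "C", "D"))
    gcskf <- setNames(c("none", "none", "up", "none"),
                      c("A", "B", "C", "D"))
    got <- skfAttribution(makeSet(micro), makeResult(skf),
                          makeResult(gcskf))
    expect_setequal(setTranscripts(got$enhanced), "A")
    expect_setequal(setTranscripts(got$attenuated), c("B", "D"))

    set.seed(61)
    for (i in 1:40) {
        ids <- sprintf("PS_%03d", seq_len(sample(20:150, 1)))
        micro <- randomDirections(ids)
        skf <- randomDirections(ids)
        gcskf <- randomDirections(ids, pDE = 0.3)
        got <- skfAttribution(makeSet(micro), makeResult(skf),
                              makeResult(gcskf))
        want <- bfSkf(micro, skf, gcskf)
        expect_setequal(setTranscripts(got$enhanced), want$enhanced)
        expect_setequal(setTranscripts(got$attenuated), want$attenuated)
        expect_length(intersect(setTranscripts(got$enhanced),
                                setTranscripts(got$attenuated)), 0)
    }
})

test_that("graviset summaries report counts and FC extremes per direction", {
    gs <- makeSet(setNames(c("up", "up", "down"), c("A", "B", "C")))
    gs@members$fcPrimary <- c(2.0, 1.4, -1.6)
    s <- summarizeGraviset(gs)
    expect_equal(s$nUp, 2); expect_equal(s$nDown, 1)
    expect_equal(s$nTotal, 3)
    expect_equal(s$avgFcUp, 1.7)
    expect_equal(s$maxFc, 2.0)
    expect_equal(s$minFc, -1.6)

    empty <- makeSet(setNames(character(), character()),
                     universe = c("A", "B"))
    s0 <- summarizeGraviset(empty)
    expect_equal(s0$nTotal, 0)
    expect_true(is.na(s0$avgFcUp))

    # direction counts of the packaged continuous-response table
    t9 <- loadPrintedTable("table9")
    fc <- t9$fc_mug_vs_bl_tx_hyp_g
    gs9 <- new("GraviSet", name = "t9", ruleText = "", fcCutoff = 1.3,
        members = S4Vectors::DataFrame(
            direction = ifelse(fc > 0, "up", "down"), fcPrimary = fc,
            row.names = t9$probeset_id),
        universe = t9$probeset_id)
    s9 <- summarizeGraviset(gs9)
    expect_equal(s9$nUp, 5)
    expect_equal(s9$nDown, 4)
})

test_that("planted truth flows into the correct gravisets at low noise", {
    tr <- generateTruth(800, classProportions =
        c(null = 0.8, micro_sensitive_continuous = 0.1,
          hyper_sensitive_continuous = 0.1),
        effectFoldRange = c(2.5, 3), seed = 71)
    x <- simulateExpression(tr, loadDesign("TEXUS"),
        noiseModel(residualLog2SD = 0.15), seed = 71)
    res <- list(mug_vs_bl = compareGroups(x, "mug", "bl"),
                bl_vs_gc = compareGroups(x, "bl", "gc"))
    sets <- texusGravisets(res)
    planted <- truthExpectedSets(tr)
    expect_gt(mean(planted$micro_sensitive_continuous %in%
                   setTranscripts(sets$micro_bl_controlled)), 0.9)
    expect_gt(mean(planted$hyper_sensitive_continuous %in%
                   setTranscripts(sets$hyper_sensitive)), 0.9)
    # hyper-planted transcripts enter the micro set only counter-directed:
    # microgravity vs the shifted baseline reads as the opposite direction,
    # so the same-direction baseline exclusion retains them
    hyperInMicro <- intersect(planted$hyper_sensitive_continuous,
                              setTranscripts(sets$micro_bl_controlled))
    if (length(hyperInMicro)) {
        plantedDir <- setNames(truthTable(tr)$direction,
                               rownames(truthTable(tr)))
        microDir <- setMembers(sets$micro_bl_controlled)[hyperInMicro,
                                                         "direction"]
        expect_true(all(microDir != plantedDir[hyperInMicro]))
    }
})
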