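# Independent brute-force oracles for the set logic, written as plain
# per-transcript loops with explicit case enumeration so they share no code
# with the vectorised implementations they check.

# Build a ComparisonResult directly from a direction vector (named by
# transcript). DE members get |fc| = 2, non-DE fc = +1.1; p-values 0.01 / 0.5.
makeResult <- function(dirs, name = "cmp", fcCutoff = 1.3) {
    fc <- ifelse(dirs == "up", 2, ifelse(dirs == "down", -2, 1.1))
    p <- ifelse(dirs == "none", 0.5, 0.01)
    new("ComparisonResult", comparison = name, numerator = "a",
        denominator = "b",
        thresholds = deThresholds(fcCutoff = fcCutoff),
        testVariant = "welch", testScale = "linear",
        results = S4Vectors::DataFrame(
            meanNum = rep(1, length(dirs)), meanDen = rep(1, length(dirs)),
            ratio = abs(fc), fc = fc, p = p,
            padj = p, direction = unname(dirs),
            row.names = names(dirs)))
}

randomDirections <- function(ids, pDE = 0.5) {
    stats::setNames(
        sample(c("up", "down", "none"), length(ids), replace = TRUE,
               prob = c(pDE / 2, pDE / 2, 1 - pDE)),
        ids)
}

# Exclusion filter: explicit 3x3 truth table over (experimental, control)
# directions; returns the retained transcript IDs.
bfExclusion <- function(expDirs, ctlDirs, mode) {
    keep <- character()
    for (id in names(expDirs)) {
        e <- expDirs[[id]]; c <- ctlDirs[[id]]
        if (e == "none") next
        retained <- if (mode == "any_direction") {
            c == "none"
        } else {
            !(e == "up" && c == "up") && !(e == "down" && c == "down")
        }
        if (retained) keep <- c(keep, id)
    }
    keep
}

# Four parabolic-flight sets by direct rule transcription.
bfPfcSets <- function(blGc, blIf, ifGc, mugBl) {
    ids <- names(blGc)
    set1 <- ids[blGc != "none"]
    set2 <- bfExclusion(blIf, ifGc, "any_direction")
    set3 <- bfExclusion(mugBl, blGc, "same_direction")
    set4 <- character()
    for (id in ids) {
        if (mugBl[[id]] == "none") next
        if (ifGc[[id]] != "none") next
        if (mugBl[[id]] == blIf[[id]]) next
        set4 <- c(set4, id)
    }
    list(hyper_texus_analogous = set1, hyper_if_controlled = set2,
         micro_bl_controlled = set3, micro_bl_and_if_controlled = set4)
}

bfTexusSets <- function(blGc, mugBl) {
    list(hyper_sensitive = names(blGc)[blGc != "none"],
         micro_bl_controlled = bfExclusion(mugBl, blGc, "same_direction"))
}

# SKF attribution by per-member enumeration.
bfSkf <- function(microDirs, skfDirs, gcSkfDirs) {
    enhanced <- character(); attenuated <- character()
    for (id in names(microDirs)) {
        m <- microDirs[[id]]
        if (m == "none") next
        s <- skfDirs[[id]]
        if (s == "none") next
        if (gcSkfDirs[[id]] != "none") next
        if (s == m) enhanced <- c(enhanced, id)
        else attenuated <- c(attenuated, id)
    }
    list(enhanced = enhanced, attenuated = attenuated)
}

# Intersection with direction bookkeeping, by loop.
bfDoubleSensitive <- function(dirsA, dirsB) {
    out <- character()
    for (id in names(dirsA))
        if (dirsA[[id]] != "none" && dirsB[[id]] != "none")
            out <- c(out, id)
    out
}

bfConcordance <- function(dirsA, dirsB, ids) {
    same <- 0L; opp <- 0L
    for (id in ids) {
        if (dirsA[[id]] == dirsB[[id]]) same <- same + 1L
        else opp <- opp + 1L
    }
    c(nSame = same, nOpposite = opp)
}

# Adaptation category by explicit enumeration of the nine pairs.
bfClassify <- function(early, late) {
    if (early == "none" && late == "none") return("no_response")
    if (early == "none") return("late_response")
    if (early == late) return("continuous")
    "adapted"
}
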