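# Shared simulation shortcuts for the tests.

twoGroupDesign <- function(n1 = 6, n2 = 8) {
    loadDesign("custom",
        groups = data.frame(group = c("g1", "g2"), n = c(n1, n2)),
        comparisons = data.frame(name = "g2_vs_g1",
                                 numerator = "g2", denominator = "g1"))
}

allNullTruth <- function(n, seed = 1) {
    generateTruth(n, classProportions = c(null = 1), seed = seed)
}

# A GraviSet built directly from a direction vector over a universe.
makeSet <- function(dirs, universe = names(dirs), name = "set") {
    de <- dirs != "none"
    new("GraviSet", name = name, ruleText = "test set", fcCutoff = 1.3,
        members = S4Vectors::DataFrame(
            direction = unname(dirs[de]),
            fcPrimary = ifelse(dirs[de] == "up", 2, -2),
            row.names = names(dirs)[de]),
        universe = universe)
}
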