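#' Build a GraviSet from the DE transcripts of one comparison
#'
#' @param result a \linkS4class{ComparisonResult}.
#' @param name set identifier.
#' @param ruleText optional rule description.
#' @return a \linkS4class{GraviSet} whose members are all DE transcripts of
#'   \code{result}, with direction and fold change frozen from it.
#' @export
deGraviSet <- function(result, name, ruleText = NULL) {
    r <- result@results
    de <- r$direction != "none"
    if (is.null(ruleText))
        ruleText <- paste0("differentially expressed in ",
                           result@comparison)
    new("GraviSet", name = name, ruleText = ruleText,
        fcCutoff = result@thresholds@fcCutoff,
        members = S4Vectors::DataFrame(
            direction = r$direction[de], fcPrimary = r$fc[de],
            row.names = rownames(r)[de]),
        universe = rownames(r))
}

#' Control-comparison exclusion filter
#'
#' Keeps the transcripts differentially expressed in the experimental
#' comparison after removing those also differentially expressed in the
#' control comparison — in either direction (\code{"any_direction"}) or only
#' in the same direction as in the experimental comparison
#' (\code{"same_direction"}). This is the rule behind the control-filtered
#' gravisensitive sets: a response also present in the control contrast
#' cannot be attributed to the gravity condition (any-direction reading) or
#' may be a protracted effect of the preceding phase (same-direction
#' reading).
#'
#' @param experimental,control \linkS4class{ComparisonResult}s over the same
#'   transcript universe.
#' @param mode \code{"same_direction"} or \code{"any_direction"}.
#' @param name set identifier.
#' @param ruleText optional rule description.
#' @return a \linkS4class{GraviSet}; members carry direction and fold change
#'   from the experimental comparison.
#' @export
exclusionFilter <- function(experimental, control,
                            mode = c("same_direction", "any_direction"),
                            name = "filtered", ruleText = NULL) {
    mode <- match.arg(mode)
    stopIfNotSameUniverse(rownames(experimental@results),
                          rownames(control@results),
                          "experimental and control comparisons")
    if (is.null(ruleText))
        ruleText <- paste0("DE in ", experimental@comparison,
            ", but not DE ",
            if (mode == "same_direction") "in the same direction " else "",
            "in ", control@comparison)
    gs <- deGraviSet(experimental, name, ruleText)
    excludeByControl(gs, control, mode)
}

# Remove from a GraviSet the members DE in `control` (any direction, or the
# member's own direction).
excludeByControl <- function(gs, control, mode) {
    m <- gs@members
    if (!nrow(m)) return(gs)
    ctl <- stats::setNames(control@results$direction,
                           rownames(control@results))[rownames(m)]
    drop <- if (mode == "any_direction") ctl != "none"
            else ctl == m$direction
    gs@members <- m[!drop, , drop = FALSE]
    gs
}

#' Gravisensitive transcript sets for the parabolic-flight platform
#'
#' Builds the four control-filtered sets of the early (20 s) platform:
#' \describe{
#'   \item{hyper_texus_analogous}{DE in hypergravity baseline vs ground
#'     control, no filter (the construction analogous to the rocket
#'     platform's hypergravity set).}
#'   \item{hyper_if_controlled}{DE in hypergravity baseline vs the 1 g
#'     in-flight control, excluding transcripts DE (either direction) in
#'     in-flight vs ground control — removes flight-condition effects.}
#'   \item{micro_bl_controlled}{DE in microgravity vs hypergravity baseline,
#'     excluding transcripts DE in the same direction in baseline vs ground
#'     control — removes protracted hypergravity effects.}
#'   \item{micro_bl_and_if_controlled}{DE in microgravity vs baseline,
#'     excluding transcripts DE (either direction) in in-flight vs ground
#'     control and transcripts DE in the same direction in baseline vs
#'     in-flight.}
#' }
#'
#' @param results named list of \linkS4class{ComparisonResult}s containing
#'   at least \code{bl_vs_gc}, \code{bl_vs_if}, \code{if_vs_gc},
#'   \code{mug_vs_bl}.
#' @return named list of \linkS4class{GraviSet}s.
#' @export
pfcGravisets <- function(results) {
    need <- c("bl_vs_gc", "bl_vs_if", "if_vs_gc", "mug_vs_bl")
    missing <- setdiff(need, names(results))
    if (length(missing))
        stop("missing comparison(s): ", paste(missing, collapse = ", "))
    set1 <- deGraviSet(results$bl_vs_gc, "hyper_texus_analogous",
        "DE in BL-PFC hyp-g vs H/W 1 g GC")
    set2 <- exclusionFilter(results$bl_vs_if, results$if_vs_gc,
        "any_direction", "hyper_if_controlled",
        "DE in BL-PFC hyp-g vs 1 g IF, but not DE in 1 g IF vs H/W 1 g GC")
    set3 <- exclusionFilter(results$mug_vs_bl, results$bl_vs_gc,
        "same_direction", "micro_bl_controlled",
        paste("DE in \u00b5g vs BL-PFC hyp-g, but not DE in the same",
              "direction in BL-PFC hyp-g vs H/W 1 g GC"))
    set4 <- exclusionFilter(results$mug_vs_bl, results$if_vs_gc,
        "any_direction", "micro_bl_and_if_controlled",
        paste("DE in \u00b5g vs BL-PFC hyp-g, but not DE in 1 g IF vs",
              "H/W 1 g GC or in the same direction in BL-PFC hyp-g vs",
              "1 g IF"))
    set4 <- excludeByControl(set4, results$bl_vs_if, "same_direction")
    list(hyper_texus_analogous = set1, hyper_if_controlled = set2,
         micro_bl_controlled = set3, micro_bl_and_if_controlled = set4)
}

#' Gravisensitive transcript sets for the rocket platform
#'
#' Builds the two sets of the late (75/300 s) platform: the hypergravity-
#' sensitive set (DE in launch baseline vs ground control, no filter) and
#' the baseline-controlled microgravity-sensitive set (DE in microgravity vs
#' baseline, excluding same-direction baseline-vs-ground-control responses).
#'
#' @param results named list of \linkS4class{ComparisonResult}s containing
#'   \code{mug_vs_bl} and \code{bl_vs_gc}.
#' @return named list of \linkS4class{GraviSet}s.
#' @export
texusGravisets <- function(results) {
    need <- c("mug_vs_bl", "bl_vs_gc")
    missing <- setdiff(need, names(results))
    if (length(missing))
        stop("missing comparison(s): ", paste(missing, collapse = ", "))
    list(
        hyper_sensitive = deGraviSet(results$bl_vs_gc, "hyper_sensitive",
            "DE in BL-TX hyp-g vs H/W 1 g GC"),
        micro_bl_controlled = exclusionFilter(results$mug_vs_bl,
            results$bl_vs_gc, "same_direction", "micro_bl_controlled",
            paste("DE in \u00b5g vs BL-TX hyp-g, but not DE in the same",
                  "direction in BL-TX hyp-g vs H/W 1 g GC")))
}

#' Attribute microgravity responses to SKF-96365-sensitive ion channels
#'
#' Splits the members of a baseline-controlled microgravity-sensitive set by
#' the effect of the cation-channel inhibitor SKF-96365: candidates are the
#' members that are DE in the inhibitor-vs-untreated microgravity comparison
#' and \emph{not} DE (either direction) in the inhibitor-vs-untreated ground
#' control comparison (which would mark a gravity-independent drug effect).
#' Candidates whose inhibitor-comparison direction equals their microgravity
#' direction are classed \code{enhanced}, those with opposite direction
#' \code{attenuated}; the two sets partition the candidates.
#'
#' @param microSet a \linkS4class{GraviSet} (microgravity-sensitive,
#'   baseline-controlled).
#' @param skfVsMicro \linkS4class{ComparisonResult} for microgravity + SKF
#'   vs microgravity.
#' @param skfGcVsGc \linkS4class{ComparisonResult} for ground control + SKF
#'   vs ground control.
#' @return list of two \linkS4class{GraviSet}s, \code{enhanced} and
#'   \code{attenuated}; member direction/fold change are frozen from the
#'   defining microgravity comparison.
#' @export
skfAttribution <- function(microSet, skfVsMicro, skfGcVsGc) {
    stopIfNotSameUniverse(microSet@universe, rownames(skfVsMicro@results),
                          "microgravity set and SKF comparison")
    stopIfNotSameUniverse(rownames(skfVsMicro@results),
                          rownames(skfGcVsGc@results),
                          "SKF comparisons")
    m <- microSet@members
    skfDir <- stats::setNames(skfVsMicro@results$direction,
                              rownames(skfVsMicro@results))[rownames(m)]
    gcDir <- stats::setNames(skfGcVsGc@results$direction,
                             rownames(skfGcVsGc@results))[rownames(m)]
    candidate <- skfDir != "none" & gcDir == "none"
    enhanced <- candidate & skfDir == m$direction
    attenuated <- candidate & skfDir != m$direction
    mk <- function(keep, label, how) new("GraviSet",
        name = paste0("skf_", label),
        ruleText = paste0(microSet@name, ", DE in \u00b5g SKF vs \u00b5g in ",
            how, " direction, not DE in H/W 1 g GC SKF vs H/W 1 g GC"),
        fcCutoff = microSet@fcCutoff,
        members = m[keep, , drop = FALSE],
        universe = microSet@universe)
    list(enhanced = mk(enhanced, "enhanced", "the same"),
         attenuated = mk(attenuated, "attenuated", "the opposite"))
}

#' Summarise a GraviSet
#'
#' Counts and fold-change summaries per direction, mirroring the published
#' set-summary layout: number up/down/total, mean FC among up- and
#' down-regulated members, and the extreme FCs (most positive among up, most
#' negative among down). With an annotation, annotated counts are added.
#' Fields of an empty direction are NA.
#'
#' @param gs a \linkS4class{GraviSet}.
#' @param annotation optional annotation data.frame.
#' @return one-row data.frame.
#' @export
summarizeGraviset <- function(gs, annotation = NULL) {
    m <- gs@members
    up <- m$fcPrimary[m$direction == "up"]
    dn <- m$fcPrimary[m$direction == "down"]
    out <- data.frame(
        name = gs@name,
        nUp = length(up), nDown = length(dn), nTotal = nrow(m),
        avgFcUp = if (length(up)) mean(up) else NA_real_,
        avgFcDown = if (length(dn)) mean(dn) else NA_real_,
        maxFc = if (length(up)) max(up) else NA_real_,
        minFc = if (length(dn)) min(dn) else NA_real_,
        stringsAsFactors = FALSE)
    if (!is.null(annotation)) {
        sym <- stats::setNames(annotation$gene_symbol,
                               annotation$probeset_id)
        annot <- !is.na(sym[rownames(m)])
        out$nUpAnnot <- sum(annot & m$direction == "up")
        out$nDownAnnot <- sum(annot & m$direction == "down")
        out$nTotalAnnot <- sum(annot)
    }
    out
}

#' @describeIn deGraviSet member table (rownames = transcript IDs, columns
#'   \code{direction}, \code{fcPrimary}) as a data.frame.
#' @param gs a \linkS4class{GraviSet}.
#' @export
setMembers <- function(gs) as.data.frame(gs@members)

#' @describeIn deGraviSet member transcript IDs.
#' @export
setTranscripts <- function(gs) rownames(gs@members)

#' @describeIn deGraviSet set identifier.
#' @export
setName <- function(gs) gs@name

#' @describeIn deGraviSet transcript universe the rule was evaluated over.
#' @export
setUniverse <- function(gs) gs@universe

setMethod("length", "GraviSet", function(x) nrow(x@members))

setMethod("show", "GraviSet", function(object) {
    m <- object@members
    cat(sprintf("GraviSet '%s': %d members (%d up, %d down) of %d transcripts\n",
        object@name, nrow(m), sum(m$direction == "up"),
        sum(m$direction == "down"), length(object@universe)))
    cat("  rule:", object@ruleText, "\n")
})
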