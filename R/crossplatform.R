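#' Transcripts sensitive in two gravisensitive sets
#'
#' Intersects two \linkS4class{GraviSet}s (matched by probeset ID) and
#' returns one direction pair per shared transcript, carrying each set's
#' frozen direction and fold change and whether they agree. Used both
#' within a platform (hypergravity vs microgravity double-sensitive
#' transcripts) and across platforms (same gravity condition at the early
#' and late time point).
#'
#' @param setA,setB \linkS4class{GraviSet}s over the same transcript
#'   universe.
#' @return data.frame with columns \code{transcript_id}, \code{dirA},
#'   \code{fcA}, \code{dirB}, \code{fcB}, \code{concordant}.
#' @export
doubleSensitive <- function(setA, setB) {
    stopIfNotSameUniverse(setA@universe, setB@universe, "gravisets")
    shared <- intersect(rownames(setA@members), rownames(setB@members))
    a <- setA@members[shared, , drop = FALSE]
    b <- setB@members[shared, , drop = FALSE]
    data.frame(
        transcript_id = shared,
        dirA = a$direction, fcA = a$fcPrimary,
        dirB = b$direction, fcB = b$fcPrimary,
        concordant = a$direction == b$direction,
        stringsAsFactors = FALSE)
}

#' Count concordant and discordant direction pairs
#'
#' @param pairs data.frame of direction pairs from
#'   \code{\link{doubleSensitive}} (or any data.frame with a logical
#'   \code{concordant} column).
#' @return named integer vector \code{nSame}, \code{nOpposite}.
#' @examples
#' t8 <- loadPrintedTable("table8")
#' concordanceCounts(fcDirectionPairs(t8, "fc_mug_vs_bl_pfc_hyp_g",
#'                                    "fc_mug_vs_bl_tx_hyp_g"))
#' @export
concordanceCounts <- function(pairs) {
    c(nSame = sum(pairs$concordant),
      nOpposite = sum(!pairs$concordant))
}

#' Direction pairs from two signed fold-change columns
#'
#' Convenience constructor turning two signed FC columns of a reference
#' table into direction pairs (positive FC = up, negative = down).
#'
#' @param tab data.frame containing \code{probeset_id} and the two columns.
#' @param colA,colB column names of the signed fold changes.
#' @return data.frame as returned by \code{\link{doubleSensitive}}.
#' @export
fcDirectionPairs <- function(tab, colA, colB) {
    fcA <- tab[[colA]]; fcB <- tab[[colB]]
    data.frame(
        transcript_id = tab$probeset_id,
        dirA = ifelse(fcA > 0, "up", "down"), fcA = fcA,
        dirB = ifelse(fcB > 0, "up", "down"), fcB = fcB,
        concordant = sign(fcA) == sign(fcB),
        stringsAsFactors = FALSE)
}

#' Classify the time course of one transcript
#'
#' Maps the pair of DE directions at the early and late time point of a
#' gravity condition to one of four categories:
#' \describe{
#'   \item{continuous}{DE in the same direction at both time points.}
#'   \item{adapted}{DE early, and late either not DE (disappearance) or DE
#'     in the opposite direction (counter-regulation).}
#'   \item{late_response}{not DE early, DE late.}
#'   \item{no_response}{not DE at either time point.}
#' }
#' Total and deterministic over all nine direction pairs; vectorised.
#'
#' @param early,late directions in \code{"up"}, \code{"down"}, \code{"none"}.
#' @return character vector of categories.
#' @examples
#' classifyAdaptation("up", "up")    # continuous
#' classifyAdaptation("up", "none")  # adapted
#' classifyAdaptation("up", "down")  # adapted
#' classifyAdaptation("none", "down")# late_response
#' @export
classifyAdaptation <- function(early, late) {
    stopifnot(all(early %in% c("up", "down", "none")),
              all(late %in% c("up", "down", "none")))
    ifelse(early == "none" & late == "none", "no_response",
    ifelse(early == "none", "late_response",
    ifelse(early == late, "continuous", "adapted")))
}

#' Adaptation summary over a transcript universe
#'
#' Classifies every transcript of a universe by its membership directions in
#' the early-time and late-time gravisensitive set of a matched gravity
#' condition (microgravity: 20 s vs 300 s; hypergravity: 20 s vs 75 s) and
#' tabulates the four categories. The adaptation percentage is
#' 100 x adapted / (adapted + continuous) — the share of initially altered
#' transcripts that no longer respond, or respond oppositely, at the late
#' time point — reported half-even to \code{decimals} decimals.
#'
#' @param earlySet,lateSet \linkS4class{GraviSet}s for the early and late
#'   time point.
#' @param universe character vector of transcript IDs to classify (e.g. all
#'   annotated transcripts); must cover both sets' members.
#' @param decimals decimals for the adaptation percentage (default 2).
#' @return list with \code{records} (data.frame transcript_id, early_dir,
#'   late_dir, category), \code{counts} (named integer vector over the four
#'   categories, partitioning the universe) and \code{adaptationPct}.
#' @export
adaptationSummary <- function(earlySet, lateSet, universe, decimals = 2) {
    uncovered <- c(setdiff(rownames(earlySet@members), universe),
                   setdiff(rownames(lateSet@members), universe))
    if (length(uncovered))
        stop("universe does not cover set member(s): ",
             paste(utils::head(uncovered, 5), collapse = ", "))
    dirOf <- function(gs) {
        d <- rep("none", length(universe))
        idx <- match(rownames(gs@members), universe)
        d[idx] <- gs@members$direction
        d
    }
    early <- dirOf(earlySet)
    late <- dirOf(lateSet)
    category <- classifyAdaptation(early, late)
    counts <- vapply(c("no_response", "continuous", "adapted",
                       "late_response"),
                     function(k) sum(category == k), integer(1))
    adapted <- counts[["adapted"]]
    continuous <- counts[["continuous"]]
    pct <- if (adapted + continuous > 0)
        percentage(adapted, adapted + continuous, decimals) else NA_real_
    list(records = data.frame(transcript_id = universe,
                              early_dir = early, late_dir = late,
                              category = category,
                              stringsAsFactors = FALSE),
         counts = counts, adaptationPct = pct)
}
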