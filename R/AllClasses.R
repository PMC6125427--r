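#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' StudyDesign: experiment groups and pre-registered comparisons
#'
#' A \code{StudyDesign} records the sample groups of one flight platform
#' (group slug, display name, number of samples, condition label and exposure
#' time in seconds) together with the pre-registered group-vs-group
#' comparisons evaluated on that platform. Group names used programmatically
#' are ASCII slugs (e.g. \code{"mug"} for the microgravity group); the
#' original display names (e.g. \code{"µg"}) are retained alongside.
#'
#' @slot platform single string, platform identifier (\code{"PFC"},
#'   \code{"TEXUS"}, or a custom identifier for user-supplied designs).
#' @slot timePoint \code{"early"} or \code{"late"}: whether this platform
#'   samples the early (~20 s) or late (75--300 s) exposure window of the
#'   two-platform time course.
#' @slot groups data.frame with columns \code{group}, \code{displayName},
#'   \code{n}, \code{conditionLabel}, \code{exposureSeconds}.
#' @slot comparisons data.frame with columns \code{name}, \code{numerator},
#'   \code{denominator} (group slugs).
#'
#' @seealso \code{\link{loadDesign}}
#' @exportClass StudyDesign
setClass("StudyDesign",
    representation(
        platform = "character",
        timePoint = "character",
        groups = "data.frame",
        comparisons = "data.frame"
    )
)

setValidity("StudyDesign", function(object) {
    g <- object@groups
    cmp <- object@comparisons
    msg <- character()
    need <- c("group", "displayName", "n", "conditionLabel", "exposureSeconds")
    if (!all(need %in% names(g)))
        return(paste("groups must have columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(g$group))
        msg <- c(msg, "duplicated group names")
    if (any(g$n < 1) || any(g$n != as.integer(g$n)))
        msg <- c(msg, "group sizes must be positive integers")
    if (any(g$exposureSeconds < 0))
        msg <- c(msg, "exposure times must be nonnegative")
    if (length(object@timePoint) != 1L ||
        !object@timePoint %in% c("early", "late"))
        msg <- c(msg, "timePoint must be 'early' or 'late'")
    if (nrow(cmp)) {
        if (!all(c("name", "numerator", "denominator") %in% names(cmp)))
            return("comparisons must have columns name, numerator, denominator")
        if (anyDuplicated(cmp$name))
            msg <- c(msg, "duplicated comparison names")
        bad <- !(cmp$numerator %in% g$group) | !(cmp$denominator %in% g$group)
        if (any(bad))
            msg <- c(msg, paste("comparison references unknown group:",
                paste(cmp$name[bad], collapse = ", ")))
        if (any(cmp$numerator == cmp$denominator))
            msg <- c(msg, "comparison must reference two distinct groups")
    }
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' GravityExperiment: linear-scale expression with a group mapping
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding one assay
#' \code{"exprs"} of strictly positive, linear-scale expression values
#' (transcripts x samples), a \code{group} column in \code{colData} mapping
#' every sample to a group of the attached \linkS4class{StudyDesign}, and an
#' optional \code{geneSymbol} column in \code{rowData} (NA = unannotated
#' probeset).
#'
#' @slot design the \linkS4class{StudyDesign} the samples belong to.
#' @exportClass GravityExperiment
setClass("GravityExperiment",
    contains = "SummarizedExperiment",
    representation(design = "StudyDesign")
)

setValidity("GravityExperiment", function(object) {
    msg <- character()
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        return("assay 'exprs' is required")
    v <- SummarizedExperiment::assay(object, "exprs")
    if (anyNA(v) || any(v <= 0))
        msg <- c(msg, "expression values must be strictly positive and non-NA")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "transcript IDs must be present and unique")
    cd <- SummarizedExperiment::colData(object)
    if (!"group" %in% names(cd)) {
        msg <- c(msg, "colData must contain a 'group' column")
    } else {
        unknown <- setdiff(unique(cd$group), object@design@groups$group)
        if (length(unknown))
            msg <- c(msg, paste("samples mapped to groups absent from the",
                "design:", paste(unknown, collapse = ", ")))
    }
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' DEThresholds: differential-expression calling thresholds
#'
#' The two thresholds defining a differential-expression call: a signed
#' fold-change cutoff (inclusive, default 1.3) and a t-test significance
#' level (strict, default 0.05). A transcript is DE iff
#' \code{fc >= +fcCutoff} or \code{fc <= -fcCutoff}, and \code{p < alpha}.
#'
#' @slot fcCutoff numeric > 1.
#' @slot alpha numeric in (0, 1).
#' @seealso \code{\link{deThresholds}}, \code{\link{callDE}}
#' @exportClass DEThresholds
setClass("DEThresholds",
    representation(fcCutoff = "numeric", alpha = "numeric")
)

setValidity("DEThresholds", function(object) {
    if (length(object@fcCutoff) != 1L || !is.finite(object@fcCutoff) ||
        object@fcCutoff <= 1)
        return("fcCutoff must be a single number > 1")
    if (length(object@alpha) != 1L || !is.finite(object@alpha) ||
        object@alpha <= 0 || object@alpha >= 1)
        return("alpha must lie strictly between 0 and 1")
    TRUE
})

#' ComparisonResult: per-transcript fold changes and DE calls for one contrast
#'
#' Result of \code{\link{compareGroups}} for one numerator-vs-denominator
#' contrast: per transcript the linear-scale group means, their ratio, the
#' signed fold change (negative-reciprocal convention, so |fc| >= 1 always),
#' the two-sided two-sample t-test p-value (NA where undefined), an
#' informational Benjamini-Hochberg adjusted p-value (never used in calls),
#' and the DE direction in \code{"up"}, \code{"down"}, \code{"none"}.
#'
#' @slot comparison comparison name.
#' @slot numerator,denominator group slugs.
#' @slot thresholds the \linkS4class{DEThresholds} used for calling.
#' @slot testVariant \code{"welch"} or \code{"pooled"}.
#' @slot testScale \code{"linear"} or \code{"log2"}.
#' @slot results \link[S4Vectors]{DataFrame} with rownames = transcript IDs
#'   and columns \code{meanNum}, \code{meanDen}, \code{ratio}, \code{fc},
#'   \code{p}, \code{padj}, \code{direction}.
#' @exportClass ComparisonResult
setClass("ComparisonResult",
    representation(
        comparison = "character",
        numerator = "character",
        denominator = "character",
        thresholds = "DEThresholds",
        testVariant = "character",
        testScale = "character",
        results = "DataFrame"
    )
)

setValidity("ComparisonResult", function(object) {
    r <- object@results
    need <- c("meanNum", "meanDen", "ratio", "fc", "p", "padj", "direction")
    if (!all(need %in% names(r)))
        return(paste("results must have columns:", paste(need, collapse = ", ")))
    msg <- character()
    if (is.null(rownames(r)) || anyDuplicated(rownames(r)))
        msg <- c(msg, "results rownames must be unique transcript IDs")
    if (nrow(r)) {
        if (any(abs(r$fc) < 1, na.rm = TRUE))
            msg <- c(msg, "|fc| must never lie below 1")
        if (!all(r$direction %in% c("up", "down", "none")))
            msg <- c(msg, "direction must be up/down/none")
        de <- r$direction != "none"
        if (any(de & sign(r$fc) != ifelse(r$direction == "up", 1, -1)))
            msg <- c(msg, "direction must match sign(fc) for DE transcripts")
    }
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' GraviSet: a rule-derived, directed transcript set
#'
#' A named set of transcripts produced by a differential-expression rule with
#' optional control-comparison exclusion (e.g. "microgravity-sensitive,
#' BL-controlled"). Each member carries the frozen direction and signed fold
#' change from the set's defining comparison; downstream analyses never
#' re-derive them. The full transcript universe the rule was evaluated over
#' is retained so set algebra can be checked for compatibility.
#'
#' @slot name set identifier.
#' @slot ruleText human-readable statement of the construction rule.
#' @slot fcCutoff fold-change cutoff the members satisfied.
#' @slot members \link[S4Vectors]{DataFrame}, rownames = transcript IDs,
#'   columns \code{direction} and \code{fcPrimary}.
#' @slot universe character vector of all transcript IDs the rule saw.
#' @exportClass GraviSet
setClass("GraviSet",
    representation(
        name = "character",
        ruleText = "character",
        fcCutoff = "numeric",
        members = "DataFrame",
        universe = "character"
    )
)

setValidity("GraviSet", function(object) {
    m <- object@members
    if (!all(c("direction", "fcPrimary") %in% names(m)))
        return("members must have columns direction, fcPrimary")
    msg <- character()
    if (nrow(m)) {
        if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
            msg <- c(msg, "member transcript IDs must be unique")
        if (!all(rownames(m) %in% object@universe))
            msg <- c(msg, "members outside the declared universe")
        if (!all(m$direction %in% c("up", "down")))
            msg <- c(msg, "member direction must be up or down")
        if (any(abs(m$fcPrimary) < object@fcCutoff))
            msg <- c(msg, "every member must satisfy |fcPrimary| >= fcCutoff")
        if (any(sign(m$fcPrimary) != ifelse(m$direction == "up", 1, -1)))
            msg <- c(msg, "member direction must match sign(fcPrimary)")
    }
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' NoiseModel: log-normal measurement-noise parameters for the simulator
#'
#' Parameters of the simulator's log-normal noise model: per-transcript
#' baseline log2 abundance drawn from
#' Normal(\code{baselineLog2Mean}, \code{baselineLog2SD}) and per-sample
#' residual measurement noise Normal(0, \code{residualLog2SD}) added on the
#' log2 scale.
#'
#' @slot baselineLog2Mean,baselineLog2SD,residualLog2SD single numerics;
#'   both SDs strictly positive.
#' @seealso \code{\link{noiseModel}}, \code{\link{simulateExpression}}
#' @exportClass NoiseModel
setClass("NoiseModel",
    representation(
        baselineLog2Mean = "numeric",
        baselineLog2SD = "numeric",
        residualLog2SD = "numeric"
    )
)

setValidity("NoiseModel", function(object) {
    if (object@baselineLog2SD <= 0 || object@residualLog2SD <= 0)
        return("standard deviations must be > 0")
    TRUE
})

#' TruthAssignment: planted per-transcript regulation classes
#'
#' Ground truth for simulated expression matrices: per transcript a
#' regulation class, a direction (\code{"up"}/\code{"down"}, NA for class
#' \code{"null"}), a multiplicative effect size (>= 1), and an annotation
#' flag. Serves as the oracle for recovery tests of the downstream set logic.
#'
#' @slot table \link[S4Vectors]{DataFrame} with rownames = transcript IDs and
#'   columns \code{class}, \code{direction}, \code{effectFold},
#'   \code{annotated}.
#' @seealso \code{\link{generateTruth}}, \code{\link{truthExpectedSets}}
#' @exportClass TruthAssignment
setClass("TruthAssignment", representation(table = "DataFrame"))

setValidity("TruthAssignment", function(object) {
    t <- object@table
    need <- c("class", "direction", "effectFold", "annotated")
    if (!all(need %in% names(t)))
        return(paste("table must have columns:", paste(need, collapse = ", ")))
    msg <- character()
    if (is.null(rownames(t)) || anyDuplicated(rownames(t)))
        msg <- c(msg, "transcript IDs must be unique")
    if (!all(t$class %in% truthClassLabels()))
        msg <- c(msg, "unknown class label")
    isNull <- t$class == "null"
    if (any(!is.na(t$direction[isNull])))
        msg <- c(msg, "null transcripts must have NA direction")
    if (any(is.na(t$direction[!isNull])) ||
        !all(t$direction[!isNull] %in% c("up", "down")))
        msg <- c(msg, "planted transcripts need direction up/down")
    if (any(t$effectFold < 1))
        msg <- c(msg, "effectFold must be >= 1")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})
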