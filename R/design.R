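#' Load a platform's experimental design
#'
#' Returns the \linkS4class{StudyDesign} of one of the two built-in flight
#' platforms, or a fully user-specified design. The built-in designs encode
#' the study groups and sizes of the two campaigns:
#' \describe{
#'   \item{\code{"PFC"}}{parabolic flight, 28 samples in four groups:
#'     hardware 1 g ground control (\code{gc}, n = 6), 1 g in-flight control
#'     (\code{if_1g}, n = 8), 1.8 g hypergravity baseline (\code{bl}, n = 6,
#'     20 s) and microgravity (\code{mug}, n = 8, 20 s).}
#'   \item{\code{"TEXUS"}}{suborbital rocket, 26 samples in five groups:
#'     \code{gc} (n = 6), hypergravity launch baseline \code{bl} (n = 5,
#'     75 s), microgravity \code{mug} (n = 7, 300 s), microgravity with the
#'     cation-channel inhibitor SKF-96365 \code{mug_skf} (n = 4) and ground
#'     control with inhibitor \code{gc_skf} (n = 4).}
#' }
#' Each design carries its pre-registered group-vs-group comparisons (six per
#' platform). Group names used in code are ASCII slugs; display names (with
#' spaces and the micro sign) are retained in the \code{displayName} column.
#'
#' @param platform \code{"PFC"}, \code{"TEXUS"}, or any identifier when
#'   \code{groups} and \code{comparisons} are fully supplied.
#' @param groups optional data.frame overriding the built-in groups; columns
#'   \code{group}, \code{displayName}, \code{n}, \code{conditionLabel},
#'   \code{exposureSeconds} (missing display/label columns are filled from
#'   the slug).
#' @param comparisons optional data.frame with columns \code{name},
#'   \code{numerator}, \code{denominator}.
#' @param timePoint optional override of the platform's position in the
#'   two-platform time course (\code{"early"} = ~20 s exposures,
#'   \code{"late"} = 75--300 s).
#' @return a validated \linkS4class{StudyDesign}.
#' @examples
#' pfc <- loadDesign("PFC")
#' sum(designGroups(pfc)$n)   # 28 samples
#' designComparisons(loadDesign("TEXUS"))
#' @export
loadDesign <- function(platform, groups = NULL, comparisons = NULL,
                       timePoint = NULL) {
    builtin <- builtinDesigns()
    if (is.null(groups)) {
        if (!platform %in% names(builtin))
            stop("unknown platform '", platform,
                 "' and no group overrides supplied; built-in platforms: ",
                 paste(names(builtin), collapse = ", "))
        d <- builtin[[platform]]
        g <- d$groups
        cmp <- if (is.null(comparisons)) d$comparisons else comparisons
        tp <- if (is.null(timePoint)) d$timePoint else timePoint
    } else {
        g <- as.data.frame(groups, stringsAsFactors = FALSE)
        if (is.null(g$displayName)) g$displayName <- g$group
        if (is.null(g$conditionLabel)) g$conditionLabel <- g$group
        if (is.null(g$exposureSeconds)) g$exposureSeconds <- 0
        if (is.null(comparisons))
            stop("custom designs must supply comparisons")
        cmp <- as.data.frame(comparisons, stringsAsFactors = FALSE)
        tp <- if (is.null(timePoint)) "early" else timePoint
    }
    new("StudyDesign", platform = platform, timePoint = tp,
        groups = g, comparisons = cmp)
}

builtinDesigns <- function() {
    pfcGroups <- data.frame(
        group = c("gc", "if_1g", "bl", "mug"),
        displayName = c("H/W 1 g GC", "1 g IF", "BL-PFC hyp-g", "\u00b5g"),
        n = c(6L, 8L, 6L, 8L),
        conditionLabel = c("hardware 1 g ground control",
                           "1 g in-flight control",
                           "hypergravity 1.8 g baseline",
                           "microgravity"),
        exposureSeconds = c(0, 0, 20, 20),
        stringsAsFactors = FALSE)
    pfcComparisons <- data.frame(
        name = c("if_vs_gc", "bl_vs_if", "mug_vs_bl",
                 "mug_vs_if", "bl_vs_gc", "mug_vs_gc"),
        numerator = c("if_1g", "bl", "mug", "mug", "bl", "mug"),
        denominator = c("gc", "if_1g", "bl", "if_1g", "gc", "gc"),
        stringsAsFactors = FALSE)
    texusGroups <- data.frame(
        group = c("gc", "bl", "mug", "mug_skf", "gc_skf"),
        displayName = c("H/W 1 g GC", "BL-TX hyp-g", "\u00b5g",
                        "\u00b5g SKF", "H/W 1 g GC SKF"),
        n = c(6L, 5L, 7L, 4L, 4L),
        conditionLabel = c("hardware 1 g ground control",
                           "hypergravity launch baseline (max 13.5 g)",
                           "microgravity",
                           "microgravity + SKF-96365",
                           "hardware 1 g ground control + SKF-96365"),
        exposureSeconds = c(0, 75, 300, 300, 0),
        stringsAsFactors = FALSE)
    texusComparisons <- data.frame(
        name = c("mug_vs_bl", "bl_vs_gc", "mug_vs_gc",
                 "gcskf_vs_gc", "mugskf_vs_gcskf", "mugskf_vs_mug"),
        numerator = c("mug", "bl", "mug", "gc_skf", "mug_skf", "mug_skf"),
        denominator = c("bl", "gc", "gc", "gc", "gc_skf", "mug"),
        stringsAsFactors = FALSE)
    list(
        PFC = list(groups = pfcGroups, comparisons = pfcComparisons,
                   timePoint = "early"),
        TEXUS = list(groups = texusGroups, comparisons = texusComparisons,
                     timePoint = "late")
    )
}

#' @describeIn loadDesign group table of a design.
#' @param design a \linkS4class{StudyDesign}.
#' @export
designGroups <- function(design) design@groups

#' @describeIn loadDesign comparison table of a design.
#' @export
designComparisons <- function(design) design@comparisons

#' @describeIn loadDesign platform identifier of a design.
#' @export
designPlatform <- function(design) design@platform

setMethod("show", "StudyDesign", function(object) {
    cat("StudyDesign:", object@platform,
        sprintf("(%s time point)\n", object@timePoint))
    cat(sprintf("  %d groups, %d samples total\n",
        nrow(object@groups), sum(object@groups$n)))
    for (i in seq_len(nrow(object@groups)))
        cat(sprintf("    %-8s %-16s n=%d\n", object@groups$group[i],
            object@groups$displayName[i], object@groups$n[i]))
    cat(sprintf("  %d pre-registered comparisons: %s\n",
        nrow(object@comparisons),
        paste(object@comparisons$name, collapse = ", ")))
})
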