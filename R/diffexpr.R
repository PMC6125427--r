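#' Signed fold change with the negative-reciprocal convention
#'
#' The fold change between two positive group means is their ratio when the
#' ratio is >= 1 and the negative reciprocal of the ratio when it is < 1, so
#' a halving is reported as -2 rather than 0.5 and |FC| is always >= 1. A
#' ratio of exactly 1 maps to +1.
#'
#' @param meanNum,meanDen positive numerics (vectorised), the average linear
#'   expression of the numerator and denominator group.
#' @return signed fold change(s).
#' @examples
#' foldChange(20, 10)   # +2
#' foldChange(10, 20)   # -2
#' foldChange(10, 10)   # +1
#' @export
foldChange <- function(meanNum, meanDen) {
    if (any(meanNum <= 0, na.rm = TRUE) || any(meanDen <= 0, na.rm = TRUE))
        stop("group means must be strictly positive")
    ratio <- meanNum / meanDen
    ifelse(ratio >= 1, ratio, -1 / ratio)
}

#' Construct DE-calling thresholds
#'
#' @param fcCutoff inclusive signed fold-change cutoff (> 1), default 1.3.
#' @param alpha strict t-test significance level, default 0.05.
#' @return a \linkS4class{DEThresholds}.
#' @export
deThresholds <- function(fcCutoff = 1.3, alpha = 0.05) {
    new("DEThresholds", fcCutoff = fcCutoff, alpha = alpha)
}

#' Call differential expression from fold change and p-value
#'
#' A transcript is called \code{"up"} iff \code{fc >= +fcCutoff} and
#' \code{p < alpha}, \code{"down"} iff \code{fc <= -fcCutoff} and
#' \code{p < alpha}, otherwise \code{"none"}. The fold-change boundary is
#' inclusive, the significance boundary strict; an undefined (NA) p-value
#' yields \code{"none"}.
#'
#' @param fc signed fold change(s), |fc| >= 1.
#' @param p p-value(s) in [0, 1] or NA.
#' @param thresholds a \linkS4class{DEThresholds}.
#' @return character vector in \code{"up"}, \code{"down"}, \code{"none"}.
#' @examples
#' callDE(1.3, 0.049)  # "up": boundary fold change is inclusive
#' callDE(2.0, 0.05)   # "none": alpha is strict
#' @export
callDE <- function(fc, p, thresholds = deThresholds()) {
    sig <- !is.na(p) & p < thresholds@alpha
    ifelse(sig & fc >= thresholds@fcCutoff, "up",
        ifelse(sig & fc <= -thresholds@fcCutoff, "down", "none"))
}

#' Compare two groups transcript-wise
#'
#' For every transcript: the linear-scale mean of each group, their ratio,
#' the signed fold change (\code{\link{foldChange}}), a two-sided two-sample
#' t-test p-value, an informational Benjamini-Hochberg adjusted p-value
#' (never used for calling, mirroring the original uncorrected procedure),
#' and the DE direction per \code{\link{callDE}}.
#'
#' The t-test is Welch (unequal variance) by default with a pooled-variance
#' option, and is computed on the linear-scale values by default (option:
#' log2-transformed values); fold changes are always linear-scale ratios.
#' Transcripts whose p-value is undefined (zero variance in both groups and
#' equal means) are called \code{"none"} and counted in a single warning.
#'
#' @param x a \linkS4class{GravityExperiment}.
#' @param numGroup,denGroup group slugs or display names; each group needs
#'   >= 2 samples.
#' @param thresholds a \linkS4class{DEThresholds}.
#' @param testVariant \code{"welch"} (default) or \code{"pooled"}.
#' @param testScale \code{"linear"} (default) or \code{"log2"}.
#' @param name comparison name; defaults to \code{"<num>_vs_<den>"}.
#' @return a \linkS4class{ComparisonResult}.
#' @export
compareGroups <- function(x, numGroup, denGroup,
                          thresholds = deThresholds(),
                          testVariant = c("welch", "pooled"),
                          testScale = c("linear", "log2"),
                          name = NULL) {
    testVariant <- match.arg(testVariant)
    testScale <- match.arg(testScale)
    numGroup <- resolveGroup(expDesign(x), numGroup)
    denGroup <- resolveGroup(expDesign(x), denGroup)
    grp <- sampleGroups(x)
    v <- exprValues(x)
    a <- v[, grp == numGroup, drop = FALSE]
    b <- v[, grp == denGroup, drop = FALSE]
    if (ncol(a) < 2 || ncol(b) < 2)
        stop("each group needs at least 2 samples (",
             numGroup, ": ", ncol(a), ", ", denGroup, ": ", ncol(b), ")")

    meanNum <- rowMeans(a)
    meanDen <- rowMeans(b)
    ratio <- meanNum / meanDen
    fc <- foldChange(meanNum, meanDen)

    ta <- if (testScale == "log2") log2(a) else a
    tb <- if (testScale == "log2") log2(b) else b
    p <- rowTTest(ta, tb, testVariant)

    nUndef <- sum(is.na(p))
    if (nUndef > 0)
        warning(nUndef, " transcript(s) with undefined t-test p-value ",
                "(zero variance in both groups, equal means); called 'none'")

    direction <- callDE(fc, p, thresholds)
    res <- S4Vectors::DataFrame(
        meanNum = meanNum, meanDen = meanDen, ratio = ratio, fc = fc,
        p = p, padj = stats::p.adjust(p, method = "BH"),
        direction = direction, row.names = rownames(v))
    if (is.null(name)) name <- paste0(numGroup, "_vs_", denGroup)
    new("ComparisonResult", comparison = name, numerator = numGroup,
        denominator = denGroup, thresholds = thresholds,
        testVariant = testVariant, testScale = testScale, results = res)
}

# Vectorised two-sided two-sample t-test over matrix rows.
# Returns NA where the statistic is undefined (zero pooled SE and zero mean
# difference); a nonzero difference with zero SE gives p = 0.
rowTTest <- function(a, b, variant) {
    n1 <- ncol(a); n2 <- ncol(b)
    m1 <- rowMeans(a); m2 <- rowMeans(b)
    v1 <- rowSums((a - m1)^2) / (n1 - 1)
    v2 <- rowSums((b - m2)^2) / (n2 - 1)
    if (variant == "welch") {
        se2 <- v1 / n1 + v2 / n2
        df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    } else {
        sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
        se2 <- sp2 * (1 / n1 + 1 / n2)
        df <- rep(n1 + n2 - 2, length(se2))
    }
    diff <- m1 - m2
    p <- rep(NA_real_, length(diff))
    zeroSE <- se2 == 0
    p[zeroSE & diff != 0] <- 0
    ok <- !zeroSE
    tt <- diff[ok] / sqrt(se2[ok])
    p[ok] <- 2 * stats::pt(-abs(tt), df[ok])
    p
}

#' Count DE transcripts by direction, overall and annotated
#'
#' @param result a \linkS4class{ComparisonResult}.
#' @param annotation annotation data.frame (\code{probeset_id},
#'   \code{gene_symbol}, NA = unannotated) covering every transcript in the
#'   result.
#' @return named integer vector \code{upAll}, \code{downAll}, \code{upAnnot},
#'   \code{downAnnot}.
#' @export
countDE <- function(result, annotation) {
    r <- result@results
    sym <- stats::setNames(annotation$gene_symbol, annotation$probeset_id)
    missing <- setdiff(rownames(r), annotation$probeset_id)
    if (length(missing))
        stop("transcripts missing from annotation: ",
             paste(utils::head(missing, 5), collapse = ", "),
             if (length(missing) > 5) ", ...")
    annot <- !is.na(sym[rownames(r)])
    c(upAll = sum(r$direction == "up"),
      downAll = sum(r$direction == "down"),
      upAnnot = sum(r$direction == "up" & annot),
      downAnnot = sum(r$direction == "down" & annot))
}

#' @describeIn compareGroups per-transcript result table as a data.frame.
#' @param result a \linkS4class{ComparisonResult}.
#' @export
resultsTable <- function(result) as.data.frame(result@results)

#' @describeIn compareGroups named vector of signed fold changes.
#' @export
foldChanges <- function(result) {
    stats::setNames(result@results$fc, rownames(result@results))
}

#' @describeIn compareGroups named vector of p-values.
#' @export
pValues <- function(result) {
    stats::setNames(result@results$p, rownames(result@results))
}

#' @describeIn compareGroups named vector of DE directions.
#' @export
directions <- function(result) {
    stats::setNames(result@results$direction, rownames(result@results))
}

#' @describeIn compareGroups IDs of DE transcripts (direction != "none").
#' @export
deTranscripts <- function(result) {
    rownames(result@results)[result@results$direction != "none"]
}

setMethod("show", "ComparisonResult", function(object) {
    r <- object@results
    cat(sprintf("ComparisonResult '%s' (%s vs %s): %d transcripts\n",
        object@comparison, object@numerator, object@denominator, nrow(r)))
    cat(sprintf("  %s t-test on %s scale; |FC| >= %g, p < %g\n",
        object@testVariant, object@testScale,
        object@thresholds@fcCutoff, object@thresholds@alpha))
    cat(sprintf("  DE: %d up, %d down\n",
        sum(r$direction == "up"), sum(r$direction == "down")))
})
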