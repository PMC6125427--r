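#' Planted regulation classes
#'
#' Class labels recognised by the simulator:
#' \describe{
#'   \item{null}{no planted effect.}
#'   \item{flight_responsive}{shifted in every in-flight group (in-flight 1 g
#'     control, hypergravity baseline, microgravity, and microgravity + SKF),
#'     i.e. responds to flight conditions rather than to gravity; the
#'     control-filtered set logic should exclude these.}
#'   \item{hyper_sensitive_adapting}{shifted in the hypergravity baseline
#'     group at the early time point; at the late time point the effect
#'     vanishes or reverses (see \code{lateMode}).}
#'   \item{hyper_sensitive_continuous}{shifted in the hypergravity baseline
#'     group at both time points, same direction.}
#'   \item{micro_sensitive_adapting}{shifted in the microgravity group(s)
#'     relative to baseline at the early time point; vanishes or reverses
#'     late.}
#'   \item{micro_sensitive_continuous}{microgravity shift in the same
#'     direction at both time points.}
#'   \item{late_responder}{microgravity shift only at the late time point.}
#'   \item{skf_enhanced}{microgravity-sensitive (continuous), and the
#'     SKF-96365-treated microgravity group is shifted further in the same
#'     direction, while ground control + SKF stays unshifted.}
#'   \item{skf_attenuated}{microgravity-sensitive (continuous), but SKF
#'     reverses the microgravity shift; ground control + SKF unshifted.}
#' }
#' @return character vector of class labels.
#' @export
truthClassLabels <- function() {
    c("null", "flight_responsive",
      "hyper_sensitive_adapting", "hyper_sensitive_continuous",
      "micro_sensitive_adapting", "micro_sensitive_continuous",
      "late_responder", "skf_enhanced", "skf_attenuated")
}

#' Default planted class proportions
#'
#' Proportions chosen to mirror the relative pool sizes observed on this
#' array platform: roughly a quarter of annotated transcripts respond to
#' hypergravity at the early time point (nearly all adapting), a few percent
#' to microgravity (again nearly all adapting), about one in ten responds to
#' flight conditions alone, a sizeable late-responder pool, and a small
#' minority of the microgravity responders is sensitive to the
#' cation-channel inhibitor SKF-96365.
#'
#' @return named numeric vector summing to 1.
#' @export
defaultClassProportions <- function() {
    c(null = 0.527,
      flight_responsive = 0.09,
      hyper_sensitive_adapting = 0.22,
      hyper_sensitive_continuous = 0.003,
      micro_sensitive_adapting = 0.035,
      micro_sensitive_continuous = 0.002,
      late_responder = 0.12,
      skf_enhanced = 0.0005,
      skf_attenuated = 0.0025)
}

#' Construct a noise model
#'
#' @param baselineLog2Mean mean log2 abundance of transcripts (default 8).
#' @param baselineLog2SD SD of per-transcript baseline log2 abundance
#'   (default 2).
#' @param residualLog2SD per-sample measurement noise SD on the log2 scale
#'   (default 0.25).
#' @return a \linkS4class{NoiseModel}.
#' @export
noiseModel <- function(baselineLog2Mean = 8, baselineLog2SD = 2,
                       residualLog2SD = 0.25) {
    new("NoiseModel", baselineLog2Mean = baselineLog2Mean,
        baselineLog2SD = baselineLog2SD, residualLog2SD = residualLog2SD)
}

#' Generate planted per-transcript ground truth
#'
#' Allocates regulation classes to transcripts by largest-remainder
#' apportionment (every class count is within one of
#' \code{nTranscripts * proportion}), shuffles the allocation with the seed,
#' draws an up/down direction for every planted transcript, a multiplicative
#' effect size uniform in \code{effectFoldRange}, and marks a
#' largest-remainder share of transcripts as annotated. Deterministic for a
#' fixed seed.
#'
#' @param nTranscripts number of transcripts.
#' @param fractionAnnotated proportion of transcripts carrying a gene symbol
#'   (default 42947/45034, the annotated share of the full array).
#' @param classProportions named numeric vector over
#'   \code{\link{truthClassLabels}} summing to 1.
#' @param effectFoldRange length-2 numeric, lower bound >= 1.
#' @param seed integer seed.
#' @return a \linkS4class{TruthAssignment}.
#' @examples
#' tr <- generateTruth(1000, classProportions = c(null = 0.9,
#'     micro_sensitive_adapting = 0.1), seed = 7)
#' table(truthTable(tr)$class)
#' @export
generateTruth <- function(nTranscripts,
                          fractionAnnotated = 42947 / 45034,
                          classProportions = defaultClassProportions(),
                          effectFoldRange = c(1.4, 2.5),
                          seed = 1L) {
    stopifnot(nTranscripts >= 1)
    p <- classProportions
    if (is.null(names(p)) || !all(names(p) %in% truthClassLabels()))
        stop("classProportions must be named with known class labels")
    if (abs(sum(p) - 1) > 1e-9)
        stop("class proportions must sum to 1 (got ", sum(p), ")")
    if (any(p < 0)) stop("class proportions must be nonnegative")
    if (effectFoldRange[1] < 1)
        stop("effect fold range must start at >= 1")
    counts <- largestRemainder(nTranscripts * p)
    labels <- rep(names(p), counts)

    ids <- sprintf("PS_%06d", seq_len(nTranscripts))
    set.seed(deriveSeed(seed, "truth"))
    labels <- sample(labels)
    planted <- labels != "null"

    set.seed(deriveSeed(seed, "direction"))
    direction <- rep(NA_character_, nTranscripts)
    direction[planted] <- sample(c("up", "down"), sum(planted),
                                 replace = TRUE)
    set.seed(deriveSeed(seed, "effect"))
    effectFold <- rep(1, nTranscripts)
    effectFold[planted] <- stats::runif(sum(planted),
        effectFoldRange[1], effectFoldRange[2])

    set.seed(deriveSeed(seed, "annotation"))
    nAnnot <- largestRemainder(c(nTranscripts * fractionAnnotated,
        nTranscripts * (1 - fractionAnnotated)))[1]
    annotated <- rep(FALSE, nTranscripts)
    annotated[sample.int(nTranscripts, nAnnot)] <- TRUE

    new("TruthAssignment", table = S4Vectors::DataFrame(
        class = labels, direction = direction, effectFold = effectFold,
        annotated = annotated, row.names = ids))
}

# Largest-remainder (Hamilton) apportionment of real-valued targets to
# integer counts preserving the total.
largestRemainder <- function(targets) {
    n <- round(sum(targets))
    base <- floor(targets)
    rem <- targets - base
    short <- n - sum(base)
    if (short > 0) {
        take <- order(rem, decreasing = TRUE)[seq_len(short)]
        base[take] <- base[take] + 1
    }
    as.integer(base)
}

#' @describeIn generateTruth the underlying truth table.
#' @param truth a \linkS4class{TruthAssignment}.
#' @export
truthTable <- function(truth) truth@table

#' @describeIn generateTruth partition of planted transcript IDs by class
#'   (classes with no members are dropped; \code{"null"} is never included).
#' @export
truthExpectedSets <- function(truth) {
    t <- truth@table
    planted <- t$class != "null"
    split(rownames(t)[planted], t$class[planted])
}

#' @describeIn generateTruth annotation table implied by the truth
#'   (synthetic gene symbols \code{GENEnnnnnn} for annotated transcripts,
#'   NA otherwise), in the format of \code{\link{readAnnotation}}.
#' @export
truthAnnotation <- function(truth) {
    t <- truth@table
    sym <- ifelse(t$annotated,
                  sprintf("GENE%06d", seq_len(nrow(t))), NA_character_)
    data.frame(probeset_id = rownames(t), gene_symbol = sym,
               stringsAsFactors = FALSE)
}

setMethod("show", "TruthAssignment", function(object) {
    t <- object@table
    cat("TruthAssignment:", nrow(t), "transcripts,",
        sum(t$class != "null"), "planted\n")
    print(table(t$class))
})

# Vectorised per-transcript log2 shift applied to one group, given the
# planted classes, the platform's position in the time course, and the
# late-adaptation mode.
classGroupShift <- function(cls, delta, group, timePoint, lateMode) {
    late <- timePoint == "late"
    adaptFactor <- if (!late) 1 else if (lateMode == "reverse") -1 else 0
    out <- numeric(length(cls))
    if (group %in% c("if_1g", "bl", "mug", "mug_skf")) {
        i <- cls == "flight_responsive"
        out[i] <- delta[i]
    }
    if (group == "bl") {
        i <- cls == "hyper_sensitive_adapting"
        out[i] <- adaptFactor * delta[i]
        i <- cls == "hyper_sensitive_continuous"
        out[i] <- delta[i]
    }
    if (group %in% c("mug", "mug_skf")) {
        i <- cls == "micro_sensitive_adapting"
        out[i] <- adaptFactor * delta[i]
        i <- cls == "micro_sensitive_continuous"
        out[i] <- delta[i]
        if (late) {
            i <- cls == "late_responder"
            out[i] <- delta[i]
        }
    }
    if (group == "mug") {
        i <- cls %in% c("skf_enhanced", "skf_attenuated")
        out[i] <- delta[i]
    }
    if (group == "mug_skf") {
        i <- cls == "skf_enhanced"
        out[i] <- 2 * delta[i]
        i <- cls == "skf_attenuated"
        out[i] <- -delta[i]
    }
    out
}

#' Simulate an expression matrix from planted truth
#'
#' Draws, per transcript, a baseline log2 abundance from the noise model,
#' adds the class- and group-dependent planted shift (additive on the log2
#' scale, so multiplicative on the linear scale) and per-sample Gaussian
#' measurement noise, and returns linear-scale values \code{2^(baseline +
#' shift + noise)} — strictly positive by construction. The direction of a
#' planted shift is \code{+log2(effectFold)} for \code{"up"} and
#' \code{-log2(effectFold)} for \code{"down"}.
#'
#' Which groups a class shifts is documented in
#' \code{\link{truthClassLabels}}; whether the platform realises the early
#' or the late time point of the two-platform time course is taken from the
#' design (parabolic flight = early, rocket = late) unless overridden.
#' Adapting classes follow \code{lateMode} at the late time point:
#' \code{"reverse"} (default) plants the opposite-direction effect,
#' \code{"vanish"} plants none.
#'
#' @param truth a \linkS4class{TruthAssignment}.
#' @param design a \linkS4class{StudyDesign}.
#' @param noise a \linkS4class{NoiseModel}.
#' @param seed integer seed; identical inputs and seed give an identical
#'   matrix.
#' @param lateMode \code{"reverse"} or \code{"vanish"}.
#' @param timePoint optional override, \code{"early"} or \code{"late"}.
#' @return a \linkS4class{GravityExperiment} carrying the truth's synthetic
#'   annotation.
#' @export
simulateExpression <- function(truth, design, noise = noiseModel(),
                               seed = 1L, lateMode = c("reverse", "vanish"),
                               timePoint = NULL) {
    lateMode <- match.arg(lateMode)
    t <- truth@table
    n <- nrow(t)
    if (is.null(timePoint)) timePoint <- design@timePoint
    g <- design@groups
    sampleGroup <- rep(g$group, g$n)
    sampleIds <- sprintf("%s_%s_%d", design@platform, sampleGroup,
        unlist(lapply(g$n, seq_len)))

    cls <- as.character(t$class)
    dirs <- as.character(t$direction)
    delta <- ifelse(is.na(dirs), 0, ifelse(dirs == "up", 1, -1)) *
        log2(as.numeric(t$effectFold))

    # transcripts x groups planted shift matrix
    shift <- vapply(g$group, function(grp)
        classGroupShift(cls, delta, grp, timePoint, lateMode),
        numeric(n))
    colnames(shift) <- g$group

    set.seed(deriveSeed(seed, "baseline"))
    baseline <- stats::rnorm(n, noise@baselineLog2Mean, noise@baselineLog2SD)
    set.seed(deriveSeed(seed, "noise"))
    eps <- matrix(stats::rnorm(n * length(sampleIds), 0,
                               noise@residualLog2SD), nrow = n)
    log2v <- baseline + shift[, sampleGroup, drop = FALSE] + eps
    values <- 2^log2v
    dimnames(values) <- list(rownames(t), sampleIds)

    ann <- truthAnnotation(truth)
    GravityExperiment(values, design,
        stats::setNames(sampleGroup, sampleIds),
        geneSymbols = stats::setNames(ann$gene_symbol, ann$probeset_id))
}
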