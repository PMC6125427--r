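#' Percentage with half-even rounding
#'
#' \code{100 * numerator / denominator}, rounded half-to-even at
#' \code{decimals} decimals (the IEC 60559 behaviour of base
#' \code{\link{round}}). Pure arithmetic; the unrounded value is
#' \code{100 * numerator / denominator}.
#'
#' @param numerator nonnegative count, at most \code{denominator}.
#' @param denominator positive count.
#' @param decimals nonnegative integer.
#' @return the rounded percentage.
#' @examples
#' percentage(1573, 1582, 2)  # 99.43
#' percentage(111, 10345, 2)  # 1.07
#' @export
percentage <- function(numerator, denominator, decimals = 2) {
    stopifnot(length(numerator) == length(denominator))
    if (any(denominator <= 0)) stop("denominator must be positive")
    if (any(numerator < 0)) stop("numerator must be nonnegative")
    if (any(numerator > denominator))
        stop("numerator must not exceed denominator")
    round(100 * numerator / denominator, decimals)
}

#' Ratio of two counts with half-even rounding
#'
#' @param countA positive numeric.
#' @param countB positive numeric.
#' @param decimals nonnegative integer.
#' @return \code{countA / countB} rounded half-even.
#' @examples
#' foldRatio(10849, 4783, 1)  # 2.3
#' @export
foldRatio <- function(countA, countB, decimals = 1) {
    if (any(countB <= 0)) stop("countB must be positive")
    round(countA / countB, decimals)
}

#' Screen comparisons for a gene set
#'
#' Finds every annotated transcript whose gene symbol belongs to a supplied
#' gene set (case-insensitive exact match) and reports its fold change and
#' DE direction in each supplied comparison — e.g. screening the DE results
#' for apoptosis/necroptosis pathway genes.
#'
#' @param results named list of \linkS4class{ComparisonResult}s over the
#'   same universe.
#' @param annotation annotation data.frame covering the universe.
#' @param geneSymbols nonempty character vector of gene symbols.
#' @return data.frame with \code{probeset_id}, \code{gene_symbol} and, per
#'   comparison \code{X}, columns \code{fc_X} and \code{dir_X}; one row per
#'   matching annotated transcript, ordered by probeset ID.
#' @export
screenGeneset <- function(results, annotation, geneSymbols) {
    if (!length(geneSymbols)) stop("gene set is empty")
    if (!length(results)) stop("no comparison results supplied")
    sym <- stats::setNames(annotation$gene_symbol, annotation$probeset_id)
    hit <- !is.na(sym) & tolower(sym) %in% tolower(geneSymbols)
    ids <- sort(annotation$probeset_id[hit])
    out <- data.frame(probeset_id = ids,
                      gene_symbol = unname(sym[ids]),
                      stringsAsFactors = FALSE)
    for (nm in names(results)) {
        r <- results[[nm]]@results
        out[[paste0("fc_", nm)]] <- r[ids, "fc"]
        out[[paste0("dir_", nm)]] <- r[ids, "direction"]
    }
    out
}

#' Run the full inference pipeline
#'
#' Executes the whole chain — simulate or read expression matrices per
#' platform, run all pre-registered comparisons, build the control-filtered
#' gravisensitive sets, the SKF-96365 attribution (when the platform has the
#' inhibitor groups), the within- and cross-platform direction-concordance
#' analyses and the time-course adaptation summaries, and optionally a
#' gene-set screen — writing every table as TSV plus a human-readable
#' summary and a parameter log into \code{outDir}. Output is deterministic
#' for a fixed config: stable row ordering (by probeset ID), no timestamps,
#' fixed number formatting — re-running the same config yields a
#' byte-identical bundle.
#'
#' @param config configuration list or path to a YAML file with entries:
#'   \code{seed} (integer, mandatory when simulating); \code{thresholds}
#'   (optional list \code{fcCutoff}, \code{alpha}); \code{test} (optional
#'   list \code{variant}, \code{scale}); \code{platforms}: named list
#'   (names = platform IDs) where each entry has either \code{simulate}
#'   (list: \code{nTranscripts}, optional \code{classProportions},
#'   \code{effectFoldRange}, \code{noise} list, \code{lateMode}) or
#'   \code{matrix} + \code{groupMap} (file paths, with optional
#'   \code{log2Input}); optional \code{annotation} (TSV path; simulated
#'   platforms default to the truth's annotation); optional \code{geneset}
#'   (path to a one-symbol-per-line file).
#' @param outDir output directory (created if absent).
#' @return invisibly, a list with the per-platform comparison results,
#'   gravisets, summaries, and the paths written.
#' @export
runPipeline <- function(config, outDir) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    if (is.null(config$platforms) || !length(config$platforms))
        stop("config must name at least one platform under 'platforms'")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    th <- do.call(deThresholds, as.list(config$thresholds))
    testVariant <- config$test$variant %||% "welch"
    testScale <- config$test$scale %||% "linear"
    log <- c("gravitrans pipeline log",
             sprintf("thresholds: |FC| >= %g (inclusive), p < %g (strict)",
                     th@fcCutoff, th@alpha),
             sprintf("t-test: %s, %s scale", testVariant, testScale))

    state <- list()
    for (platform in names(config$platforms)) {
        pc <- config$platforms[[platform]]
        design <- loadDesign(platform)
        if (!is.null(pc$simulate)) {
            if (is.null(config$seed))
                stop("config$seed is mandatory when simulating")
            sim <- pc$simulate
            truth <- generateTruth(
                nTranscripts = sim$nTranscripts %||% 5000,
                classProportions = unlist(sim$classProportions) %||%
                    defaultClassProportions(),
                effectFoldRange = sim$effectFoldRange %||% c(1.4, 2.5),
                seed = config$seed)
            nm <- do.call(noiseModel, as.list(sim$noise))
            x <- simulateExpression(truth, design, nm,
                seed = config$seed + match(platform,
                    names(config$platforms)),
                lateMode = sim$lateMode %||% "reverse")
            annotation <- truthAnnotation(truth)
            log <- c(log, sprintf(
                "%s: simulated %d transcripts (seed %d)", platform,
                nrow(x), config$seed))
        } else if (!is.null(pc$matrix)) {
            annotation <- if (!is.null(config$annotation))
                readAnnotation(config$annotation) else NULL
            x <- readExpressionMatrix(pc$matrix, design, pc$groupMap,
                annotation = annotation,
                log2Input = isTRUE(pc$log2Input))
            if (is.null(annotation))
                annotation <- data.frame(probeset_id = rownames(x),
                    gene_symbol = NA_character_, stringsAsFactors = FALSE)
            log <- c(log, sprintf("%s: read %d transcripts x %d samples",
                platform, nrow(x), ncol(x)))
        } else {
            stop("platform '", platform,
                 "' has neither a 'simulate' nor a 'matrix' input")
        }
        gtab <- table(sampleGroups(x))
        log <- c(log, sprintf("%s groups: %s", platform,
            paste(sprintf("%s=%d", names(gtab), gtab), collapse = ", ")))

        results <- list()
        for (i in seq_len(nrow(design@comparisons))) {
            cmp <- design@comparisons[i, ]
            results[[cmp$name]] <- suppressWarnings(compareGroups(
                x, cmp$numerator, cmp$denominator, th,
                testVariant = testVariant, testScale = testScale,
                name = cmp$name))
            counts <- countDE(results[[cmp$name]], annotation)
            log <- c(log, sprintf(
                "%s %s: %d up / %d down (annotated %d / %d)", platform,
                cmp$name, counts["upAll"], counts["downAll"],
                counts["upAnnot"], counts["downAnnot"]))
            writeComparisonTSV(results[[cmp$name]], annotation,
                file.path(outDir, sprintf("comparison_%s_%s.tsv",
                                          platform, cmp$name)))
        }
        sets <- if (platform == "PFC") pfcGravisets(results)
                else texusGravisets(results)
        if (all(c("mugskf_vs_mug", "gcskf_vs_gc") %in% names(results))) {
            skf <- skfAttribution(sets$micro_bl_controlled,
                results$mugskf_vs_mug, results$gcskf_vs_gc)
            sets <- c(sets, skf)
        }
        for (s in sets)
            log <- c(log, sprintf("%s set %s: %d members (%d up, %d down)",
                platform, s@name, length(s),
                sum(s@members$direction == "up"),
                sum(s@members$direction == "down")))
        writeGravisetTSV(sets, annotation,
            file.path(outDir, sprintf("gravisets_%s.tsv", platform)))
        summaries <- do.call(rbind, lapply(sets, summarizeGraviset,
                                           annotation = annotation))
        utils::write.table(summaries,
            file.path(outDir, sprintf("graviset_summary_%s.tsv", platform)),
            sep = "\t", quote = FALSE, row.names = FALSE)
        state[[platform]] <- list(experiment = x, results = results,
                                  sets = sets, annotation = annotation)
    }

    report <- list()
    if (all(c("PFC", "TEXUS") %in% names(state))) {
        report <- crossPlatformReport(state, outDir)
        log <- c(log, report$log)
    }
    if (!is.null(config$geneset)) {
        symbols <- readLines(config$geneset)
        symbols <- symbols[nzchar(symbols)]
        for (platform in names(state)) {
            screen <- screenGeneset(state[[platform]]$results,
                state[[platform]]$annotation, symbols)
            utils::write.table(screen,
                file.path(outDir, sprintf("geneset_screen_%s.tsv", platform)),
                sep = "\t", quote = FALSE, row.names = FALSE)
            log <- c(log, sprintf("%s gene-set screen: %d hits of %d symbols",
                platform, nrow(screen), length(symbols)))
        }
    }
    writeLines(log, file.path(outDir, "pipeline_log.txt"))
    invisible(list(platforms = state, crossPlatform = report$values,
                   outDir = outDir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

writeComparisonTSV <- function(result, annotation, file) {
    tab <- resultsTable(result)
    out <- data.frame(probeset_id = rownames(tab), stringsAsFactors = FALSE)
    if (!is.null(annotation)) {
        sym <- stats::setNames(annotation$gene_symbol,
                               annotation$probeset_id)
        out$gene_symbol <- unname(sym[out$probeset_id])
    }
    out <- cbind(out, tab)
    out <- out[order(out$probeset_id), ]
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
}

writeGravisetTSV <- function(sets, annotation, file) {
    rows <- lapply(sets, function(s) {
        m <- setMembers(s)
        if (!nrow(m)) return(NULL)
        data.frame(probeset_id = rownames(m), set_name = s@name,
                   direction = m$direction, fc_primary = m$fcPrimary,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    if (is.null(out))
        out <- data.frame(probeset_id = character(), set_name = character(),
                          direction = character(), fc_primary = numeric())
    if (!is.null(annotation) && nrow(out)) {
        sym <- stats::setNames(annotation$gene_symbol,
                               annotation$probeset_id)
        out$gene_symbol <- unname(sym[out$probeset_id])
    }
    out <- out[order(out$set_name, out$probeset_id), ]
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
}

# Cross-platform concordance and adaptation, given both platforms' state.
crossPlatformReport <- function(state, outDir) {
    pfc <- state$PFC; tx <- state$TEXUS
    log <- character()
    # within-platform double-sensitive transcripts
    withinPfc <- doubleSensitive(pfc$sets$hyper_texus_analogous,
                                 pfc$sets$micro_bl_controlled)
    withinTx <- doubleSensitive(tx$sets$hyper_sensitive,
                                tx$sets$micro_bl_controlled)
    ccPfc <- concordanceCounts(withinPfc)
    ccTx <- concordanceCounts(withinTx)
    log <- c(log, sprintf(
        "PFC hyper/micro double-sensitive: %d (%d same, %d opposite)",
        nrow(withinPfc), ccPfc["nSame"], ccPfc["nOpposite"]))
    log <- c(log, sprintf(
        "TEXUS hyper/micro double-sensitive: %d (%d same, %d opposite)",
        nrow(withinTx), ccTx["nSame"], ccTx["nOpposite"]))

    # universes differ between independently simulated/read platforms only
    # if the inputs do; cross-platform matching is by probeset ID
    hyperEarly <- pfc$sets$hyper_if_controlled
    hyperLate <- tx$sets$hyper_sensitive
    microEarly <- pfc$sets$micro_bl_and_if_controlled
    microLate <- tx$sets$micro_bl_controlled
    crossHyper <- doubleSensitive(hyperEarly, hyperLate)
    crossMicro <- doubleSensitive(microEarly, microLate)
    ccH <- concordanceCounts(crossHyper)
    ccM <- concordanceCounts(crossMicro)
    log <- c(log, sprintf(
        "cross-platform hypergravity: %d shared (%d same, %d opposite)",
        nrow(crossHyper), ccH["nSame"], ccH["nOpposite"]))
    log <- c(log, sprintf(
        "cross-platform microgravity: %d shared (%d same, %d opposite)",
        nrow(crossMicro), ccM["nSame"], ccM["nOpposite"]))
    utils::write.table(crossHyper[order(crossHyper$transcript_id), ],
        file.path(outDir, "crossplatform_hyper_pairs.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(crossMicro[order(crossMicro$transcript_id), ],
        file.path(outDir, "crossplatform_micro_pairs.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)

    # adaptation over annotated transcripts (matched gravity conditions)
    annotIds <- function(st) {
        a <- st$annotation
        sort(a$probeset_id[!is.na(a$gene_symbol)])
    }
    universe <- intersect(annotIds(pfc), annotIds(tx))
    restrict <- function(gs, universe) {
        gs@members <- gs@members[rownames(gs@members) %in% universe, ,
                                 drop = FALSE]
        gs@universe <- universe
        gs
    }
    adHyper <- adaptationSummary(restrict(hyperEarly, universe),
                                 restrict(hyperLate, universe), universe)
    adMicro <- adaptationSummary(restrict(microEarly, universe),
                                 restrict(microLate, universe), universe)
    for (nm in c("hyper", "micro")) {
        ad <- if (nm == "hyper") adHyper else adMicro
        log <- c(log, sprintf(
            paste0("%sgravity adaptation: no_response=%d continuous=%d ",
                   "adapted=%d late_response=%d; adapted %% = %s"),
            nm, ad$counts["no_response"], ad$counts["continuous"],
            ad$counts["adapted"], ad$counts["late_response"],
            formatC(ad$adaptationPct, format = "f", digits = 2)))
        utils::write.table(ad$records,
            file.path(outDir, sprintf("adaptation_%sgravity.tsv", nm)),
            sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(log = log,
         values = list(withinPfc = ccPfc, withinTexus = ccTx,
                       crossHyper = ccH, crossMicro = ccM,
                       adaptHyper = adHyper, adaptMicro = adMicro))
}
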