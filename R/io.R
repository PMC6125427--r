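#' Construct a GravityExperiment from an expression matrix
#'
#' Wraps a strictly positive, linear-scale transcript x sample matrix, a
#' sample-to-group map and a \linkS4class{StudyDesign} into a validated
#' \linkS4class{GravityExperiment}. Fold changes downstream are ratios of
#' group means on the linear scale, so values must be linear; RMA summaries
#' exported on the log2 scale can be declared with \code{log2Input = TRUE}
#' and are exponentiated on construction.
#'
#' @param values numeric matrix, rownames = transcript IDs, colnames =
#'   sample IDs.
#' @param design a \linkS4class{StudyDesign}.
#' @param sampleGroups named character vector (names = sample IDs) or
#'   data.frame with columns \code{sample_id}, \code{group}; groups may be
#'   slugs or display names.
#' @param geneSymbols optional named character vector of gene symbols
#'   (NA = unannotated), names = transcript IDs.
#' @param log2Input if TRUE, \code{values} are log2-scale and are
#'   exponentiated.
#' @return a \linkS4class{GravityExperiment}.
#' @export
GravityExperiment <- function(values, design, sampleGroups,
                              geneSymbols = NULL, log2Input = FALSE) {
    values <- as.matrix(values)
    if (is.null(rownames(values)))
        stop("values must carry transcript IDs as rownames")
    if (log2Input) values <- 2^values
    if (is.data.frame(sampleGroups)) {
        sg <- stats::setNames(as.character(sampleGroups$group),
                              sampleGroups$sample_id)
    } else sg <- sampleGroups
    missing <- setdiff(colnames(values), names(sg))
    if (length(missing))
        stop("samples with no group assignment: ",
             paste(missing, collapse = ", "))
    grp <- vapply(unname(sg[colnames(values)]),
                  function(g) resolveGroup(design, g), character(1))
    bad <- which(!is.finite(values) | values <= 0, arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf(
            "nonpositive or non-numeric expression value at transcript '%s', sample '%s'",
            rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]))
    cd <- S4Vectors::DataFrame(group = grp, row.names = colnames(values))
    rd <- S4Vectors::DataFrame(row.names = rownames(values))
    if (!is.null(geneSymbols))
        rd$geneSymbol <- unname(geneSymbols[rownames(values)])
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values), colData = cd, rowData = rd)
    new("GravityExperiment", se, design = design)
}

#' Read an expression matrix from TSV
#'
#' Reads a tab-separated expression table (first column \code{probeset_id},
#' remaining columns one per sample, '.' decimal separator) together with a
#' sample-to-group TSV (\code{sample_id}, \code{group}) into a
#' \linkS4class{GravityExperiment}. Row order is preserved. Errors report
#' the offending transcript/sample for nonpositive or non-numeric cells,
#' duplicated probeset IDs, and samples lacking a group.
#'
#' @param file path to the expression TSV.
#' @param design a \linkS4class{StudyDesign}.
#' @param groupMap path to the group-map TSV, or a data.frame/named vector
#'   as accepted by \code{\link{GravityExperiment}}.
#' @param annotation optional annotation data.frame as returned by
#'   \code{\link{readAnnotation}}.
#' @inheritParams GravityExperiment
#' @return a \linkS4class{GravityExperiment}.
#' @seealso \code{\link{writeExpressionMatrix}}
#' @export
readExpressionMatrix <- function(file, design, groupMap,
                                 annotation = NULL, log2Input = FALSE) {
    tab <- utils::read.table(file, header = TRUE, sep = "\t",
                             quote = "", comment.char = "",
                             check.names = FALSE, colClasses = "character")
    if (names(tab)[1] != "probeset_id")
        stop("expression TSV must have 'probeset_id' as its first column")
    ids <- tab[[1]]
    dup <- ids[duplicated(ids)]
    if (length(dup))
        stop("duplicated probeset ID(s): ",
             paste(unique(dup), collapse = ", "))
    num <- suppressWarnings(
        vapply(tab[-1], as.numeric, numeric(nrow(tab))))
    num <- matrix(num, nrow = nrow(tab),
                  dimnames = list(ids, names(tab)[-1]))
    if (is.character(groupMap)) {
        gm <- utils::read.table(groupMap, header = TRUE, sep = "\t",
                                quote = "", comment.char = "",
                                stringsAsFactors = FALSE)
        groupMap <- stats::setNames(gm$group, gm$sample_id)
    }
    gs <- NULL
    if (!is.null(annotation))
        gs <- stats::setNames(annotation$gene_symbol, annotation$probeset_id)
    GravityExperiment(num, design, groupMap, geneSymbols = gs,
                      log2Input = log2Input)
}

#' Write an expression matrix (and its group map) to TSV
#'
#' Values are written with 17 significant digits so that reading the file
#' back reproduces them exactly (full double precision round trip).
#'
#' @param x a \linkS4class{GravityExperiment}.
#' @param file path for the expression TSV.
#' @param groupMapFile optional path for the sample-to-group TSV.
#' @return invisibly, \code{file}.
#' @export
writeExpressionMatrix <- function(x, file, groupMapFile = NULL) {
    v <- exprValues(x)
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(paste(c("probeset_id", colnames(v)), collapse = "\t"), con)
    body <- vapply(seq_len(nrow(v)), function(i)
        paste(c(rownames(v)[i], formatFull(v[i, ])), collapse = "\t"),
        character(1))
    writeLines(body, con)
    if (!is.null(groupMapFile)) {
        gm <- data.frame(sample_id = colnames(x),
                         group = sampleGroups(x))
        utils::write.table(gm, groupMapFile, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(file)
}

#' Read a probeset annotation table
#'
#' TSV with columns \code{probeset_id} and \code{gene_symbol}; an empty
#' gene symbol marks an unannotated probeset and is read as NA.
#'
#' @param file path to the annotation TSV.
#' @return data.frame with columns \code{probeset_id}, \code{gene_symbol}.
#' @export
readAnnotation <- function(file) {
    a <- utils::read.table(file, header = TRUE, sep = "\t", quote = "",
                           comment.char = "", stringsAsFactors = FALSE,
                           na.strings = c("", "NA"),
                           colClasses = "character")
    if (!all(c("probeset_id", "gene_symbol") %in% names(a)))
        stop("annotation TSV needs columns probeset_id, gene_symbol")
    a
}

#' Load a packaged reference fold-change table
#'
#' The package ships two published reference tables of signed fold changes,
#' transcribed verbatim:
#' \describe{
#'   \item{\code{"table8"}}{the 57 annotated transcripts differentially
#'     regulated in all four gravity conditions across both platforms, with
#'     FC columns for the two parabolic-flight contrasts
#'     (BL-PFC hyp-g vs 1 g IF; microgravity vs BL-PFC hyp-g) and the two
#'     rocket contrasts (microgravity vs BL-TX hyp-g; BL-TX hyp-g vs GC).}
#'   \item{\code{"table9"}}{the 9 annotated transcripts with a continuous
#'     (non-adapting) microgravity response, with FC columns for
#'     microgravity vs baseline on each platform.}
#' }
#' Every tabulated fold change satisfies |FC| >= 1.3.
#'
#' @param tableId \code{"table8"} or \code{"table9"}.
#' @return data.frame with columns \code{gene_name}, \code{probeset_id} and
#'   the signed FC columns; the comparison labels are attached as attribute
#'   \code{"column_labels"}.
#' @examples
#' t8 <- loadPrintedTable("table8")
#' nrow(t8)  # 57
#' @export
loadPrintedTable <- function(tableId) {
    files <- c(table8 = "crossplatform_gravity_regulated_fc.tsv",
               table9 = "microgravity_continuous_fc.tsv")
    if (!tableId %in% names(files))
        stop("unknown reference table '", tableId, "'; available: ",
             paste(names(files), collapse = ", "))
    path <- system.file("extdata", files[[tableId]], package = "gravitrans",
                        mustWork = TRUE)
    tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                             stringsAsFactors = FALSE)
    fcCols <- setdiff(names(tab), c("gene_name", "probeset_id"))
    stopifnot(all(abs(as.matrix(tab[fcCols])) >= 1.3))
    attr(tab, "column_labels") <- fcCols
    tab
}

#' @describeIn GravityExperiment linear-scale expression matrix.
#' @param x a \linkS4class{GravityExperiment}.
#' @export
exprValues <- function(x) SummarizedExperiment::assay(x, "exprs")

#' @describeIn GravityExperiment group slug of every sample.
#' @export
sampleGroups <- function(x) {
    stats::setNames(SummarizedExperiment::colData(x)$group, colnames(x))
}

#' @describeIn GravityExperiment the attached StudyDesign.
#' @export
expDesign <- function(x) x@design

#' @describeIn GravityExperiment gene symbols (NA where unannotated), or
#'   NULL if the experiment carries no annotation.
#' @export
geneSymbols <- function(x) {
    rd <- SummarizedExperiment::rowData(x)
    if (!"geneSymbol" %in% names(rd)) return(NULL)
    stats::setNames(rd$geneSymbol, rownames(x))
}

setMethod("show", "GravityExperiment", function(object) {
    cat("GravityExperiment:", nrow(object), "transcripts x",
        ncol(object), "samples on platform", object@design@platform, "\n")
    tab <- table(SummarizedExperiment::colData(object)$group)
    cat("  samples per group:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
    gs <- geneSymbols(object)
    if (!is.null(gs))
        cat("  annotated transcripts:", sum(!is.na(gs)), "\n")
})
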