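#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom SummarizedExperiment assay<- rowData<- colData<-
NULL

setOldClass("hclust")

#' CountMatrix: transcripts-by-samples abundance table with sample metadata
#'
#' The universal currency of the pipeline: a thin wrapper around
#' \linkS4class{SummarizedExperiment} whose single assay holds nonnegative
#' abundances (raw counts, fpkm-like values, or relative abundances after
#' \code{\link{normalizeRelative}}) and whose \code{colData} carries, for every
#' sample, a \code{condition} (one of \code{control}, \code{cold},
#' \code{desiccated}, \code{field}), a \code{site} label and a \code{replicate}
#' index.
#'
#' @slot . inherits all slots from \code{SummarizedExperiment}.
#' @aliases CountMatrix-class
#' @exportClass CountMatrix
setClass("CountMatrix", contains = "SummarizedExperiment")

.validConditions <- c("control", "cold", "desiccated", "field")

setValidity("CountMatrix", function(object) {
    msg <- character()
    a <- assay(object)
    if (nrow(object) > 0 &&
        (is.null(rownames(object)) || anyDuplicated(rownames(object))))
        msg <- c(msg, "transcript identifiers (rownames) must be present and unique")
    if (ncol(object) > 0 &&
        (is.null(colnames(object)) || anyDuplicated(colnames(object))))
        msg <- c(msg, "sample identifiers (colnames) must be present and unique")
    if (!is.numeric(a) || any(!is.finite(a)) || any(a < 0))
        msg <- c(msg, "abundances must be finite and nonnegative")
    cd <- colData(object)
    if (!"condition" %in% colnames(cd)) {
        msg <- c(msg, "colData must contain a 'condition' column")
    } else if (any(is.na(cd$condition)) ||
               !all(cd$condition %in% .validConditions)) {
        msg <- c(msg, sprintf("every sample needs a condition in {%s}",
                              paste(.validConditions, collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' Construct a CountMatrix
#'
#' @param counts numeric matrix, transcripts in rows (rownames = transcript
#'   identifiers), samples in columns (colnames = sample identifiers).
#' @param condition character vector, one of \code{control}, \code{cold},
#'   \code{desiccated}, \code{field} per sample.
#' @param site character vector or scalar, site label per sample.
#' @param replicate integer vector or scalar, replicate index per sample.
#' @param ... further per-sample columns (e.g. a latent \code{stress_level}),
#'   recycled to the number of samples.
#'
#' @return a \linkS4class{CountMatrix}.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("t", 1:3), c("s1", "s2")))
#' CountMatrix(m, condition = c("control", "cold"))
#' @export
CountMatrix <- function(counts, condition, site = "lab", replicate = NA_integer_,
                        ...) {
    counts <- as.matrix(counts)
    n <- ncol(counts)
    cd <- DataFrame(condition = rep_len(as.character(condition), n),
                    site = rep_len(as.character(site), n),
                    replicate = rep_len(as.integer(replicate), n),
                    ...)
    rownames(cd) <- colnames(counts)
    new("CountMatrix",
        SummarizedExperiment(assays = list(abundance = counts), colData = cd))
}

#' @describeIn CountMatrix abundance matrix (the single assay)
#' @param x a CountMatrix
#' @export
abundances <- function(x) {
    if (is(x, "SummarizedExperiment")) assay(x) else as.matrix(x)
}

#' @describeIn CountMatrix condition label per sample
#' @export
sampleConditions <- function(x) as.character(colData(x)$condition)

#' @describeIn CountMatrix site label per sample
#' @export
sampleSites <- function(x) as.character(colData(x)$site)

setMethod("show", "CountMatrix", function(object) {
    cat("CountMatrix:", nrow(object), "transcripts x", ncol(object), "samples\n")
    tab <- table(sampleConditions(object))
    cat("  conditions:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
})

#' MarkerCatalog: stressor-specific marker transcript sets
#'
#' Holds, per stressor, the transcripts regulated by exactly that stressor
#' (with direction), the transcripts regulated by both stressors (dual, kept
#' apart because they are excluded from index calculation but included in the
#' wider clustering dataset), and per-stressor sets of constantly expressed
#' transcripts used as ratio denominators.
#'
#' @slot regulated data.frame with columns \code{transcript_id},
#'   \code{stressor} (\code{cold}/\code{desiccation}), \code{direction}
#'   (\code{up}/\code{down}); single-stressor transcripts only.
#' @slot dual character, transcripts regulated by both stressors.
#' @slot constant named list of character vectors, one per stressor.
#' @slot thresholds list, provenance of the thresholds used.
#' @aliases MarkerCatalog-class
#' @exportClass MarkerCatalog
setClass("MarkerCatalog",
         representation(regulated = "data.frame", dual = "character",
                        constant = "list", thresholds = "list"),
         prototype(regulated = data.frame(transcript_id = character(),
                                          stressor = character(),
                                          direction = character()),
                   dual = character(), constant = list(), thresholds = list()))

setValidity("MarkerCatalog", function(object) {
    msg <- character()
    reg <- object@regulated
    need <- c("transcript_id", "stressor", "direction")
    if (!all(need %in% colnames(reg)))
        return(sprintf("regulated must have columns %s",
                       paste(need, collapse = ", ")))
    if (!all(reg$stressor %in% c("cold", "desiccation")))
        msg <- c(msg, "stressor must be 'cold' or 'desiccation'")
    if (!all(reg$direction %in% c("up", "down")))
        msg <- c(msg, "direction must be 'up' or 'down'")
    if (anyDuplicated(reg$transcript_id))
        msg <- c(msg, "a transcript may be specific to at most one stressor")
    if (length(intersect(reg$transcript_id, object@dual)))
        msg <- c(msg, "single-stressor and dual sets must be disjoint")
    regOrDual <- union(reg$transcript_id, object@dual)
    bad <- intersect(unlist(object@constant, use.names = FALSE), regOrDual)
    if (length(bad))
        msg <- c(msg, sprintf("constant set overlaps regulated/dual set: %s",
                              paste(bad, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Construct a MarkerCatalog
#'
#' @param regulated data.frame(transcript_id, stressor, direction) of
#'   single-stressor-regulated transcripts.
#' @param dual character, transcripts regulated by both stressors.
#' @param constant named list of character vectors (per stressor) of constantly
#'   expressed transcripts; a single character vector is used for both.
#' @param thresholds list recording the selection thresholds (provenance).
#' @return a \linkS4class{MarkerCatalog}
#' @export
MarkerCatalog <- function(regulated, dual = character(),
                          constant = character(), thresholds = list()) {
    if (is.character(constant))
        constant <- list(cold = constant, desiccation = constant)
    regulated$transcript_id <- as.character(regulated$transcript_id)
    new("MarkerCatalog", regulated = as.data.frame(regulated),
        dual = as.character(dual), constant = constant,
        thresholds = thresholds)
}

.checkStressor <- function(stressor) {
    match.arg(stressor, c("cold", "desiccation"))
}

#' @describeIn MarkerCatalog data.frame(transcript_id, direction) of
#'   transcripts regulated specifically by \code{stressor}
#' @param x a MarkerCatalog
#' @param stressor \code{"cold"} or \code{"desiccation"}
#' @export
regulatedMarkers <- function(x, stressor) {
    stressor <- .checkStressor(stressor)
    reg <- x@regulated[x@regulated$stressor == stressor,
                       c("transcript_id", "direction"), drop = FALSE]
    rownames(reg) <- NULL
    reg
}

#' @describeIn MarkerCatalog constantly expressed transcripts used as
#'   denominators for \code{stressor}
#' @export
constantMarkers <- function(x, stressor) {
    stressor <- .checkStressor(stressor)
    ids <- x@constant[[stressor]]
    if (is.null(ids)) character() else ids
}

#' @describeIn MarkerCatalog transcripts regulated by both stressors
#' @export
dualMarkers <- function(x) x@dual

setMethod("show", "MarkerCatalog", function(object) {
    cat("MarkerCatalog\n")
    for (s in c("cold", "desiccation")) {
        cat(sprintf("  %-11s: %d regulated, %d constant\n", s,
                    nrow(regulatedMarkers(object, s)),
                    length(constantMarkers(object, s))))
    }
    cat("  dual-regulated:", length(object@dual), "\n")
})

#' SimprofResult: similarity-profile test over a dendrogram
#'
#' Result of the recursive SIMPROF procedure: the Ward.D2 dendrogram, one row
#' per internal node with the pi statistic and permutation p-value where the
#' node was tested, and the maximal non-significant groups reported as
#' clusters.
#'
#' @slot tree the \code{hclust} dendrogram.
#' @slot tests data.frame with columns \code{node} (hclust merge row),
#'   \code{n} (group size), \code{pi}, \code{p_value}, \code{tested},
#'   \code{significant}.
#' @slot clusters list of character vectors of sample ids (the significant
#'   partition: maximal groups with no detectable internal structure).
#' @slot alpha,nExpected,nSimulated,seed test parameters.
#' @aliases SimprofResult-class
#' @exportClass SimprofResult
setClass("SimprofResult",
         representation(tree = "hclust", tests = "data.frame",
                        clusters = "list", alpha = "numeric",
                        nExpected = "numeric", nSimulated = "numeric",
                        seed = "numeric"))

setValidity("SimprofResult", function(object) {
    msg <- character()
    tst <- object@tests
    if (any(tst$pi[tst$tested] < 0, na.rm = TRUE))
        msg <- c(msg, "pi statistics must be nonnegative")
    p <- tst$p_value[tst$tested]
    if (any(p <= 0 | p > 1, na.rm = TRUE))
        msg <- c(msg, "permutation p-values must lie in (0, 1]")
    leaves <- sort(object@tree$labels)
    if (!identical(sort(unlist(object@clusters, use.names = FALSE)), leaves))
        msg <- c(msg, "clusters must partition the dendrogram leaves")
    if (length(msg)) msg else TRUE
})

#' @describeIn SimprofResult the significant partition (list of sample-id
#'   vectors)
#' @param x a SimprofResult
#' @export
significantClusters <- function(x) x@clusters

#' @describeIn SimprofResult per-node test table
#' @export
simprofTests <- function(x) x@tests

setMethod("show", "SimprofResult", function(object) {
    nt <- sum(object@tests$tested)
    cat(sprintf("SimprofResult: %d samples, %d node(s) tested, alpha = %g\n",
                length(object@tree$labels), nt, object@alpha))
    cat(sprintf("  %d significant cluster group(s):\n", length(object@clusters)))
    for (cl in object@clusters)
        cat("   -", paste(cl, collapse = ", "), "\n")
})
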