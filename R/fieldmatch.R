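.blastColumns <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                   "gapopen", "qstart", "qend", "sstart", "send",
                   "evalue", "bitscore")

.checkHits <- function(hits) {
    miss <- setdiff(c("qseqid", "sseqid", "pident", "evalue", "bitscore"),
                    colnames(hits))
    if (length(miss))
        stop("hit table lacks column(s): ", paste(miss, collapse = ", "))
    bad <- which(!is.finite(hits$pident) | hits$pident < 0 | hits$pident > 100 |
                 !is.finite(hits$evalue) | hits$evalue < 0)
    if (length(bad))
        stop("malformed hit row(s): ", paste(utils::head(bad, 5), collapse = ", "))
    invisible(hits)
}

#' Filter identity hits by percent identity and e-value
#'
#' Retains hits with \code{pident >= minIdentity} and
#' \code{evalue <= maxEvalue} (defaults: the 98\% identity and 1e-50 e-value
#' retention thresholds used to recognise target-organism contigs in a mixed
#' metatranscriptome), then reduces to the single best hit per query contig
#' (highest bit score, then highest identity, then lexicographically smallest
#' subject id). Idempotent: filtering a filtered table changes nothing.
#'
#' @param hits data.frame of hits, e.g. from \code{\link{readBlastTab}} or
#'   \code{\link{simulateIdentityHits}}
#' @param minIdentity minimum percent identity (0-100)
#' @param maxEvalue maximum e-value
#' @return the retained hits, one row per query, with the counts before and
#'   after filtering in \code{attr(, "funnel")}
#' @export
filterHits <- function(hits, minIdentity = 98, maxEvalue = 1e-50) {
    .checkHits(hits)
    keep <- hits$pident >= minIdentity & hits$evalue <= maxEvalue
    ret <- hits[keep, , drop = FALSE]
    ord <- order(ret$qseqid, -ret$bitscore, -ret$pident, ret$sseqid)
    ret <- ret[ord, , drop = FALSE]
    ret <- ret[!duplicated(ret$qseqid), , drop = FALSE]
    rownames(ret) <- NULL
    attr(ret, "funnel") <- c(input = nrow(hits), pass_thresholds = sum(keep),
                             best_per_query = nrow(ret))
    ret
}

#' Map retained field contigs onto reference transcripts
#'
#' Abundances of all contigs assigned to the same reference transcript are
#' summed per field sample (fragmented assemblies of one gene are additive in
#' reads); the result is indexed by reference transcript ids.
#'
#' @param hits retained hits from \code{\link{filterHits}} (one per query)
#' @param field contig-level field \linkS4class{CountMatrix}; every retained
#'   query must be present among its rows
#' @return a \linkS4class{CountMatrix} over reference transcript ids, keeping
#'   the field sample metadata
#' @export
mapToReference <- function(hits, field) {
    counts <- abundances(field)
    if (nrow(hits) == 0) {
        warning("no retained hits; returning an empty table")
        empty <- counts[integer(0), , drop = FALSE]
        return(CountMatrix(empty, condition = sampleConditions(field),
                           site = sampleSites(field),
                           replicate = colData(field)$replicate))
    }
    absent <- setdiff(hits$qseqid, rownames(counts))
    if (length(absent))
        stop("query contig(s) absent from field matrix: ",
             paste(utils::head(absent, 5), collapse = ", "))
    agg <- rowsum(counts[hits$qseqid, , drop = FALSE], group = hits$sseqid)
    CountMatrix(agg[sort(rownames(agg)), , drop = FALSE],
                condition = sampleConditions(field), site = sampleSites(field),
                replicate = colData(field)$replicate)
}

#' Per-sample relative abundances
#'
#' Scales every sample (column) to sum to 1 over the transcripts present in
#' the table. When the table has already been restricted to the target
#' organism's transcripts this realises normalization to the organism's total
#' reads; being a per-sample rescale it is invariant to library size.
#'
#' @param x a \linkS4class{CountMatrix} or plain matrix of nonnegative
#'   abundances
#' @return object of the same class with every column summing to 1
#' @export
normalizeRelative <- function(x) {
    counts <- abundances(x)
    totals <- colSums(counts)
    zero <- colnames(counts)[totals == 0]
    if (length(zero))
        stop("all-zero sample(s): ", paste(zero, collapse = ", "))
    norm <- sweep(counts, 2, totals, "/")
    if (is(x, "SummarizedExperiment")) {
        assay(x) <- norm
        x
    } else norm
}
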