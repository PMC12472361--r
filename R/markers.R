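.stressCondition <- function(stressor) {
    switch(.checkStressor(stressor), cold = "cold", desiccation = "desiccated")
}

# scale every sample to the mean library size, preserving count-like magnitude
.libraryScale <- function(counts) {
    totals <- colSums(counts)
    if (any(totals == 0))
        stop("all-zero sample(s): ",
             paste(colnames(counts)[totals == 0], collapse = ", "))
    sweep(counts, 2, mean(totals) / totals, "*")
}

# vectorized Welch two-sample test, one row per transcript
.welchTest <- function(a, b) {
    na <- ncol(a); nb <- ncol(b)
    ma <- rowMeans(a); mb <- rowMeans(b)
    va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
    se2 <- va / na + vb / nb
    t <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * stats::pt(-abs(t), df)
    p[!is.finite(t)] <- 0        # zero variance, unequal means
    p[is.nan(t)] <- 1            # zero variance, equal means: no evidence
    p
}

#' Classify transcripts as stress-regulated or not
#'
#' Lightweight differential-expression classifier honouring the published
#' thresholds (fold change > 2, p < 0.05, FDR < 0.05): per-sample abundances
#' are scaled to a common library size, the log2 fold change is the log ratio
#' of condition means (with a pseudocount \code{eps} against zeros), p-values
#' come from a Welch two-sample test on \code{log2(scaled abundance + 1)}, and
#' the FDR is Benjamini-Hochberg over all transcripts tested for the stressor.
#' Users with a full differential-expression analysis from a dedicated tool
#' can bypass this classifier via \code{\link{readRegulationTable}}.
#'
#' @param lab a lab \linkS4class{CountMatrix} with at least 2 replicates each
#'   of \code{control} and the stressor condition
#' @param stressor \code{"cold"} or \code{"desiccation"}
#' @param foldChange fold-change threshold (on the natural, not log, scale)
#' @param pValue p-value threshold
#' @param fdr FDR threshold (Benjamini-Hochberg)
#' @param eps pseudocount added to condition means for the fold change
#' @return data.frame with one row per transcript: \code{transcript_id},
#'   \code{stressor}, \code{log2_fold_change}, \code{p_value}, \code{fdr},
#'   \code{class} in \{up, down, not_regulated\}
#' @export
classifyRegulation <- function(lab, stressor, foldChange = 2,
                               pValue = 0.05, fdr = 0.05, eps = 0.5) {
    stressor <- .checkStressor(stressor)
    counts <- abundances(lab)
    if (nrow(counts) == 0 || ncol(counts) == 0) stop("empty count matrix")
    cond <- sampleConditions(lab)
    sc <- .stressCondition(stressor)
    nCtrl <- sum(cond == "control"); nStr <- sum(cond == sc)
    if (nCtrl < 2 || nStr < 2)
        stop(sprintf("need >= 2 replicates of control and %s (found %d, %d)",
                     sc, nCtrl, nStr))
    scaled <- .libraryScale(counts)
    ctrl <- scaled[, cond == "control", drop = FALSE]
    stress <- scaled[, cond == sc, drop = FALSE]
    l2fc <- log2((rowMeans(stress) + eps) / (rowMeans(ctrl) + eps))
    p <- .welchTest(log2(stress + 1), log2(ctrl + 1))
    q <- stats::p.adjust(p, method = "BH")
    cls <- rep("not_regulated", nrow(counts))
    hit <- p < pValue & q < fdr
    cls[hit & l2fc > log2(foldChange)] <- "up"
    cls[hit & l2fc < -log2(foldChange)] <- "down"
    res <- data.frame(transcript_id = rownames(counts), stressor = stressor,
                      log2_fold_change = as.numeric(l2fc),
                      p_value = as.numeric(p), fdr = as.numeric(q),
                      class = cls, stringsAsFactors = FALSE)
    rownames(res) <- NULL
    attr(res, "thresholds") <- list(fold_change = foldChange, p_value = pValue,
                                    fdr = fdr, eps = eps)
    res
}

#' Read a precomputed differential-expression table
#'
#' Accepts a TSV with columns \code{transcript_id}, \code{stressor},
#' \code{log2_fold_change}, \code{p_value}, \code{fdr} — e.g. exported from a
#' dedicated differential-expression package — and assigns regulation classes
#' at the same thresholds \code{\link{classifyRegulation}} uses.
#'
#' @param path TSV path
#' @inheritParams classifyRegulation
#' @return data.frame in the \code{\link{classifyRegulation}} layout
#' @export
readRegulationTable <- function(path, foldChange = 2, pValue = 0.05,
                                fdr = 0.05) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("transcript_id", "stressor", "log2_fold_change", "p_value", "fdr")
    miss <- setdiff(need, colnames(tab))
    if (length(miss))
        stop("regulation table lacks column(s): ", paste(miss, collapse = ", "))
    cls <- rep("not_regulated", nrow(tab))
    hit <- tab$p_value < pValue & tab$fdr < fdr
    cls[hit & tab$log2_fold_change > log2(foldChange)] <- "up"
    cls[hit & tab$log2_fold_change < -log2(foldChange)] <- "down"
    tab$class <- cls
    attr(tab, "thresholds") <- list(fold_change = foldChange, p_value = pValue,
                                    fdr = fdr)
    tab[c(need, "class")]
}

#' Find constantly expressed transcripts
#'
#' A transcript qualifies as constantly expressed (housekeeping-like ratio
#' denominator) when it is \code{not_regulated} under both stressors, its
#' |log2 fold change| stays below \code{stabilityThreshold} under both, and
#' its mean abundance is nonzero in every lab condition.
#'
#' @param recordsCold,recordsDes classification tables from
#'   \code{\link{classifyRegulation}} for the two stressors, from the same lab
#'   matrix
#' @param lab the lab \linkS4class{CountMatrix}
#' @param stabilityThreshold bound on |log2 fold change| under either stressor
#' @return character vector of transcript ids
#' @export
findConstant <- function(recordsCold, recordsDes, lab,
                         stabilityThreshold = 0.5) {
    if (!setequal(recordsCold$transcript_id, recordsDes$transcript_id))
        stop("records must cover the same transcript universe")
    recordsDes <- recordsDes[match(recordsCold$transcript_id,
                                   recordsDes$transcript_id), ]
    stable <- recordsCold$class == "not_regulated" &
        recordsDes$class == "not_regulated" &
        abs(recordsCold$log2_fold_change) < stabilityThreshold &
        abs(recordsDes$log2_fold_change) < stabilityThreshold
    counts <- abundances(lab)
    cond <- sampleConditions(lab)
    condMeans <- vapply(unique(cond), function(cc)
        rowMeans(counts[, cond == cc, drop = FALSE]), numeric(nrow(counts)))
    expressed <- rownames(counts)[rowSums(condMeans == 0) == 0]
    intersect(recordsCold$transcript_id[stable], expressed)
}

#' Build the stressor-specific marker catalog
#'
#' Partitions regulated transcripts into cold-specific, desiccation-specific
#' and dual-regulated sets — only single-stressor transcripts enter index
#' calculation; dual ones are retained for the wider clustering dataset — and
#' attaches the constantly expressed set.
#'
#' @param recordsCold,recordsDes classification tables from
#'   \code{\link{classifyRegulation}}
#' @param constantIds constantly expressed transcript ids, e.g. from
#'   \code{\link{findConstant}}; must not overlap any regulated set
#' @return a \linkS4class{MarkerCatalog}
#' @export
buildCatalog <- function(recordsCold, recordsDes, constantIds = character()) {
    regOf <- function(rec) rec[rec$class %in% c("up", "down"), , drop = FALSE]
    rc <- regOf(recordsCold); rd <- regOf(recordsDes)
    dual <- intersect(rc$transcript_id, rd$transcript_id)
    coldOnly <- rc[!rc$transcript_id %in% dual, , drop = FALSE]
    desOnly <- rd[!rd$transcript_id %in% dual, , drop = FALSE]
    bad <- intersect(constantIds,
                     union(rc$transcript_id, rd$transcript_id))
    if (length(bad))
        stop("constant transcripts overlap regulated sets: ",
             paste(bad, collapse = ", "))
    regulated <- data.frame(
        transcript_id = c(coldOnly$transcript_id, desOnly$transcript_id),
        stressor = rep(c("cold", "desiccation"),
                       c(nrow(coldOnly), nrow(desOnly))),
        direction = c(coldOnly$class, desOnly$class),
        stringsAsFactors = FALSE)
    thr <- attr(recordsCold, "thresholds")
    MarkerCatalog(regulated, dual = dual, constant = as.character(constantIds),
                  thresholds = if (is.null(thr)) list() else thr)
}

#' Tabulate regulated-transcript counts per stressor
#'
#' @param records one or more classification tables (rows bound together)
#' @return data.frame(stressor, up, down)
#' @export
summarizeRegulation <- function(records) {
    if (is.list(records) && !is.data.frame(records))
        records <- do.call(rbind, records)
    res <- do.call(rbind, lapply(split(records, records$stressor), function(r)
        data.frame(stressor = r$stressor[1],
                   up = sum(r$class == "up"),
                   down = sum(r$class == "down"),
                   stringsAsFactors = FALSE)))
    rownames(res) <- NULL
    if (is.null(res))
        res <- data.frame(stressor = character(), up = integer(),
                          down = integer())
    res
}
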