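# fixed TSV dialect: UTF-8, tab-separated, '.' decimal, 9 significant digits
.fmtNum <- function(x) {
    ifelse(is.na(x), "NA",
           ifelse(x == round(x) & abs(x) < 1e15,
                  sprintf("%.0f", x), sprintf("%.9g", x)))
}

.writeTsv <- function(df, path) {
    out <- df
    for (j in seq_along(out))
        if (is.numeric(out[[j]])) out[[j]] <- .fmtNum(out[[j]])
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Read a transcript count table with sample metadata
#'
#' The count table is a TSV whose first column (\code{transcript_id}) holds
#' unique transcript identifiers and whose remaining columns are samples; the
#' metadata TSV has columns \code{sample_id}, \code{condition}, \code{site},
#' \code{replicate}. The two files must describe exactly the same samples.
#'
#' @param path count-table TSV path
#' @param metadataPath sample-metadata TSV path
#' @return a validated \linkS4class{CountMatrix}
#' @export
readCounts <- function(path, metadataPath) {
    if (!file.exists(path)) stop("count file not found: ", path)
    if (!file.exists(metadataPath))
        stop("metadata file not found: ", metadataPath)
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (colnames(tab)[1] != "transcript_id")
        stop("first column must be 'transcript_id'")
    ids <- tab$transcript_id
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
        stop("duplicated transcript id(s): ", paste(dup, collapse = ", "))
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- ids
    if (any(m < 0)) stop("negative abundance values in ", path)
    meta <- utils::read.delim(metadataPath, stringsAsFactors = FALSE)
    need <- c("sample_id", "condition", "site", "replicate")
    miss <- setdiff(need, colnames(meta))
    if (length(miss))
        stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
    extra <- setdiff(meta$sample_id, colnames(m))
    missing <- setdiff(colnames(m), meta$sample_id)
    if (length(extra) || length(missing))
        stop("sample mismatch between counts and metadata; ",
             "unknown in matrix: [", paste(extra, collapse = ", "),
             "]; without metadata: [", paste(missing, collapse = ", "), "]")
    meta <- meta[match(colnames(m), meta$sample_id), ]
    extraCols <- setdiff(colnames(meta), need)
    do.call(CountMatrix,
            c(list(counts = m, condition = meta$condition, site = meta$site,
                   replicate = meta$replicate),
              as.list(meta[extraCols])))
}

#' Write a CountMatrix (and its sample metadata) as TSV
#'
#' @param x a \linkS4class{CountMatrix}
#' @param path output path for the count table
#' @param metadataPath optional output path for the sample metadata
#' @return \code{path}, invisibly
#' @export
writeCounts <- function(x, path, metadataPath = NULL) {
    df <- data.frame(transcript_id = rownames(x), abundances(x),
                     check.names = FALSE, stringsAsFactors = FALSE)
    .writeTsv(df, path)
    if (!is.null(metadataPath)) {
        cd <- as.data.frame(colData(x))
        meta <- data.frame(sample_id = rownames(cd), cd, row.names = NULL,
                           check.names = FALSE)
        .writeTsv(meta, metadataPath)
    }
    invisible(path)
}

#' Read a 12-column BLAST tabular (outfmt 6) hit file
#'
#' Columns: qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend,
#' sstart, send, evalue, bitscore. Comment lines starting with \code{#} are
#' skipped; scientific-notation e-values are parsed; a row with the wrong
#' number of columns raises an error naming its line.
#'
#' @param path hit-file path
#' @return data.frame of typed hits
#' @export
readBlastTab <- function(path) {
    if (!file.exists(path)) stop("hit file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    keep <- !startsWith(lines, "#") & nzchar(lines)
    lineNo <- which(keep)
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    bad <- which(lengths(fields) != 12L)
    if (length(bad))
        stop(sprintf("line %d: expected 12 tab-separated columns, found %d",
                     lineNo[bad[1]], lengths(fields)[bad[1]]))
    if (length(fields) == 0) {
        out <- as.data.frame(matrix(nrow = 0, ncol = 12))
        colnames(out) <- .blastColumns
        return(out)
    }
    m <- do.call(rbind, fields)
    out <- data.frame(qseqid = m[, 1], sseqid = m[, 2],
                      pident = as.numeric(m[, 3]),
                      length = as.integer(m[, 4]),
                      mismatch = as.integer(m[, 5]),
                      gapopen = as.integer(m[, 6]),
                      qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
                      sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
                      evalue = as.numeric(m[, 11]),
                      bitscore = as.numeric(m[, 12]),
                      stringsAsFactors = FALSE)
    badNum <- which(!is.finite(out$pident) | !is.finite(out$evalue))
    if (length(badNum))
        stop(sprintf("line %d: unparseable pident/evalue", lineNo[badNum[1]]))
    out
}

#' Write hits in BLAST outfmt-6 layout
#'
#' @param hits data.frame with the 12 outfmt-6 columns
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeBlastTab <- function(hits, path) {
    miss <- setdiff(.blastColumns, colnames(hits))
    if (length(miss))
        stop("hit table lacks column(s): ", paste(miss, collapse = ", "))
    out <- hits[.blastColumns]
    out$evalue <- sprintf("%.3g", out$evalue)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE,
                       fileEncoding = "UTF-8")
    invisible(path)
}
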