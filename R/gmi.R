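#' Enumerate marker pairs for a stressor
#'
#' The full Cartesian product of the stressor's single-stressor-regulated
#' transcripts with its constantly expressed transcripts; one index is later
#' evaluated per pair. The pair count is |regulated| x |constant| (e.g. 11
#' regulated x 13 constant = 143 pairs).
#'
#' @param catalog a \linkS4class{MarkerCatalog}
#' @param stressor \code{"cold"} or \code{"desiccation"}
#' @return data.frame(pair_index, regulated_id, constant_id, stressor,
#'   direction)
#' @export
enumeratePairs <- function(catalog, stressor) {
    stressor <- .checkStressor(stressor)
    reg <- regulatedMarkers(catalog, stressor)
    const <- constantMarkers(catalog, stressor)
    if (nrow(reg) == 0 || length(const) == 0)
        return(data.frame(pair_index = integer(), regulated_id = character(),
                          constant_id = character(), stressor = character(),
                          direction = character()))
    grid <- expand.grid(ri = seq_len(nrow(reg)), constant_id = const,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    data.frame(pair_index = seq_len(nrow(grid)),
               regulated_id = reg$transcript_id[grid$ri],
               constant_id = grid$constant_id,
               stressor = stressor,
               direction = reg$direction[grid$ri],
               stringsAsFactors = FALSE)
}

#' Lab ratio bounds for every marker pair
#'
#' For each (regulated r, constant c) pair the control-condition bound is
#' \eqn{X_{min} = \bar r_{ctrl} / \bar c_{ctrl}} and the treatment-condition
#' bound is \eqn{X_{max} = \bar r_{stress} / \bar c_{stress}}, with means
#' taken over the replicates of the named condition (ratio of replicate-mean
#' abundances: stabler at low counts than the mean of per-replicate ratios,
#' and it makes linear index recovery exact in expectation). Pairs with a
#' zero denominator mean, a nonpositive or nonfinite ratio, or
#' \eqn{|X_{max} - X_{min}|} below \code{delta} are dropped with a recorded
#' reason.
#'
#' @param labNormalized the lab \linkS4class{CountMatrix} after
#'   \code{\link{normalizeRelative}}
#' @param catalog a \linkS4class{MarkerCatalog}
#' @param stressor \code{"cold"} or \code{"desiccation"}
#' @param delta degeneracy tolerance on \eqn{|X_{max} - X_{min}|}
#' @return data.frame(pair_index, regulated_id, constant_id, stressor,
#'   direction, x_min, x_max); dropped pairs with reasons in
#'   \code{attr(, "dropped")}
#' @export
computePairBounds <- function(labNormalized, catalog, stressor, delta = 1e-9) {
    stressor <- .checkStressor(stressor)
    counts <- abundances(labNormalized)
    cond <- sampleConditions(labNormalized)
    sc <- .stressCondition(stressor)
    if (!any(cond == "control") || !any(cond == sc))
        stop("lab matrix lacks control or ", sc, " replicates")
    pairs <- enumeratePairs(catalog, stressor)
    ids <- union(pairs$regulated_id, pairs$constant_id)
    absent <- setdiff(ids, rownames(counts))
    if (length(absent))
        stop("catalog transcript(s) absent from lab matrix: ",
             paste(utils::head(absent, 5), collapse = ", "))
    mCtrl <- rowMeans(counts[, cond == "control", drop = FALSE])
    mStr <- rowMeans(counts[, cond == sc, drop = FALSE])
    xMin <- mCtrl[pairs$regulated_id] / mCtrl[pairs$constant_id]
    xMax <- mStr[pairs$regulated_id] / mStr[pairs$constant_id]
    reason <- rep(NA_character_, nrow(pairs))
    zeroDen <- mCtrl[pairs$constant_id] == 0 | mStr[pairs$constant_id] == 0
    reason[zeroDen] <- "zero_constant_mean"
    badRatio <- is.na(reason) &
        (!is.finite(xMin) | !is.finite(xMax) | xMin <= 0 | xMax <= 0)
    reason[badRatio] <- "nonpositive_ratio"
    degen <- is.na(reason) & abs(xMax - xMin) < delta
    reason[degen] <- "degenerate_bounds"
    keep <- is.na(reason)
    dropped <- cbind(pairs[!keep, , drop = FALSE],
                     reason = reason[!keep])
    if (nrow(dropped))
        message(nrow(dropped), " pair(s) dropped (",
                paste(unique(dropped$reason), collapse = ", "), ")")
    out <- pairs[keep, , drop = FALSE]
    out$x_min <- as.numeric(xMin[keep])
    out$x_max <- as.numeric(xMax[keep])
    rownames(out) <- NULL
    attr(out, "dropped") <- dropped
    out
}

.gmiCategory <- function(gmi) {
    ifelse(gmi < 0, "below_range",
    ifelse(gmi > 100, "above_range",
    ifelse(gmi < 25, "q1", ifelse(gmi < 50, "q2",
    ifelse(gmi < 75, "q3", "q4")))))
}

#' Evaluate Gene Marker Indices on field samples
#'
#' For pair i and a field sample, \eqn{X_i} is the ratio of the regulated
#' transcript's abundance to the constant transcript's abundance, and
#' \deqn{GMI_i = (X_i - X_{i,min}) / (X_{i,max} - X_{i,min}) \times 100,}
#' the field ratio expressed as a percentage of the lab control-to-treatment
#' effect. The same formula serves down-regulated markers (there
#' \eqn{X_{max} < X_{min}}, so a treatment-like ratio still maps to 100).
#' Values outside [0, 100] mean the field ratio fell below the lab control or
#' beyond the lab treatment. Records are skipped — not pseudocounted, which
#' preserves exact per-sample scale invariance — when the constant transcript
#' has zero abundance, or when either transcript is absent from the table.
#'
#' @param pairs pair table from \code{\link{computePairBounds}}
#' @param fieldNormalized field abundances after \code{\link{normalizeRelative}}
#'   (\linkS4class{CountMatrix} or matrix)
#' @param samples sample ids to evaluate (default: all columns)
#' @return data.frame(pair_index, regulated_id, constant_id, direction,
#'   sample_id, x_i, gmi, category) with category in \{below_range, q1, q2,
#'   q3, q4, above_range\}; skipped records with reasons in
#'   \code{attr(, "skipped")}
#' @export
computeGMI <- function(pairs, fieldNormalized, samples = NULL) {
    counts <- abundances(fieldNormalized)
    if (is.null(samples)) samples <- colnames(counts)
    stopifnot(all(samples %in% colnames(counts)))
    if (nrow(pairs) == 0) stop("no marker pairs supplied")
    present <- rownames(counts)
    regAbsent <- !pairs$regulated_id %in% present
    constAbsent <- !pairs$constant_id %in% present
    usable <- !(regAbsent | constAbsent)

    res <- list(); skipped <- list()
    for (s in samples) {
        v <- counts[, s]
        p <- pairs[usable, , drop = FALSE]
        cAb <- v[p$constant_id]
        rAb <- v[p$regulated_id]
        zeroC <- cAb == 0
        xi <- rAb[!zeroC] / cAb[!zeroC]
        pk <- p[!zeroC, , drop = FALSE]
        gmi <- (xi - pk$x_min) / (pk$x_max - pk$x_min) * 100
        res[[s]] <- data.frame(pair_index = pk$pair_index,
                               regulated_id = pk$regulated_id,
                               constant_id = pk$constant_id,
                               direction = pk$direction,
                               sample_id = s, x_i = as.numeric(xi),
                               gmi = as.numeric(gmi),
                               category = .gmiCategory(as.numeric(gmi)),
                               stringsAsFactors = FALSE)
        skipIdx <- c(pairs$pair_index[regAbsent],
                     pairs$pair_index[constAbsent & !regAbsent],
                     p$pair_index[zeroC])
        skipped[[s]] <- data.frame(
            pair_index = skipIdx,
            sample_id = rep(s, length(skipIdx)),
            reason = c(rep("regulated_absent", sum(regAbsent)),
                       rep("constant_absent", sum(constAbsent & !regAbsent)),
                       rep("zero_constant_abundance", sum(zeroC))),
            stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    attr(out, "skipped") <- do.call(rbind, c(skipped, make.row.names = FALSE))
    out
}

#' Summarize a set of GMI evaluations
#'
#' Counts records per category, splits the out-of-range fraction into
#' below-control and above-treatment parts, reports mean and standard
#' deviation of the in-range (0-100) values, and tabulates how often each
#' transcript participates in an in-range record — the transcript-reliability
#' view used to judge individual markers.
#'
#' @param records record table from \code{\link{computeGMI}}
#' @return object of class \code{GMISummary}: a list with \code{n_total},
#'   \code{n_in_range}, \code{fraction_below}, \code{fraction_above},
#'   \code{in_range_mean}, \code{in_range_sd}, \code{category_counts},
#'   \code{transcript_frequency} and \code{n_skipped}
#' @export
summarizeGMI <- function(records) {
    if (is.null(records) || nrow(records) == 0) stop("no GMI records")
    inRange <- records$gmi >= 0 & records$gmi <= 100
    cats <- factor(records$category,
                   levels = c("below_range", "q1", "q2", "q3", "q4",
                              "above_range"))
    ir <- records[inRange, , drop = FALSE]
    freq <- rbind(
        data.frame(transcript_id = ir$regulated_id, role = "regulated"),
        data.frame(transcript_id = ir$constant_id, role = "constant"))
    freq <- as.data.frame(table(freq$transcript_id, freq$role),
                          stringsAsFactors = FALSE)
    names(freq) <- c("transcript_id", "role", "n_in_range")
    freq <- freq[freq$n_in_range > 0, , drop = FALSE]
    rownames(freq) <- NULL
    skipped <- attr(records, "skipped")
    structure(list(
        n_total = nrow(records),
        n_in_range = sum(inRange),
        fraction_below = mean(records$gmi < 0),
        fraction_above = mean(records$gmi > 100),
        in_range_mean = mean(ir$gmi),
        in_range_sd = stats::sd(ir$gmi),
        in_range_median = stats::median(ir$gmi),
        category_counts = table(cats),
        transcript_frequency = freq,
        n_skipped = if (is.null(skipped)) 0L else nrow(skipped)),
        class = "GMISummary")
}

#' @export
print.GMISummary <- function(x, ...) {
    cat(sprintf(
        "GMI summary: %d records, %d in range (mean %.1f%%, SD %.1f%%)\n",
        x$n_total, x$n_in_range, x$in_range_mean, x$in_range_sd))
    cat(sprintf("  out of range: %.1f%% below control, %.1f%% above treatment\n",
                100 * x$fraction_below, 100 * x$fraction_above))
    if (x$n_skipped)
        cat("  skipped records:", x$n_skipped, "\n")
    invisible(x)
}
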