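# Independent oracles, kept deliberately naive.

# Bray-Curtis by an explicit double loop over sample pairs
bruteBray <- function(m) {
    k <- ncol(m)
    D <- matrix(0, k, k, dimnames = list(colnames(m), colnames(m)))
    for (i in seq_len(k)) {
        for (j in seq_len(k)) {
            D[i, j] <- sum(abs(m[, i] - m[, j])) / sum(m[, i] + m[, j])
        }
    }
    D
}

# Naive agglomerative Ward.D2 via the Lance-Williams update; returns, per
# merge step, the height and the set of leaf labels of the newly formed
# cluster (a coding-independent description of the merge order).
wardOracle <- function(D) {
    d <- as.matrix(D)
    labels <- rownames(d)
    sizes <- rep(1, nrow(d))
    members <- as.list(labels)
    heights <- numeric(0)
    formed <- list()
    while (nrow(d) > 1) {
        dm <- d; diag(dm) <- Inf
        idx <- which(dm == min(dm), arr.ind = TRUE)
        idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
        i <- min(idx); j <- max(idx)
        heights <- c(heights, d[i, j])
        formed[[length(formed) + 1]] <- sort(c(members[[i]], members[[j]]))
        ni <- sizes[i]; nj <- sizes[j]
        upd <- vapply(seq_len(nrow(d)), function(mm) {
            if (mm == i || mm == j) return(0)
            nm <- sizes[mm]
            sqrt(((ni + nm) * d[i, mm]^2 + (nj + nm) * d[j, mm]^2 -
                  nm * d[i, j]^2) / (ni + nj + nm))
        }, numeric(1))
        d[i, ] <- upd; d[, i] <- upd; d[i, i] <- 0
        d <- d[-j, -j, drop = FALSE]
        members[[i]] <- formed[[length(formed)]]
        members <- members[-j]
        sizes[i] <- ni + nj; sizes <- sizes[-j]
    }
    list(heights = heights, formed = formed)
}

# member leaf sets per merge step of an hclust tree
hclustMergeSets <- function(tree) {
    members <- vector("list", nrow(tree$merge))
    for (i in seq_len(nrow(tree$merge))) {
        get <- function(k) if (k < 0) tree$labels[-k] else members[[k]]
        members[[i]] <- sort(c(get(tree$merge[i, 1]), get(tree$merge[i, 2])))
    }
    members
}

# small scenario used across tests
tinyScenario <- function(...) {
    args <- utils::modifyList(
        list(nTranscripts = 400, nUpCold = 15, nDownCold = 15,
             nUpDes = 15, nDownDes = 15, nConstant = 25,
             foldChangeRange = c(4, 8), nReplicates = 3,
             dispersion = 0.05, librarySizeRange = c(2e5, 3e5), seed = 11L),
        list(...))
    do.call(SyntheticScenario, args)
}

# lab matrix built directly from fixed per-condition means, Poisson-free
meansMatrix <- function(means, nrep = 3, ids = NULL) {
    # means: matrix transcripts x 3 (control, cold, desiccated)
    counts <- means[, rep(1:3, each = nrep), drop = FALSE]
    if (is.null(ids)) ids <- sprintf("g%03d", seq_len(nrow(means)))
    dimnames(counts) <- list(ids, paste0(rep(c("ctrl", "cold", "des"),
                                             each = nrep), "_",
                                         rep(seq_len(nrep), 3)))
    CountMatrix(counts,
                condition = rep(c("control", "cold", "desiccated"),
                                each = nrep),
                site = "lab", replicate = rep(seq_len(nrep), 3))
}
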