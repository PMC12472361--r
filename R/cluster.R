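#' Assemble a lab-plus-field matrix over a marker transcript set
#'
#' Combines the lab replicates of the control and stress conditions with all
#' field replicates, restricted to a transcript set, and renormalizes every
#' column to relative abundances. Two standard variants: \code{dataset1} uses
#' only the transcripts regulated by exactly the named stressor (the ones
#' entering index calculation); \code{dataset2} uses all regulated
#' transcripts, including dual-regulated ones, and is therefore a superset.
#'
#' @param catalog a \linkS4class{MarkerCatalog}
#' @param fieldTable field \linkS4class{CountMatrix} over reference transcript
#'   ids (e.g. from \code{\link{mapToReference}})
#' @param labMatrix lab \linkS4class{CountMatrix}
#' @param variant \code{"dataset1"} or \code{"dataset2"}
#' @param stressor \code{"cold"} or \code{"desiccation"}
#' @param transcripts optional explicit transcript set overriding the variant;
#'   every listed transcript must be present in both tables
#' @return a combined, column-normalized \linkS4class{CountMatrix}
#' @export
buildDataset <- function(catalog, fieldTable, labMatrix,
                         variant = c("dataset1", "dataset2"), stressor,
                         transcripts = NULL) {
    variant <- match.arg(variant)
    stressor <- .checkStressor(stressor)
    labCounts <- abundances(labMatrix)
    fieldCounts <- abundances(fieldTable)
    if (is.null(transcripts)) {
        ids <- if (variant == "dataset1") {
            regulatedMarkers(catalog, stressor)$transcript_id
        } else {
            union(catalog@regulated$transcript_id, dualMarkers(catalog))
        }
        ids <- intersect(ids, intersect(rownames(labCounts),
                                        rownames(fieldCounts)))
        if (length(ids) == 0)
            stop("no catalog transcript present in both lab and field tables")
    } else {
        absent <- setdiff(transcripts,
                          intersect(rownames(labCounts), rownames(fieldCounts)))
        if (length(absent))
            stop("transcript(s) absent from lab or field table: ",
                 paste(absent, collapse = ", "))
        ids <- transcripts
    }
    sc <- .stressCondition(stressor)
    labKeep <- sampleConditions(labMatrix) %in% c("control", sc)
    combined <- cbind(labCounts[ids, labKeep, drop = FALSE],
                      fieldCounts[ids, , drop = FALSE])
    cm <- CountMatrix(combined,
                      condition = c(sampleConditions(labMatrix)[labKeep],
                                    sampleConditions(fieldTable)),
                      site = c(sampleSites(labMatrix)[labKeep],
                               sampleSites(fieldTable)),
                      replicate = c(colData(labMatrix)$replicate[labKeep],
                                    colData(fieldTable)$replicate))
    normalizeRelative(cm)
}

#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{D(j,k) = \sum_t |x_{tj} - x_{tk}| / \sum_t (x_{tj} + x_{tk})} over
#' transcripts, bounded in [0, 1], zero between identical samples and one
#' between samples with disjoint support. Note that Bray-Curtis on raw counts
#' is sensitive to library size; normalize to relative abundances first.
#'
#' @param x a \linkS4class{CountMatrix} or matrix (transcripts x samples)
#' @return symmetric dissimilarity matrix with zero diagonal
#' @export
brayCurtis <- function(x) {
    m <- abundances(x)
    if (any(m < 0)) stop("negative abundances")
    zero <- colSums(m) == 0
    if (sum(zero) >= 2)
        stop("Bray-Curtis undefined between all-zero samples: ",
             paste(colnames(m)[zero], collapse = ", "))
    D <- as.matrix(vegan::vegdist(t(m), method = "bray"))
    dimnames(D) <- list(colnames(m), colnames(m))
    D
}

#' Ward.D2 hierarchical clustering of a dissimilarity matrix
#'
#' Agglomerative clustering with the Ward.D2 criterion (the Lance-Williams
#' update applied to squared dissimilarities under a square root). The method
#' is routinely applied to Bray-Curtis input although Bray-Curtis is not
#' Euclidean; heights are then conventional merge costs, not variances — a
#' caveat, not an error.
#'
#' @param D symmetric dissimilarity matrix (zero diagonal) or \code{dist}
#' @return an \code{hclust} tree
#' @export
wardCluster <- function(D) {
    if (!inherits(D, "dist")) {
        D <- as.matrix(D)
        if (!isSymmetric(unname(D), tol = 1e-8))
            stop("dissimilarity matrix must be symmetric")
        if (any(abs(diag(D)) > 1e-12))
            stop("dissimilarity matrix must have a zero diagonal")
        D <- stats::as.dist(D)
    }
    stats::hclust(D, method = "ward.D2")
}

# sorted pairwise Bray-Curtis similarities of the columns of x
.similarityProfile <- function(x) {
    num <- as.vector(stats::dist(t(x), method = "manhattan"))
    tot <- colSums(x)
    pairSums <- outer(tot, tot, "+")
    den <- pairSums[lower.tri(pairSums)]
    s <- 1 - num / den
    s[den == 0] <- 1
    sort(s)
}

# reproducible per-group seed derived from the global seed and the sorted
# member names, so results do not depend on input sample order
.groupSeed <- function(seed, members) {
    key <- paste(sort(members), collapse = "|")
    h <- sum(utf8ToInt(key) * seq_len(nchar(key))) %% 1048573L
    (as.integer(seed) + 7919L * h) %% 2147483647L
}

# SIMPROF test of one group: pi statistic and permutation p-value
.simprofGroup <- function(x, nExpected, nSimulated, seed) {
    x <- x[order(rownames(x)), order(colnames(x)), drop = FALSE]
    set.seed(.groupSeed(seed, colnames(x)))
    obs <- .similarityProfile(x)
    k <- ncol(x)
    B <- nExpected + nSimulated
    profiles <- matrix(0, length(obs), B)
    for (b in seq_len(B)) {
        xp <- x
        for (t in seq_len(nrow(x))) xp[t, ] <- x[t, sample.int(k)]
        profiles[, b] <- .similarityProfile(xp)
    }
    meanNull <- rowMeans(profiles[, seq_len(nExpected), drop = FALSE])
    piObs <- sum(abs(obs - meanNull))
    piNull <- colSums(abs(profiles[, nExpected + seq_len(nSimulated),
                                   drop = FALSE] - meanNull))
    list(pi = piObs,
         p = (sum(piNull >= piObs) + 1) / (nSimulated + 1))
}

#' Similarity-profile (SIMPROF) test with recursive cluster pruning
#'
#' Tests whether groups of samples carry more multivariate structure than
#' expected under independent permutation of each transcript across the
#' group's samples. The observed profile is the sorted vector of pairwise
#' Bray-Curtis similarities; its departure \eqn{\pi = \sum_k |obs_k -
#' \overline{null}_k|} from the mean of \code{nExpected} permutation profiles
#' is referred to \code{nSimulated} further permutations, with the add-one
#' rule \eqn{p = (\#\{\pi_{null} \ge \pi_{obs}\} + 1) / (nSimulated + 1)} so p
#' is never exactly zero. Starting from the root of the Ward.D2 dendrogram,
#' only children of significant nodes are tested (groups smaller than 3 are
#' terminal); the maximal groups without detectable structure are reported as
#' the significant partition.
#'
#' @param x matrix or \linkS4class{CountMatrix} (transcripts x samples),
#'   typically relative abundances from \code{\link{buildDataset}}
#' @param alpha per-node significance level in (0, 1)
#' @param nExpected permutations defining the expected null profile
#' @param nSimulated permutations for the p-value
#' @param seed integer seed; each tested group draws from a stream derived
#'   from the seed and its (sorted) member names, so results are invariant to
#'   input sample order
#' @return a \linkS4class{SimprofResult}
#' @export
simprof <- function(x, alpha = 0.05, nExpected = 999, nSimulated = 999,
                    seed = 1L) {
    if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
    m <- abundances(x)
    if (ncol(m) < 2) stop("need at least two samples")
    tree <- wardCluster(brayCurtis(m))
    merge <- tree$merge
    labels <- tree$labels
    members <- vector("list", nrow(merge))
    for (i in seq_len(nrow(merge))) {
        get <- function(k) if (k < 0) labels[-k] else members[[k]]
        members[[i]] <- c(get(merge[i, 1]), get(merge[i, 2]))
    }
    tests <- data.frame(node = seq_len(nrow(merge)),
                        n = lengths(members), pi = NA_real_,
                        p_value = NA_real_, tested = FALSE,
                        significant = FALSE)
    clusters <- list()
    visit <- function(k) {
        if (k < 0) {                               # leaf split off by a
            clusters[[length(clusters) + 1]] <<- labels[-k]  # significant node
            return(invisible())
        }
        grp <- members[[k]]
        if (length(grp) < 3) {                     # too small to test
            clusters[[length(clusters) + 1]] <<- grp
            return(invisible())
        }
        res <- .simprofGroup(m[, grp, drop = FALSE], nExpected, nSimulated,
                             seed)
        tests$pi[k] <<- res$pi
        tests$p_value[k] <<- res$p
        tests$tested[k] <<- TRUE
        if (res$p <= alpha) {
            tests$significant[k] <<- TRUE
            visit(merge[k, 1])
            visit(merge[k, 2])
        } else {
            clusters[[length(clusters) + 1]] <<- grp
        }
        invisible()
    }
    visit(nrow(merge))
    new("SimprofResult", tree = tree, tests = tests, clusters = clusters,
        alpha = alpha, nExpected = nExpected, nSimulated = nSimulated,
        seed = as.numeric(seed))
}

.newickQuote <- function(s) {
    if (grepl("[][ ():;,']", s))
        paste0("'", gsub("'", "''", s, fixed = TRUE), "'")
    else s
}

#' Serialize a dendrogram as annotated Newick text
#'
#' Branch lengths are height differences between a node and its parent;
#' internal nodes tested by SIMPROF carry a \code{p=<value>} label. Leaf
#' names containing spaces or Newick metacharacters are single-quoted. The
#' output round-trips through standard Newick parsers.
#'
#' @param tree an \code{hclust} tree (e.g. from \code{\link{wardCluster}})
#' @param simprofResult optional \linkS4class{SimprofResult} supplying
#'   per-node p-values
#' @return a single Newick string, terminated by \code{";"}
#' @export
renderNewick <- function(tree, simprofResult = NULL) {
    stopifnot(inherits(tree, "hclust"))
    merge <- tree$merge; h <- tree$height; labels <- tree$labels
    pv <- rep(NA_real_, nrow(merge))
    if (!is.null(simprofResult)) {
        tst <- simprofTests(simprofResult)
        pv[tst$node[tst$tested]] <- tst$p_value[tst$tested]
    }
    fmt <- function(v) sprintf("%.9g", v)
    nodeLabel <- function(k)
        if (is.na(pv[k])) "" else sprintf("p=%.4g", pv[k])
    rec <- function(k, parentHeight) {
        if (k < 0)
            return(paste0(.newickQuote(labels[-k]), ":", fmt(parentHeight)))
        paste0("(", rec(merge[k, 1], h[k]), ",", rec(merge[k, 2], h[k]), ")",
               nodeLabel(k), ":", fmt(parentHeight - h[k]))
    }
    root <- nrow(merge)
    paste0("(", rec(merge[root, 1], h[root]), ",",
           rec(merge[root, 2], h[root]), ")", nodeLabel(root), ";")
}
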