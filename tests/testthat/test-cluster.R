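test_that("Bray-Curtis agrees with a brute-force double loop", {
    set.seed(101)
    for (rep in 1:5) {
        m <- matrix(runif(30, 0, 10), nrow = 5,
                    dimnames = list(paste0("t", 1:5), paste0("s", 1:6)))
        expect_equal(brayCurtis(m), bruteBray(m), tolerance = 1e-12)
    }
})

test_that("Bray-Curtis has its defining endpoint and bound properties", {
    m <- matrix(c(2, 2, 0, 0,
                  2, 2, 0, 0,
                  0, 0, 3, 1), nrow = 4,
                dimnames = list(paste0("t", 1:4), c("a", "b", "c")))
    D <- brayCurtis(m)
    expect_equal(D["a", "b"], 0)            # identical columns
    expect_equal(D["a", "c"], 1)            # disjoint support
    expect_true(all(D >= 0 & D <= 1))
    expect_equal(D, t(D))
    expect_equal(diag(D), c(a = 0, b = 0, c = 0))
    # raw (2,2) vs (1,1) differ by 1/3; after normalization they coincide
    m2 <- matrix(c(2, 2, 1, 1), 2, dimnames = list(c("t1", "t2"), c("x", "y")))
    expect_equal(brayCurtis(m2)["x", "y"], 1 / 3)
    expect_equal(brayCurtis(normalizeRelative(m2))["x", "y"], 0)
    expect_error(brayCurtis(matrix(c(0, 0, 0, 0), 2,
                                   dimnames = list(NULL, c("u", "v")))),
                 "all-zero")
})

test_that("Ward.D2 matches an independent Lance-Williams oracle", {
    set.seed(202)
    for (rep in 1:20) {
        m <- matrix(rlnorm(6 * 8), nrow = 8,
                    dimnames = list(paste0("t", 1:8), paste0("s", 1:6)))
        D <- brayCurtis(m)
        tree <- wardCluster(D)
        oracle <- wardOracle(D)
        expect_equal(hclustMergeSets(tree), oracle$formed)
        expect_equal(tree$height, oracle$heights, tolerance = 1e-10)
    }
})

test_that("Ward.D2 merges two samples at their distance, monotonically", {
    D <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("a", "b"),
                                                      c("a", "b")))
    tree <- wardCluster(D)
    expect_equal(tree$height, 0.4)
    # heights are non-decreasing on metric input
    set.seed(7)
    pts <- matrix(rnorm(14), ncol = 2)
    D2 <- as.matrix(dist(pts))
    expect_true(all(diff(wardCluster(D2)$height) >= -1e-12))
    expect_error(wardCluster(matrix(c(0, 1, 2, 0), 2)), "symmetric")
    expect_error(wardCluster(matrix(c(0.5, 1, 1, 0), 2,
                                    dimnames = list(c("a", "b"),
                                                    c("a", "b")))),
                 "zero diagonal")
})

test_that("identical samples give pi = 0, p = 1 and a single cluster", {
    m <- matrix(rep(c(5, 3, 2, 7), 4), nrow = 4,
                dimnames = list(paste0("t", 1:4), paste0("s", 1:4)))
    res <- simprof(m, nExpected = 49, nSimulated = 49, seed = 1)
    tst <- simprofTests(res)
    root <- tst[tst$node == max(tst$node), ]
    expect_equal(root$pi, 0)
    expect_equal(root$p_value, 1)
    expect_length(significantClusters(res), 1)
    expect_setequal(significantClusters(res)[[1]], paste0("s", 1:4))
})

test_that("a two-block structure is detected and recovered", {
    set.seed(33)
    blockA <- matrix(rlnorm(40, log(50), 0.1), nrow = 10)
    blockB <- matrix(rlnorm(40, log(50), 0.1), nrow = 10)
    m <- rbind(cbind(blockA, matrix(rlnorm(40, log(0.5), 0.1), nrow = 10)),
               cbind(matrix(rlnorm(40, log(0.5), 0.1), nrow = 10), blockB))
    dimnames(m) <- list(paste0("t", 1:20),
                        c(paste0("a", 1:4), paste0("b", 1:4)))
    res <- simprof(m, nExpected = 99, nSimulated = 99, seed = 5)
    tst <- simprofTests(res)
    root <- tst[tst$node == max(tst$node), ]
    expect_true(root$significant)
    expect_lte(root$p_value, 0.05)
    expect_true(any(vapply(significantClusters(res), setequal, logical(1),
                           paste0("a", 1:4))))
    expect_true(any(vapply(significantClusters(res), setequal, logical(1),
                           paste0("b", 1:4))))
})

test_that("simprof is deterministic under a seed and p is never zero", {
    set.seed(44)
    m <- matrix(rlnorm(48), nrow = 6,
                dimnames = list(paste0("t", 1:6), paste0("s", 1:8)))
    r1 <- simprof(m, nExpected = 49, nSimulated = 49, seed = 9)
    r2 <- simprof(m, nExpected = 49, nSimulated = 49, seed = 9)
    expect_identical(simprofTests(r1), simprofTests(r2))
    expect_identical(significantClusters(r1), significantClusters(r2))
    p <- simprofTests(r1)$p_value
    expect_true(all(p[!is.na(p)] > 0))
    expect_error(simprof(m, alpha = 1.2), "alpha")
})

test_that("results do not depend on input sample order", {
    set.seed(55)
    m <- matrix(rlnorm(48), nrow = 6,
                dimnames = list(paste0("t", 1:6), paste0("s", 1:8)))
    perm <- sample(ncol(m))
    r1 <- simprof(m, nExpected = 49, nSimulated = 49, seed = 9)
    r2 <- simprof(m[, perm], nExpected = 49, nSimulated = 49, seed = 9)
    canon <- function(cl) sort(vapply(cl, function(x)
        paste(sort(x), collapse = "+"), character(1)))
    expect_equal(canon(significantClusters(r1)),
                 canon(significantClusters(r2)))
    t1 <- simprofTests(r1); t2 <- simprofTests(r2)
    expect_equal(sort(t1$pi[t1$tested]), sort(t2$pi[t2$tested]))
    expect_equal(sort(t1$p_value[t1$tested]), sort(t2$p_value[t2$tested]))
})

test_that("groups smaller than three are terminal and untested", {
    m <- matrix(c(1, 1, 1.01, 1.01), nrow = 2,
                dimnames = list(c("t1", "t2"), c("x", "y")))
    res <- simprof(m, nExpected = 9, nSimulated = 9, seed = 1)
    expect_equal(sum(simprofTests(res)$tested), 0)
    expect_length(significantClusters(res), 1)
})

test_that("dataset 1 is a subset of dataset 2 and errors are named", {
    scn <- tinyScenario(dispersion = 0.01, nReplicates = 3, seed = 23L)
    sim <- simulateLabExperiment(scn)
    rc <- classifyRegulation(sim$counts, "cold")
    rd <- classifyRegulation(sim$counts, "desiccation")
    cat <- buildCatalog(rc, rd, findConstant(rc, rd, sim$counts))
    fld <- simulateFieldSamples(scn, sim$counts, sim$truth, "cold")
    fldN <- normalizeRelative(fld)
    d1 <- buildDataset(cat, fldN, sim$counts, "dataset1", "cold")
    d2 <- buildDataset(cat, fldN, sim$counts, "dataset2", "cold")
    expect_true(all(rownames(d1) %in% rownames(d2)))
    expect_gt(nrow(d2), nrow(d1))           # dual markers enter dataset 2
    expect_true(all(dualMarkers(cat) %in% rownames(d2)))
    expect_false(any(dualMarkers(cat) %in% rownames(d1)))
    expect_equal(unname(colSums(abundances(d1))), rep(1, ncol(d1)))
    # lab columns are control + stressor condition only, plus all field
    expect_setequal(unique(sampleConditions(d1)),
                    c("control", "cold", "field"))
    expect_error(buildDataset(cat, fldN, sim$counts, "dataset1", "cold",
                              transcripts = c("missing-one")),
                 "missing-one")
})

test_that("field samples at high latent stress cluster with lab stress", {
    scn <- tinyScenario(dispersion = 0.01, fieldDispersion = 0.02,
                        fieldStressLevels = c(0.9, 0.95, 0.9),
                        nReplicates = 3, seed = 29L)
    sim <- simulateLabExperiment(scn)
    rc <- classifyRegulation(sim$counts, "cold")
    rd <- classifyRegulation(sim$counts, "desiccation")
    cat <- buildCatalog(rc, rd, findConstant(rc, rd, sim$counts))
    fld <- simulateFieldSamples(scn, sim$counts, sim$truth, "cold")
    d1 <- buildDataset(cat, normalizeRelative(fld), sim$counts, "dataset1",
                       "cold")
    tree <- wardCluster(brayCurtis(d1))
    # the first split of the dendrogram separates control from
    # stress-plus-field
    side <- cutree(tree, 2)
    fieldSide <- unique(side[startsWith(names(side), "field")])
    coldSide <- unique(side[startsWith(names(side), "cold")])
    ctrlSide <- unique(side[startsWith(names(side), "ctrl")])
    expect_length(fieldSide, 1)
    expect_equal(fieldSide, coldSide, ignore_attr = TRUE)
    expect_false(fieldSide == ctrlSide)
})

test_that("newick output is well-formed, annotated and parseable", {
    D <- matrix(c(0, 0.6, 0.6, 0), 2, dimnames = list(c("A", "B"),
                                                      c("A", "B")))
    tree <- wardCluster(D)
    expect_equal(renderNewick(tree), "(A:0.6,B:0.6);")
    # round-trip: topology survives a standard parser
    set.seed(66)
    m <- matrix(rlnorm(42), nrow = 6,
                dimnames = list(paste0("t", 1:6), paste0("s", 1:7)))
    tr <- wardCluster(brayCurtis(m))
    parsed <- ape::read.tree(text = renderNewick(tr))
    expect_setequal(parsed$tip.label, tr$labels)
    expect_true(ape::all.equal.phylo(parsed, ape::as.phylo(tr),
                                     use.edge.length = FALSE))
    # simprof p-values are carried as node annotations
    res <- simprof(m, nExpected = 19, nSimulated = 19, seed = 2)
    expect_match(renderNewick(tr, res), "p=")
    # names with spaces are quoted
    D2 <- matrix(c(0, 0.5, 0.5, 0), 2,
                 dimnames = list(c("sample one", "B"), c("sample one", "B")))
    expect_match(renderNewick(wardCluster(D2)), "'sample one'", fixed = TRUE)
})
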