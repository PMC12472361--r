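test_that("flat transcripts are not regulated and have zero fold change", {
    means <- cbind(rep(50, 10), rep(50, 10), rep(50, 10))
    lab <- meansMatrix(means)
    rec <- classifyRegulation(lab, "cold")
    expect_true(all(rec$class == "not_regulated"))
    expect_equal(rec$log2_fold_change, rep(0, 10))
})

test_that("classification matches an independent Welch + BH oracle", {
    set.seed(42)
    n <- 1001
    means <- cbind(runif(n, 20, 200), 0, 0)
    means[, 2] <- means[, 1]; means[, 3] <- means[, 1]
    counts <- means[, rep(1:3, each = 3)]           # 1000 flat backgrounds
    counts[1, 4:6] <- c(50, 48, 52); counts[1, c(1:3, 7:9)] <- 10
    ids <- sprintf("g%04d", seq_len(n))
    dimnames(counts) <- list(ids, paste0(rep(c("ctrl", "cold", "des"),
                                             each = 3), "_", rep(1:3, 3)))
    lab <- CountMatrix(counts, condition = rep(c("control", "cold",
                                                 "desiccated"), each = 3),
                       replicate = rep(1:3, 3))
    rec <- classifyRegulation(lab, "cold")
    expect_equal(rec$class[1], "up")
    expect_true(all(rec$class[-1] == "not_regulated"))

    # oracle: stats::t.test per transcript on the same transformed data,
    # then stats::p.adjust
    scaled <- sweep(counts, 2, mean(colSums(counts)) / colSums(counts), "*")
    lg <- log2(scaled + 1)
    pOracle <- vapply(seq_len(n), function(i) {
        tryCatch(stats::t.test(lg[i, 4:6], lg[i, 1:3])$p.value,
                 error = function(e) 1)   # zero variance in both groups
    }, numeric(1))
    expect_equal(rec$p_value, pOracle, tolerance = 1e-10)
    expect_equal(rec$fdr, stats::p.adjust(pOracle, "BH"), tolerance = 1e-10)
})

test_that("BH-adjusted values are monotone in p after step-up enforcement", {
    scn <- tinyScenario(seed = 31L)
    rec <- classifyRegulation(simulateLabExperiment(scn)$counts, "cold")
    ord <- order(rec$p_value)
    expect_true(all(diff(rec$fdr[ord]) >= -1e-12))
    expect_true(all(rec$fdr >= rec$p_value - 1e-12))
})

test_that("near-noise-free classification matches the truth labels", {
    scn <- tinyScenario(dispersion = 1e-4, nReplicates = 4, seed = 13L)
    sim <- simulateLabExperiment(scn)
    rc <- classifyRegulation(sim$counts, "cold")
    rd <- classifyRegulation(sim$counts, "desiccation")
    truth <- sim$truth
    coldUp <- truth$transcript_id[truth$label == "up_cold"]
    coldDown <- truth$transcript_id[truth$label == "down_cold"]
    expect_true(all(rc$class[match(coldUp, rc$transcript_id)] == "up"))
    expect_true(all(rc$class[match(coldDown, rc$transcript_id)] == "down"))
    unreg <- truth$transcript_id[truth$label %in% c("constant", "background")]
    expect_true(all(rc$class[match(unreg, rc$transcript_id)] ==
                    "not_regulated"))
    # desiccation-only transcripts are silent under cold
    desOnly <- truth$transcript_id[truth$label %in% c("up_des", "down_des")]
    expect_true(all(rc$class[match(desOnly, rc$transcript_id)] ==
                    "not_regulated"))
    expect_true(all(rd$class[match(desOnly, rd$transcript_id)] !=
                    "not_regulated"))
})

test_that("replicate and emptiness preconditions are enforced", {
    means <- cbind(rep(50, 5), rep(50, 5), rep(50, 5))
    lab1 <- meansMatrix(means, nrep = 1)
    expect_error(classifyRegulation(lab1, "cold"), ">= 2 replicates")
    empty <- CountMatrix(matrix(numeric(0), 0, 3,
                                dimnames = list(NULL, c("a", "b", "c"))),
                         condition = c("control", "cold", "desiccated"))
    expect_error(classifyRegulation(empty, "cold"), "empty")
})

test_that("constant-transcript selection applies all three rules", {
    filler <- matrix(rep(seq(60, 200, length.out = 30), 3), ncol = 3)
    means <- rbind(flat = c(50, 50, 50),        # constant
                   up  = c(10, 80, 10),         # cold-regulated
                   zero = c(40, 40, 0),         # zero in desiccated
                   drift = c(40, 62, 40),       # drifts past the stability bound
                   filler)                      # stabilizes library totals
    ids <- c("flat", "up", "zero", "drift", sprintf("f%02d", 1:30))
    lab <- meansMatrix(means, nrep = 3, ids = ids)
    # tiny replicate jitter so Welch tests are defined
    set.seed(1)
    counts <- abundances(lab) *
        matrix(exp(rnorm(length(abundances(lab)), 0, 0.02)), nrow(means))
    counts["zero", 7:9] <- 0
    lab <- CountMatrix(counts, condition = sampleConditions(lab),
                       replicate = rep(1:3, 3))
    rc <- classifyRegulation(lab, "cold")
    rd <- classifyRegulation(lab, "desiccation")
    const <- findConstant(rc, rd, lab, stabilityThreshold = 0.5)
    expect_true("flat" %in% const)
    expect_false("up" %in% const)        # regulated under cold
    expect_false("zero" %in% const)      # zero mean in one condition
    expect_false("drift" %in% const)     # |log2FC| above stability bound
})

test_that("catalog construction partitions regulated sets correctly", {
    mkRec <- function(ids, regulated, stressor, dir = "up") {
        data.frame(transcript_id = ids, stressor = stressor,
                   log2_fold_change = ifelse(ids %in% regulated, 2, 0),
                   p_value = ifelse(ids %in% regulated, 1e-4, 0.9),
                   fdr = ifelse(ids %in% regulated, 1e-3, 0.9),
                   class = ifelse(ids %in% regulated, dir, "not_regulated"))
    }
    ids <- c("A", "B", "C", "D", "E")
    cat <- buildCatalog(mkRec(ids, c("A", "B", "C"), "cold"),
                        mkRec(ids, c("B", "D"), "desiccation"),
                        constantIds = "E")
    expect_setequal(regulatedMarkers(cat, "cold")$transcript_id, c("A", "C"))
    expect_setequal(regulatedMarkers(cat, "desiccation")$transcript_id, "D")
    expect_equal(dualMarkers(cat), "B")
    expect_setequal(constantMarkers(cat, "cold"), "E")
    # specificity partition: specific sets and dual tile the union, disjointly
    parts <- list(c("A", "C"), "D", "B")
    expect_setequal(unlist(parts), c("A", "B", "C", "D"))
    expect_equal(anyDuplicated(unlist(parts)), 0L)
    # constant overlapping a regulated set violates the invariant
    expect_error(buildCatalog(mkRec(ids, c("A", "B"), "cold"),
                              mkRec(ids, "B", "desiccation"),
                              constantIds = "A"), "overlap")
    # empty inputs give an empty catalog without error
    emptyCat <- buildCatalog(mkRec(ids, character(), "cold"),
                             mkRec(ids, character(), "desiccation"))
    expect_equal(nrow(regulatedMarkers(emptyCat, "cold")), 0)
})

test_that("22 + 22 regulated with 11 shared leaves 11 stressor-specific", {
    ids <- sprintf("t%02d", 1:60)
    coldSet <- ids[1:22]
    desSet <- c(ids[12:22], ids[23:33])    # 11 shared with cold
    mkRec <- function(regulated, stressor) {
        data.frame(transcript_id = ids, stressor = stressor,
                   log2_fold_change = ifelse(ids %in% regulated, 2.5, 0),
                   p_value = ifelse(ids %in% regulated, 1e-4, 0.8),
                   fdr = ifelse(ids %in% regulated, 1e-3, 0.8),
                   class = ifelse(ids %in% regulated, "up", "not_regulated"))
    }
    cat <- buildCatalog(mkRec(coldSet, "cold"), mkRec(desSet, "desiccation"))
    expect_equal(length(dualMarkers(cat)), 11)
    expect_equal(nrow(regulatedMarkers(cat, "cold")), 11)
    expect_equal(nrow(regulatedMarkers(cat, "desiccation")), 11)
})

test_that("regulation summaries count directions per stressor", {
    scn <- tinyScenario(dispersion = 1e-4, nUpCold = 10, nDownCold = 5,
                        nUpDes = 0, nDownDes = 0, nReplicates = 4, seed = 17L)
    sim <- simulateLabExperiment(scn)
    rc <- classifyRegulation(sim$counts, "cold")
    tab <- summarizeRegulation(rc)
    # dual transcripts may add cold responses beyond the 10/5 singles
    truth <- sim$truth
    nUp <- sum(truth$fc_cold > 1); nDown <- sum(truth$fc_cold < 1)
    expect_equal(tab$up[tab$stressor == "cold"], nUp)
    expect_equal(tab$down[tab$stressor == "cold"], nDown)
    expect_false("desiccation" %in% tab$stressor)
    # no regulation at all
    flat <- classifyRegulation(meansMatrix(cbind(rep(50, 8), rep(50, 8),
                                                 rep(50, 8))), "cold")
    tab0 <- summarizeRegulation(flat)
    expect_equal(tab0$up + tab0$down, 0)
})

test_that("precomputed regulation tables are classified at the thresholds", {
    path <- tempfile(fileext = ".tsv")
    on.exit(unlink(path))
    df <- data.frame(transcript_id = c("A", "B", "C"),
                     stressor = "cold",
                     log2_fold_change = c(2.0, -3.0, 0.5),
                     p_value = c(1e-4, 1e-5, 0.2),
                     fdr = c(1e-3, 1e-4, 0.4))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    rec <- readRegulationTable(path)
    expect_equal(rec$class, c("up", "down", "not_regulated"))
})
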