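.defaultThresholds <- function() {
    list(min_identity = 98, max_evalue = 1e-50, fold_change = 2,
         p_value = 0.05, fdr = 0.05, stability_threshold = 0.5,
         delta = 1e-9, alpha = 0.05, n_expected = 999, n_simulated = 999)
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE))
}

#' Read a pipeline configuration
#'
#' A YAML file (or an equivalent R list passed straight to
#' \code{\link{runPipeline}}) with either a \code{scenario} block of
#' \code{\link{SyntheticScenario}} parameters or input paths
#' (\code{lab_counts}, \code{lab_metadata}, \code{field_counts},
#' \code{field_metadata}, \code{identity_hits}), an optional
#' \code{thresholds} block, a \code{seed} and an \code{out_dir}.
#'
#' @param path YAML config path
#' @return config list with threshold defaults filled in
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- yaml::read_yaml(path)
    cfg$thresholds <- utils::modifyList(.defaultThresholds(),
                                        as.list(cfg$thresholds))
    cfg
}

#' Run the full stress-detection pipeline
#'
#' Chains every stage: marker classification on the lab experiment, catalog
#' construction, identity filtering and mapping of field contigs, ratio
#' bounds, Gene Marker Indices with summaries, the two clustering datasets,
#' and Ward.D2 + SIMPROF per stressor. Writes the marker catalog, pair
#' bounds, GMI records and summaries, annotated Newick dendrograms, a stage
#' log with filter in/out counts, and a provenance manifest. Identical
#' config + seed produce byte-identical outputs.
#'
#' @param config config list (see \code{\link{readRunConfig}}) or a YAML path
#' @param outDir output directory (default \code{config$out_dir})
#' @param seed integer seed overriding \code{config$seed}
#' @return invisibly, a list with the in-memory stage results
#' @export
runPipeline <- function(config, outDir = NULL, seed = NULL) {
    if (is.character(config)) config <- readRunConfig(config)
    thr <- utils::modifyList(.defaultThresholds(), as.list(config$thresholds))
    if (is.null(seed)) seed <- if (is.null(config$seed)) 1L else config$seed
    if (is.null(outDir)) outDir <- config$out_dir
    if (is.null(outDir)) stop("no output directory configured")
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    logLines <- character()
    note <- function(...) logLines <<- c(logLines, sprintf(...))

    if (!is.null(config$scenario)) {
        scn <- .stage("simulate", do.call(SyntheticScenario,
                      utils::modifyList(as.list(config$scenario),
                                        list(seed = seed))))
        sim <- .stage("simulate", simulateLabExperiment(scn))
        lab <- sim$counts
        fieldStressor <- if (is.null(config$field_stressor)) "cold"
                         else config$field_stressor
        fieldRef <- .stage("simulate",
            simulateFieldSamples(scn, lab, sim$truth, fieldStressor))
        # present the field table at contig level so the matching stage runs
        contigField <- abundances(fieldRef)
        rownames(contigField) <- paste0("contig-", rownames(contigField))
        field <- CountMatrix(contigField, condition = "field", site = "field",
                             replicate = colData(fieldRef)$replicate)
        nDecoys <- if (is.null(config$n_decoys)) 100L else config$n_decoys
        hits <- .stage("simulate",
                       simulateIdentityHits(sim$truth, nDecoys, seed))
        writeCounts(lab, file.path(outDir, "lab_counts.tsv"),
                    file.path(outDir, "lab_metadata.tsv"))
        writeCounts(field, file.path(outDir, "field_counts.tsv"),
                    file.path(outDir, "field_metadata.tsv"))
        .writeTsv(sim$truth, file.path(outDir, "truth_labels.tsv"))
        writeBlastTab(hits, file.path(outDir, "identity_hits.tsv"))
        note("simulate: %d transcripts, %d lab samples, %d field samples",
             nrow(lab), ncol(lab), ncol(field))
    } else {
        lab <- .stage("read", readCounts(config$lab_counts,
                                         config$lab_metadata))
        field <- .stage("read", readCounts(config$field_counts,
                                           config$field_metadata))
        hits <- .stage("read", readBlastTab(config$identity_hits))
        note("read: %d transcripts, %d lab samples, %d field contigs",
             nrow(lab), ncol(lab), nrow(field))
    }

    recCold <- .stage("classify", classifyRegulation(
        lab, "cold", thr$fold_change, thr$p_value, thr$fdr))
    recDes <- .stage("classify", classifyRegulation(
        lab, "desiccation", thr$fold_change, thr$p_value, thr$fdr))
    regSummary <- summarizeRegulation(list(recCold, recDes))
    note("classify: %s", paste(sprintf("%s %d up / %d down",
         regSummary$stressor, regSummary$up, regSummary$down),
         collapse = "; "))
    constant <- .stage("catalog", findConstant(recCold, recDes, lab,
                                               thr$stability_threshold))
    catalog <- .stage("catalog", buildCatalog(recCold, recDes, constant))
    note("catalog: %d cold-specific, %d desiccation-specific, %d dual, %d constant",
         nrow(regulatedMarkers(catalog, "cold")),
         nrow(regulatedMarkers(catalog, "desiccation")),
         length(dualMarkers(catalog)), length(constant))

    retained <- .stage("match", filterHits(hits, thr$min_identity,
                                           thr$max_evalue))
    funnel <- attr(retained, "funnel")
    note("match: %d hits in, %d pass thresholds, %d best-per-query",
         funnel["input"], funnel["pass_thresholds"], funnel["best_per_query"])
    fieldRefTable <- .stage("match", mapToReference(retained, field))
    labNorm <- .stage("normalize", normalizeRelative(lab))
    fieldNorm <- .stage("normalize", normalizeRelative(fieldRefTable))

    catalogTab <- rbind(
        data.frame(transcript_id = catalog@regulated$transcript_id,
                   role = paste0("regulated_", catalog@regulated$stressor),
                   direction = catalog@regulated$direction),
        data.frame(transcript_id = dualMarkers(catalog), role = "dual",
                   direction = NA_character_),
        data.frame(transcript_id = constant, role = "constant",
                   direction = NA_character_))
    .writeTsv(catalogTab, file.path(outDir, "marker_catalog.tsv"))
    .writeTsv(regSummary, file.path(outDir, "regulation_summary.tsv"))

    results <- list(catalog = catalog, regulation = list(cold = recCold,
                    desiccation = recDes), field = fieldNorm)
    for (stressor in c("cold", "desiccation")) {
        bounds <- .stage("gmi", computePairBounds(labNorm, catalog, stressor,
                                                  thr$delta))
        if (nrow(bounds) == 0) {
            note("gmi %s: no usable pairs", stressor)
            next
        }
        gmi <- .stage("gmi", computeGMI(bounds, fieldNorm))
        gsum <- .stage("gmi", summarizeGMI(gmi))
        note("gmi %s: %d pairs (%d dropped), %d records, %d in range",
             stressor, nrow(bounds), nrow(attr(bounds, "dropped")),
             gsum$n_total, gsum$n_in_range)
        .writeTsv(bounds, file.path(outDir,
                  sprintf("pair_bounds_%s.tsv", stressor)))
        .writeTsv(gmi, file.path(outDir,
                  sprintf("gmi_records_%s.tsv", stressor)))
        .writeTsv(data.frame(
            statistic = c("n_total", "n_in_range", "fraction_below",
                          "fraction_above", "in_range_mean", "in_range_sd"),
            value = c(gsum$n_total, gsum$n_in_range, gsum$fraction_below,
                      gsum$fraction_above, gsum$in_range_mean,
                      gsum$in_range_sd)),
            file.path(outDir, sprintf("gmi_summary_%s.tsv", stressor)))
        results[[stressor]] <- list(bounds = bounds, gmi = gmi,
                                    summary = gsum)
        for (variant in c("dataset1", "dataset2")) {
            ds <- tryCatch(
                buildDataset(catalog, fieldNorm, lab, variant, stressor),
                error = function(e) NULL)
            if (is.null(ds) || ncol(ds) < 3) next
            sp <- .stage("cluster", simprof(ds, thr$alpha, thr$n_expected,
                                            thr$n_simulated, seed))
            writeLines(renderNewick(sp@tree, sp),
                       file.path(outDir, sprintf("dendrogram_%s_%s.nwk",
                                                 stressor, variant)))
            note("cluster %s %s: %d samples, %d significant cluster group(s)",
                 stressor, variant, ncol(ds),
                 length(significantClusters(sp)))
            results[[paste(stressor, variant, sep = "_")]] <- sp
        }
    }

    writeLines(logLines, file.path(outDir, "pipeline.log"))
    manifest <- c(sprintf("gmindex %s",
                          as.character(utils::packageVersion("gmindex"))),
                  sprintf("seed: %d", as.integer(seed)),
                  "thresholds:",
                  sprintf("  %s: %g", names(thr), unlist(thr)))
    writeLines(manifest, file.path(outDir, "manifest.txt"))
    invisible(results)
}
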