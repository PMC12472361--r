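#' SyntheticScenario: parameters of the synthetic study design
#'
#' Describes a replicated laboratory stress experiment (control, cold,
#' desiccated conditions) plus field samples drawn at known latent stress
#' fractions, with a known partition of transcripts into stressor-regulated,
#' dual-regulated, constantly expressed and background sets. Counts follow a
#' negative-binomial model with variance \eqn{\mu + \phi \mu^2}.
#'
#' @slot nTranscripts total number of transcripts.
#' @slot nUpCold,nDownCold,nUpDes,nDownDes numbers of transcripts regulated by
#'   exactly one stressor, split by direction.
#' @slot overlapFraction fraction of the union of regulated transcripts that
#'   is regulated by both stressors (the dual set); with the default 1/3 a
#'   design with 11 + 11 single-stressor transcripts carries 11 dual ones.
#' @slot nConstant number of constantly expressed transcripts.
#' @slot foldChangeRange interval of true |fold changes| for regulated
#'   transcripts; the lower bound must exceed 2, the detection threshold.
#' @slot baselineMeanRange interval of per-transcript baseline expression
#'   means (arbitrary expression units before library scaling).
#' @slot dispersion negative-binomial overdispersion phi for lab samples
#'   (0 gives Poisson noise).
#' @slot fieldDispersion overdispersion for field samples; field replicates
#'   are typically noisier than lab cultures.
#' @slot nReplicates replicates per lab condition.
#' @slot fieldStressLevels latent stress fractions s in [0,1], one per
#'   synthetic field replicate.
#' @slot librarySizeRange interval of per-sample total counts.
#' @slot seed integer seed; all simulators derive their streams from it.
#' @aliases SyntheticScenario-class
#' @exportClass SyntheticScenario
setClass("SyntheticScenario",
         representation(nTranscripts = "numeric",
                        nUpCold = "numeric", nDownCold = "numeric",
                        nUpDes = "numeric", nDownDes = "numeric",
                        overlapFraction = "numeric", nConstant = "numeric",
                        foldChangeRange = "numeric",
                        baselineMeanRange = "numeric",
                        dispersion = "numeric", fieldDispersion = "numeric",
                        nReplicates = "numeric",
                        fieldStressLevels = "numeric",
                        librarySizeRange = "numeric", seed = "numeric"))

setValidity("SyntheticScenario", function(object) {
    msg <- character()
    cnt <- c(object@nTranscripts, object@nUpCold, object@nDownCold,
             object@nUpDes, object@nDownDes, object@nConstant)
    if (any(cnt < 0)) msg <- c(msg, "all counts must be nonnegative")
    if (object@overlapFraction < 0 || object@overlapFraction >= 1)
        msg <- c(msg, "overlapFraction must lie in [0, 1)")
    if (length(object@fieldStressLevels) &&
        (any(object@fieldStressLevels < 0) || any(object@fieldStressLevels > 1)))
        msg <- c(msg, "every field stress level must lie in [0, 1]")
    if (object@foldChangeRange[1] <= 2)
        msg <- c(msg, paste("lower bound of foldChangeRange must exceed 2:",
                            "regulation below the detection threshold makes",
                            "the truth labels unlearnable"))
    if (diff(object@foldChangeRange) < 0 || diff(object@baselineMeanRange) < 0 ||
        diff(object@librarySizeRange) < 0)
        msg <- c(msg, "ranges must be ordered (low, high)")
    if (object@nReplicates < 1)
        msg <- c(msg, "at least one replicate per condition is required")
    if (object@dispersion < 0 || object@fieldDispersion < 0)
        msg <- c(msg, "dispersions must be nonnegative")
    nLabeled <- sum(object@nUpCold, object@nDownCold, object@nUpDes,
                    object@nDownDes, .nDual(object), object@nConstant)
    if (nLabeled > object@nTranscripts)
        msg <- c(msg, sprintf(
            "labeled transcripts (%d incl. %d dual) exceed nTranscripts (%d)",
            nLabeled, .nDual(object), object@nTranscripts))
    if (length(msg)) msg else TRUE
})

# dual set sized so that dual / |union of regulated sets| = overlapFraction:
# with singles S and dual d, d = f (S + d)  =>  d = f S / (1 - f)
.nDual <- function(scenario) {
    S <- sum(scenario@nUpCold, scenario@nDownCold,
             scenario@nUpDes, scenario@nDownDes)
    round(scenario@overlapFraction * S / (1 - scenario@overlapFraction))
}

#' Construct a SyntheticScenario
#'
#' Defaults describe a modest bulk RNA-seq stress experiment: 2000 transcripts,
#' 60 up- and 60 down-regulated per stressor with true fold changes in [4, 8],
#' a dual-regulated set sized so that one third of the union of regulated
#' transcripts responds to both stressors, 100 constantly expressed
#' transcripts, 3 replicates per lab condition, and 3 field replicates at
#' latent stress 0.25 / 0.5 / 0.75.
#'
#' @param nTranscripts,nUpCold,nDownCold,nUpDes,nDownDes,overlapFraction,nConstant
#'   design sizes, see \linkS4class{SyntheticScenario}.
#' @param foldChangeRange,baselineMeanRange,dispersion,fieldDispersion,nReplicates,fieldStressLevels,librarySizeRange,seed
#'   generative parameters, see \linkS4class{SyntheticScenario}.
#' @return a validated \linkS4class{SyntheticScenario}
#' @export
SyntheticScenario <- function(nTranscripts = 2000,
                              nUpCold = 60, nDownCold = 60,
                              nUpDes = 60, nDownDes = 60,
                              overlapFraction = 1 / 3, nConstant = 100,
                              foldChangeRange = c(4, 8),
                              baselineMeanRange = c(20, 500),
                              dispersion = 0.05,
                              fieldDispersion = dispersion,
                              nReplicates = 3,
                              fieldStressLevels = c(0.25, 0.5, 0.75),
                              librarySizeRange = c(8e5, 1.2e6),
                              seed = 1L) {
    new("SyntheticScenario", nTranscripts = nTranscripts, nUpCold = nUpCold,
        nDownCold = nDownCold, nUpDes = nUpDes, nDownDes = nDownDes,
        overlapFraction = overlapFraction, nConstant = nConstant,
        foldChangeRange = as.numeric(foldChangeRange),
        baselineMeanRange = as.numeric(baselineMeanRange),
        dispersion = dispersion, fieldDispersion = fieldDispersion,
        nReplicates = nReplicates,
        fieldStressLevels = as.numeric(fieldStressLevels),
        librarySizeRange = as.numeric(librarySizeRange), seed = seed)
}

setMethod("show", "SyntheticScenario", function(object) {
    cat(sprintf(paste0(
        "SyntheticScenario: %d transcripts (%d+%d cold, %d+%d desiccation,",
        " %d dual, %d constant)\n  %d reps/condition, %d field sample(s),",
        " dispersion %g, seed %d\n"),
        object@nTranscripts, object@nUpCold, object@nDownCold, object@nUpDes,
        object@nDownDes, .nDual(object), object@nConstant,
        object@nReplicates, length(object@fieldStressLevels),
        object@dispersion, object@seed))
})

# Seed-splitting rule: every simulator draws from seed * 8 + k for a fixed
# small k, so adding a simulator never perturbs existing streams.
.subSeed <- function(seed, k) (as.integer(seed) * 8L + as.integer(k)) %% 2147483647L

.rcounts <- function(n, mu, phi) {
    if (phi <= 0) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / phi)
}

# condition-wise expected expression (pre library scaling) from truth labels
.expectedMeans <- function(truth) {
    ctrl <- truth$baseline_mean
    cbind(control = ctrl, cold = ctrl * truth$fc_cold,
          desiccated = ctrl * truth$fc_des)
}

.drawSampleCounts <- function(expected, libSizes, phi, sampleIds) {
    counts <- vapply(seq_along(libSizes), function(j) {
        mu <- expected[, j] * libSizes[j] / sum(expected[, j])
        .rcounts(length(mu), mu, phi)
    }, numeric(nrow(expected)))
    dimnames(counts) <- list(rownames(expected), sampleIds)
    counts
}

#' Simulate a replicated laboratory stress experiment
#'
#' Generates negative-binomial counts for control, cold and desiccated
#' conditions with known regulated / constant / background transcripts.
#' Regulated transcripts have expected stress-condition means equal to
#' baseline times their true fold change (divided for down-regulation);
#' constant and background transcripts keep their baseline mean in every
#' condition. The generative per-condition expectations are stored in
#' \code{rowData} of the returned matrix so that field samples can be
#' interpolated from them.
#'
#' @param scenario a \linkS4class{SyntheticScenario}
#' @return list with elements \code{counts} (a \linkS4class{CountMatrix} with
#'   \code{3 * nReplicates} samples) and \code{truth} (data.frame with
#'   \code{transcript_id}, \code{label}, \code{fc_cold}, \code{fc_des},
#'   \code{baseline_mean}; fold changes are ratios of stress to control
#'   expectation, mutually exclusive labels in \{up_cold, down_cold, up_des,
#'   down_des, dual, constant, background\}).
#' @export
simulateLabExperiment <- function(scenario) {
    stopifnot(is(scenario, "SyntheticScenario"))
    validObject(scenario)

    ids <- sprintf("t%05d", seq_len(scenario@nTranscripts))
    nDual <- .nDual(scenario)

    set.seed(.subSeed(scenario@seed, 1L))

    labCounts <- c(up_cold = scenario@nUpCold, down_cold = scenario@nDownCold,
                   up_des = scenario@nUpDes, down_des = scenario@nDownDes,
                   dual = nDual, constant = scenario@nConstant)
    label <- rep("background", scenario@nTranscripts)
    label[seq_len(sum(labCounts))] <- rep(names(labCounts), labCounts)

    drawFC <- function(n) stats::runif(n, scenario@foldChangeRange[1],
                                       scenario@foldChangeRange[2])
    fcCold <- rep(1, scenario@nTranscripts)
    fcDes <- rep(1, scenario@nTranscripts)
    fcCold[label == "up_cold"] <- drawFC(sum(label == "up_cold"))
    fcCold[label == "down_cold"] <- 1 / drawFC(sum(label == "down_cold"))
    fcDes[label == "up_des"] <- drawFC(sum(label == "up_des"))
    fcDes[label == "down_des"] <- 1 / drawFC(sum(label == "down_des"))
    isDual <- label == "dual"
    if (any(isDual)) {
        sgn <- function(n) ifelse(stats::runif(n) < 0.5, 1, -1)
        fcCold[isDual] <- drawFC(sum(isDual))^sgn(sum(isDual))
        fcDes[isDual] <- drawFC(sum(isDual))^sgn(sum(isDual))
    }
    baseline <- stats::runif(scenario@nTranscripts,
                             scenario@baselineMeanRange[1],
                             scenario@baselineMeanRange[2])
    truth <- data.frame(transcript_id = ids, label = label,
                        fc_cold = fcCold, fc_des = fcDes,
                        baseline_mean = baseline,
                        stringsAsFactors = FALSE)
    rownames(truth) <- ids

    set.seed(.subSeed(scenario@seed, 2L))
    conditions <- rep(c("control", "cold", "desiccated"),
                      each = scenario@nReplicates)
    sampleIds <- paste0(rep(c("ctrl", "cold", "des"),
                            each = scenario@nReplicates),
                        "_", rep(seq_len(scenario@nReplicates), 3))
    libSizes <- stats::runif(length(sampleIds), scenario@librarySizeRange[1],
                             scenario@librarySizeRange[2])
    expected <- .expectedMeans(truth)[, conditions, drop = FALSE]
    rownames(expected) <- ids
    counts <- .drawSampleCounts(expected, libSizes, scenario@dispersion,
                                sampleIds)

    cm <- CountMatrix(counts, condition = conditions, site = "lab",
                      replicate = rep(seq_len(scenario@nReplicates), 3))
    rowData(cm) <- DataFrame(.expectedMeans(truth), row.names = ids)
    list(counts = cm, truth = truth)
}

#' Simulate field metatranscriptome samples at known latent stress levels
#'
#' For each latent stress fraction s in the scenario, each transcript's
#' expected abundance is the arithmetic interpolation
#' \eqn{(1-s)\,E[\mathrm{control}] + s\,E[\mathrm{stress}]} between the lab
#' generative expectations (carried in \code{rowData} of the lab matrix),
#' rescaled to a drawn library size and re-drawn with the scenario's field
#' dispersion. Linear interpolation makes the population-level marker-pair
#' ratio exactly \eqn{(1-s)X_{min} + sX_{max}} when the denominator transcript
#' is constant, so index recovery (GMI close to 100 s) is analytically
#' grounded.
#'
#' @param scenario a \linkS4class{SyntheticScenario}
#' @param lab the lab \linkS4class{CountMatrix} from
#'   \code{\link{simulateLabExperiment}} (its \code{rowData} must carry the
#'   generative expectations)
#' @param truth the matching truth data.frame (determinism guard: its
#'   transcripts must match the lab matrix)
#' @param stressor \code{"cold"} or \code{"desiccation"}
#' @return a \linkS4class{CountMatrix} of field samples; \code{colData} keeps
#'   the latent \code{stress_level} per sample
#' @export
simulateFieldSamples <- function(scenario, lab, truth,
                                 stressor = c("cold", "desiccation")) {
    stressor <- match.arg(stressor)
    stopifnot(is(scenario, "SyntheticScenario"), is(lab, "CountMatrix"))
    validObject(scenario)
    s <- scenario@fieldStressLevels
    if (length(s) == 0) stop("scenario defines no field stress levels")
    if (any(s < 0 | s > 1)) stop("latent stress levels must lie in [0, 1]")
    stressCond <- if (stressor == "cold") "cold" else "desiccated"
    if (!all(c("control", stressCond) %in% sampleConditions(lab)))
        stop("lab matrix must contain control and ", stressCond, " samples")
    rd <- as.data.frame(rowData(lab))
    if (!all(c("control", stressCond) %in% colnames(rd)))
        stop("lab rowData lacks generative expectations; ",
             "use simulateLabExperiment() output")
    if (!identical(rownames(lab), truth$transcript_id))
        stop("truth labels do not match the lab matrix")

    set.seed(.subSeed(scenario@seed, 3L + (stressor == "desiccation")))
    expected <- vapply(s, function(si)
        (1 - si) * rd$control + si * rd[[stressCond]], numeric(nrow(rd)))
    rownames(expected) <- rownames(lab)
    sampleIds <- paste0("field_", seq_along(s))
    libSizes <- stats::runif(length(s), scenario@librarySizeRange[1],
                             scenario@librarySizeRange[2])
    counts <- .drawSampleCounts(expected, libSizes, scenario@fieldDispersion,
                                sampleIds)
    CountMatrix(counts, condition = "field", site = "field",
                replicate = seq_along(s), stress_level = s)
}

#' Simulate a BLAST-tabular identity-hit table
#'
#' Every transcript in \code{truth} receives a field contig hit passing the
#' default retention filter (identity uniform in [98, 100], e-value at or
#' below 1e-60); decoy contigs receive hits failing it, either by identity
#' (below 98) or by e-value (above 1e-50). With default filter settings the
#' survivors of \code{\link{filterHits}} are therefore exactly the truth
#' transcripts.
#'
#' @param truth truth data.frame from \code{\link{simulateLabExperiment}} (or
#'   any data.frame with a \code{transcript_id} column)
#' @param nDecoys number of decoy contigs
#' @param seed integer seed
#' @return data.frame in 12-column BLAST outfmt-6 layout (qseqid, sseqid,
#'   pident, length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#'   bitscore); query ids are \code{contig-<transcript>} for true hits and
#'   \code{decoy-<i>} for decoys
#' @export
simulateIdentityHits <- function(truth, nDecoys = 0, seed = 1L) {
    stopifnot(nDecoys >= 0)
    ids <- truth$transcript_id
    set.seed(.subSeed(seed, 4L))
    mkHit <- function(q, s, pid, ev) {
        len <- sample(200:1500, length(q), replace = TRUE)
        data.frame(qseqid = q, sseqid = s,
                   pident = round(pid, 3), length = len,
                   mismatch = pmax(0L, as.integer(round(len * (100 - pid) / 100))),
                   gapopen = 0L, qstart = 1L, qend = len,
                   sstart = 1L, send = len,
                   evalue = ev,
                   bitscore = round(stats::runif(length(q), 200, 2500), 1),
                   stringsAsFactors = FALSE)
    }
    hits <- mkHit(paste0("contig-", ids), ids,
                  stats::runif(length(ids), 98, 100),
                  10^-stats::runif(length(ids), 60, 150))
    if (nDecoys > 0) {
        lowIdent <- seq_len(nDecoys) %% 2 == 0
        decoys <- mkHit(sprintf("decoy-%04d", seq_len(nDecoys)),
                        sample(ids, nDecoys, replace = TRUE),
                        ifelse(lowIdent, stats::runif(nDecoys, 80, 97.9),
                               stats::runif(nDecoys, 98, 100)),
                        ifelse(lowIdent, 10^-stats::runif(nDecoys, 60, 150),
                               10^-stats::runif(nDecoys, 10, 40)))
        hits <- rbind(hits, decoys)
    }
    rownames(hits) <- NULL
    hits
}

#' Fixture mirroring the published marker-catalog sizes
#'
#' Builds per-site marker catalogs at the sizes reported for the two Antarctic
#' biocrust sites — cold stress: 13 constantly expressed with 11 (site 1) or
#' 10 (site 3) regulated transcripts; desiccation stress: 12 constantly
#' expressed with 8 regulated at both sites — together with a small
#' deterministic lab count table consistent with those labels (regulated
#' transcripts change fourfold under their stressor, constants stay flat).
#'
#' @return list with \code{catalogs} (named list of \linkS4class{MarkerCatalog}
#'   for \code{site1} and \code{site3}) and \code{counts} (a noise-free lab
#'   \linkS4class{CountMatrix} with 3 replicates per condition)
#' @export
makeTable4Fixture <- function() {
    coldIds <- sprintf("KfCOLD%02d", 1:11)
    desIds <- sprintf("KfDES%02d", 1:8)
    refIds <- sprintf("KfREF%02d", 1:13)
    mkCatalog <- function(nCold) {
        MarkerCatalog(
            regulated = data.frame(
                transcript_id = c(coldIds[seq_len(nCold)], desIds),
                stressor = rep(c("cold", "desiccation"), c(nCold, length(desIds))),
                direction = rep(c("up", "down"),
                                length.out = nCold + length(desIds))),
            constant = list(cold = refIds, desiccation = refIds[1:12]),
            thresholds = list(source = "published site catalogs"))
    }
    ids <- c(coldIds, desIds, refIds)
    base <- 10 * (1 + (seq_along(ids) %% 7))          # distinct flat baselines
    dirFor <- function(i) if (i %% 2 == 1) 4 else 1 / 4  # alternating up/down
    mu <- cbind(control = base, cold = base, desiccated = base)
    for (i in seq_along(coldIds)) mu[i, "cold"] <- base[i] * dirFor(i)
    for (i in seq_along(desIds))
        mu[length(coldIds) + i, "desiccated"] <- base[length(coldIds) + i] * dirFor(i)
    counts <- mu[, rep(c("control", "cold", "desiccated"), each = 3)]
    dimnames(counts) <- list(ids, paste0(rep(c("ctrl", "cold", "des"), each = 3),
                                         "_", rep(1:3, 3)))
    cm <- CountMatrix(counts,
                      condition = rep(c("control", "cold", "desiccated"), each = 3),
                      site = "lab", replicate = rep(1:3, 3))
    list(catalogs = list(site1 = mkCatalog(11), site3 = mkCatalog(10)),
         counts = cm)
}
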