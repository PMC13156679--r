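## End-to-end orchestration: simulate (or load) -> preprocess -> segment ->
## extract -> batch-correct -> cluster -> markers, with a JSON run report.

#' Default pipeline parameters
#'
#' All stage parameters with their defaults: signal-to-noise threshold 6,
#' cell/background ratio 5, blur sigma 5 px, single-cell area 100-2500 um^2,
#' aspect ratio 0.75-1.25, consensus resampling rate 0.8 with 500 iterations
#' over 8 neighbour values and 19 resolutions, and marker thresholds 1.5 /
#' 0.667 at adjusted alpha 0.01.
#'
#' @return named list of defaults, suitable as a starting point for
#'   [runPipeline()] configs.
#' @export
pipelineDefaults <- function() {
    list(snr = 6, ratio = 5, sigmaPx = 5,
         areaRange = c(100, 2500), aspectRange = c(0.75, 1.25),
         kGrid = c(5, 10, 15, 20, 25, 30, 40, 50),
         resGrid = seq(0.1, 1.9, by = 0.1),
         nIter = 500L, subsample = 0.8, minSupport = 10L,
         alpha = 0.01, fcHigh = 1.5, fcLow = 0.667,
         nPcs = 10L, kOverride = NULL, doTsne = TRUE,
         featureVoteFrac = 0.5, seed = 1L)
}

#' Run the full single-cell MSI analysis
#'
#' Executes every stage in order on a simulated experiment: per sample, TIC
#' normalization, spatially smoothed k-means cell-pixel detection and the 5x
#' cell-specific peak filter; brightfield blur/threshold/contour segmentation
#' and pixel assignment into dispersed and cohesive cells; single-cell mean
#' spectra; empirical-Bayes batch correction across matrix-application
#' pairs; z-scoring, PCA, subsampled SNN/Leiden consensus clustering with
#' silhouette ranking of K; and marker calling of each selected cluster
#' against the pooled remaining cells. Cell-specific features are those
#' passing the ratio filter in at least \code{featureVoteFrac} of the
#' samples. Everything is reproducible from (config, seed).
#'
#' @param config list with element \code{sim} (a list of arguments for
#'   [simConfig()] minus treatment/pair/batch, plus \code{nPairs} and
#'   optionally \code{batchScales}) and any overrides of
#'   [pipelineDefaults()].
#' @param outDir optional directory; when given, the report is written as
#'   \code{report.json} and the figure-data CSVs of
#'   [compareGroupsReport()] alongside it.
#' @return (invisibly) a list: \code{report} (plain summary), plus the
#'   intermediate objects (\code{samples}, \code{units}, \code{corrected},
#'   \code{scaled}, \code{pca}, \code{consensus}, \code{markers},
#'   \code{truth}).
#' @export
runPipeline <- function(config, outDir = NULL) {
    p <- utils::modifyList(pipelineDefaults(), config[setdiff(names(config),
                                                              "sim")])
    if (is.null(config$sim))
        stop("config must carry a 'sim' block; external imzML inputs are ",
             "loaded with readMSIDataset() and fed in as prepared samples")
    simCfg <- config$sim
    nPairs <- simCfg$nPairs %||% 2L
    seed <- as.integer(p$seed)
    set.seed(seed)
    batchScales <- simCfg$batchScales %||% exp(stats::rnorm(nPairs, 0, 0.25))
    simArgs <- simCfg[setdiff(names(simCfg), c("nPairs", "batchScales"))]

    samples <- list()
    truths <- list()
    featVotes <- NULL
    for (pr in seq_len(nPairs)) {
        for (tr in c("CTR", "EGF")) {
            args <- utils::modifyList(simArgs, list(
                treatment = tr, pairId = sprintf("pair%d", pr),
                batchScale = batchScales[pr],
                seed = seed + pr * 100L + (tr == "EGF")))
            sim <- simulateExperiment(do.call(simConfig, args))
            pt <- ticNormalize(asPeakTable(sim$msi))
            part <- spatialKmeans(pt, seed = seed + pr)
            feats <- cellSpecificPeaks(pt, part, ratioMin = p$ratio)
            mask <- blurAndThreshold(sim$brightfield, sigmaPx = p$sigmaPx)
            cs <- filterSingleCellContours(
                findCellContours(mask, sim$brightfield@umPerPx),
                p$areaRange, p$aspectRange)
            ca <- assignPixels(cs, part, sim$brightfield,
                               sampleId = pt@sampleId,
                               treatment = tr, pairId = pt@pairId)
            id <- pt@sampleId
            samples[[id]] <- list(pt = pt, part = part, feats = feats,
                                  assignment = ca)
            truths[[id]] <- sim$truth
            v <- logical(length(pt@featureMz)); v[feats] <- TRUE
            featVotes <- rbind(featVotes, v)
        }
    }
    features <- which(colMeans(featVotes) >= p$featureVoteFrac)
    if (!length(features)) stop("no cell-specific features survive voting")

    units <- combineUnits(lapply(samples, function(s)
        extractUnits(s$pt, s$assignment, "single_cell", features)))
    corrected <- combatCorrect(units)
    scaled <- zscoreScale(corrected)
    pca <- pcaEmbed(scaled, nComponents = min(p$nPcs, ncol(units) - 1L,
                                              nrow(units)))
    cc <- consensusCluster(scaled, kGrid = p$kGrid, resGrid = p$resGrid,
                           nIter = p$nIter, subsample = p$subsample,
                           seed = seed, minSupport = p$minSupport)
    cc <- selectK(cc, pca$scores, override = p$kOverride)

    labels <- clusterLabels(cc)
    markers <- list()
    for (k in sort(unique(labels))) {
        others <- setdiff(unique(labels), k)
        markers[[as.character(k)]] <- tryCatch(
            findMarkers(corrected, labels, k, others, alpha = p$alpha,
                        fcHigh = p$fcHigh, fcLow = p$fcLow),
            error = function(e) NULL)
    }

    pop <- populationSummary(lapply(samples, `[[`, "assignment"))
    treat <- as.character(colData(units)$treatment)
    composition <- prop.table(table(cluster = labels, treatment = treat),
                              margin = 1L)
    ari <- NA_real_
    truthLab <- .truthSubpopLabels(units, samples, truths)
    if (requireNamespace("mclust", quietly = TRUE) && !anyNA(truthLab))
        ari <- mclust::adjustedRandIndex(labels, truthLab)

    report <- list(
        seed = seed,
        parameters = p[c("snr", "ratio", "sigmaPx", "areaRange",
                         "aspectRange", "nIter", "subsample", "alpha",
                         "fcHigh", "fcLow")],
        perSample = pop$perSample,
        populationTests = pop$tests,
        nCellsAnalyzed = ncol(units),
        groupShares = as.list(groupShares(table(treat))),
        kRanking = cc@ranking,
        selectedK = selectedK(cc),
        clusterComposition = as.data.frame.matrix(composition),
        nMarkersPerCluster = vapply(markers, function(mt)
            if (is.null(mt)) 0L else sum(mt$is_marker), integer(1)),
        ariVsTruth = ari)

    result <- list(report = report, samples = samples, units = units,
                   corrected = corrected, scaled = scaled, pca = pca,
                   consensus = cc, markers = markers, truth = truths)
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        jsonlite::write_json(
            report, file.path(outDir, "report.json"),
            auto_unbox = TRUE, digits = NA, dataframe = "rows", force = TRUE)
        compareGroupsReport(result, outDir = outDir)
    }
    invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## map every analyzed single cell back to its planted subpopulation via the
## majority planted id among the cell's pixels (contour ids are arbitrary)
.truthSubpopLabels <- function(units, samples, truths) {
    cd <- colData(units)
    vapply(seq_len(ncol(units)), function(j) {
        id <- cd$sample_id[j]
        s <- samples[[id]]; tr <- truths[[id]]
        if (is.null(s) || !length(tr@subpopLabels)) return(NA_integer_)
        cellNo <- as.integer(sub("^cell", "", cd$unit[j]))
        ca <- s$assignment
        px <- which(ca@cellId == cellNo & ca@organization == "dispersed")
        if (!length(px)) return(NA_integer_)
        lin <- ca@coords[px, 1L] + 1L + ca@coords[px, 2L] * ca@gridShape[1L]
        planted <- as.vector(tr@cellIdMap)[lin]
        planted <- planted[planted > 0L]
        if (!length(planted)) return(NA_integer_)
        maj <- as.integer(names(which.max(table(planted))))
        tr@subpopLabels[[as.character(maj)]]
    }, integer(1))
}

#' Figure-data bundle for group comparisons
#'
#' Emits the tables behind the standard figures: per-sample cell-pixel and
#' dispersed percentages (boxplot data), paired CTR-vs-EGF sample means per
#' feature (paired dot plots), paired cohesive-vs-dispersed pools per sample,
#' PCA scores with annotations, the cluster x feature heatmap matrix of mean
#' scaled intensities, cluster composition, and (optionally) t-SNE
#' coordinates.
#'
#' @param result the list returned by [runPipeline()].
#' @param outDir optional directory to write one CSV per table.
#' @param doTsne compute t-SNE coordinates (default from the run's
#'   parameters; pass FALSE to skip).
#' @return (invisibly) a named list of data.frames.
#' @export
compareGroupsReport <- function(result, outDir = NULL, doTsne = NULL) {
    samples <- result$samples
    scaled <- result$scaled
    cc <- result$consensus
    labels <- clusterLabels(cc)
    cd <- as.data.frame(colData(result$units))

    pop <- populationSummary(lapply(samples, `[[`, "assignment"))
    boxes <- pop$perSample

    ## paired dot plots: whole-sample means per feature, CTR vs EGF by pair
    sm <- combineUnits(lapply(samples, function(s)
        extractUnits(s$pt, s$assignment, "sample_mean",
                     .featureIndices(result))))
    smx <- assay(sm, "intensities")
    smd <- as.data.frame(colData(sm))
    pairedDots <- do.call(rbind, lapply(unique(smd$pair_id), function(pid) {
        a <- which(smd$pair_id == pid & smd$treatment == "CTR")
        b <- which(smd$pair_id == pid & smd$treatment == "EGF")
        if (!length(a) || !length(b)) return(NULL)
        data.frame(pair_id = pid, feature = rownames(smx),
                   ctr = smx[, a[1L]], egf = smx[, b[1L]])
    }))
    rownames(pairedDots) <- NULL

    ## paired treatment test per feature (paired by matrix application round)
    treatTests <- .pairedFeatureTests(smx, smd)

    orgUnits <- combineUnits(lapply(samples, function(s)
        suppressWarnings(extractUnits(s$pt, s$assignment,
                                      "organization_mean",
                                      .featureIndices(result)))))
    orgTab <- data.frame(as.data.frame(colData(orgUnits)),
                         t(assay(orgUnits, "intensities")),
                         check.names = FALSE)

    pcaTab <- data.frame(cd[, c("sample_id", "treatment", "pair_id")],
                         cluster = labels, result$pca$scores,
                         check.names = FALSE)

    sx <- assay(scaled, "scaled")
    heat <- t(vapply(sort(unique(labels)), function(k)
        rowMeans(sx[, labels == k, drop = FALSE]), numeric(nrow(sx))))
    rownames(heat) <- paste0("C", sort(unique(labels)))
    heatmap <- data.frame(cluster = rownames(heat), heat, check.names = FALSE)

    comp <- as.data.frame.matrix(prop.table(
        table(cluster = labels, treatment = cd$treatment), margin = 1L))
    comp <- data.frame(cluster = rownames(comp), comp, check.names = FALSE)

    out <- list(population_boxes = boxes, paired_dots = pairedDots,
                treatment_tests = treatTests, organization_means = orgTab,
                pca_scores = pcaTab, heatmap_matrix = heatmap,
                cluster_composition = comp)
    if (is.null(doTsne)) doTsne <- isTRUE(result$report$parameters$doTsne)
    if (doTsne) {
        Y <- tsneEmbed(scaled, seed = result$report$seed)
        out$tsne_coords <- data.frame(cd[, c("sample_id", "treatment")],
                                      cluster = labels,
                                      tsne1 = Y[, 1L], tsne2 = Y[, 2L])
    }
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        for (nm in names(out))
            utils::write.csv(out[[nm]],
                             file.path(outDir, paste0(nm, ".csv")),
                             row.names = FALSE)
    }
    invisible(out)
}

.featureIndices <- function(result) {
    anyPt <- result$samples[[1L]]$pt
    match(rowData(result$units)$mz, anyPt@featureMz)
}

.pairedFeatureTests <- function(smx, smd) {
    pairs <- unique(smd$pair_id)
    a <- vapply(pairs, function(pid)
        smx[, which(smd$pair_id == pid & smd$treatment == "CTR")[1L]],
        numeric(nrow(smx)))
    b <- vapply(pairs, function(pid)
        smx[, which(smd$pair_id == pid & smd$treatment == "EGF")[1L]],
        numeric(nrow(smx)))
    if (length(pairs) < 2L)
        return(data.frame(feature = rownames(smx), t = NA_real_,
                          p_raw = NA_real_, p_adj = NA_real_))
    res <- lapply(seq_len(nrow(smx)), function(f) {
        tt <- pairedTTest(b[f, ], a[f, ])
        data.frame(feature = rownames(smx)[f], t = tt$t, p_raw = tt$p)
    })
    out <- do.call(rbind, res)
    out$p_adj <- bonferroniAdjust(out$p_raw)
    out
}
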