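## Synthetic single-cell MALDI-MSI experiments with known ground truth.
##
## The generator emulates the structure of the emulated assay: adherent cells
## on a conductive slide, imaged at 10 um pitch over m/z 500-1000, with a
## co-registered brightfield micrograph; intensities are produced directly as
## centroided peak heights (profile-mode spectra are generated separately for
## exercising the peak picker).

#' Simulation configuration
#'
#' All knobs of the synthetic-data generator. Defaults encode the emulated
#' study conditions: 10 um pixel pitch, m/z 500-1000, a 60-feature panel of
#' which 46 are cell-specific lipid features with class-structured treatment
#' effects (PA/PS/PE/PI-like features decrease under EGF, PG/LPI-like features
#' increase), multiplicative per-batch (matrix application) factors, and
#' log-normal intensity noise.
#'
#' @slot gridShape MSI grid (rows, cols) in pixels.
#' @slot pixelUm pixel pitch, micrometres (default 10).
#' @slot nFeatures total number of m/z features, cell-specific plus
#'   matrix-cluster background features.
#' @slot mzRange m/z interval in Da (default 500-1000).
#' @slot nColonies,nSingletons number of cohesive colonies (unions of >= 2
#'   overlapping discs) and dispersed single cells (single discs with area
#'   drawn inside 100-2500 um^2).
#' @slot colonyRadiusPx disc radius range for colony discs, in MSI pixels.
#' @slot treatment \code{"CTR"} or \code{"EGF"}.
#' @slot pairId matrix-application batch label.
#' @slot batchScale multiplicative batch factor applied to all intensities.
#' @slot effectMap per-feature log2 treatment effect applied multiplicatively
#'   on cell pixels of EGF samples; length 0 means "use the panel default".
#' @slot subpopSpec list of \code{list(fraction=, shift=)} planted single-cell
#'   subpopulations; shifts are per-cell-specific-feature log2 offsets.
#' @slot noiseCv coefficient of variation of the mean-preserving log-normal
#'   intensity noise.
#' @slot bfUmPerPx brightfield scale, micrometres per pixel.
#' @slot seed RNG seed for this sample.
#' @slot panelSeed RNG seed for the feature panel; keep it constant across the
#'   samples of one experiment so all samples share one feature axis.
#' @seealso [simulateExperiment()], [simulateSingleCellMatrix()],
#'   [lipidFeaturePanel()]
#' @name SimConfig-class
#' @exportClass SimConfig
setClass("SimConfig", representation(
    gridShape = "integer", pixelUm = "numeric", nFeatures = "integer",
    mzRange = "numeric", nColonies = "integer", nSingletons = "integer",
    colonyRadiusPx = "numeric", treatment = "character", pairId = "character",
    batchScale = "numeric", effectMap = "numeric", subpopSpec = "list",
    noiseCv = "numeric", bfUmPerPx = "numeric", seed = "integer",
    panelSeed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- NULL
    if (any(object@gridShape < 1L)) msg <- c(msg, "gridShape must be positive")
    if (object@mzRange[1L] >= object@mzRange[2L])
        msg <- c(msg, "mzRange low must be below high")
    if (object@noiseCv < 0) msg <- c(msg, "noiseCv must be >= 0")
    if (object@batchScale <= 0) msg <- c(msg, "batchScale must be positive")
    if (!object@treatment %in% c("CTR", "EGF"))
        msg <- c(msg, "treatment must be CTR or EGF")
    if (length(object@subpopSpec)) {
        fr <- vapply(object@subpopSpec, function(s) s$fraction, numeric(1))
        if (abs(sum(fr) - 1) > 1e-8)
            msg <- c(msg, "subpopulation fractions must sum to 1")
        if (any(fr <= 0)) msg <- c(msg, "subpopulation fractions must be positive")
    }
    if (length(object@effectMap) &&
        length(object@effectMap) != object@nFeatures)
        msg <- c(msg, "effectMap must have one entry per feature")
    if (is.null(msg)) TRUE else msg
})

#' @param gridShape,pixelUm,nFeatures,mzRange,nColonies,nSingletons,colonyRadiusPx,treatment,pairId,batchScale,effectMap,subpopSpec,noiseCv,bfUmPerPx,seed,panelSeed
#'   see the class slots.
#' @rdname SimConfig-class
#' @export
simConfig <- function(gridShape = c(120L, 120L), pixelUm = 10,
                      nFeatures = 60L, mzRange = c(500, 1000),
                      nColonies = 6L, nSingletons = 20L,
                      colonyRadiusPx = c(3, 4.5), treatment = "CTR",
                      pairId = "pair1", batchScale = 1,
                      effectMap = numeric(0),
                      subpopSpec = list(list(fraction = 1, shift = 0)),
                      noiseCv = 0.2, bfUmPerPx = 0.65, seed = 1L,
                      panelSeed = 20260101L) {
    new("SimConfig", gridShape = as.integer(gridShape),
        pixelUm = as.numeric(pixelUm), nFeatures = as.integer(nFeatures),
        mzRange = as.numeric(mzRange), nColonies = as.integer(nColonies),
        nSingletons = as.integer(nSingletons),
        colonyRadiusPx = as.numeric(colonyRadiusPx), treatment = treatment,
        pairId = pairId, batchScale = as.numeric(batchScale),
        effectMap = as.numeric(effectMap), subpopSpec = subpopSpec,
        noiseCv = as.numeric(noiseCv), bfUmPerPx = as.numeric(bfUmPerPx),
        seed = as.integer(seed), panelSeed = as.integer(panelSeed))
}

#' Ground truth of a simulated experiment
#'
#' @slot cellMask logical grid: which pixels carry cell signal.
#' @slot cellIdMap integer grid, 0 = background, otherwise the planted cell
#'   (or colony) id.
#' @slot organizationMap named character: dispersed/cohesive per planted id.
#' @slot cellSpecificFeatures indices of the features planted at >= 5x
#'   background on cell pixels.
#' @slot subpopLabels integer subpopulation per cell (named by cell id for
#'   imaging simulations).
#' @slot batchFactors named multiplicative batch factors.
#' @slot panel the feature panel data.frame used (see [lipidFeaturePanel()]).
#' @name SimTruth-class
#' @exportClass SimTruth
setClass("SimTruth", representation(
    cellMask = "matrix", cellIdMap = "matrix", organizationMap = "character",
    cellSpecificFeatures = "integer", subpopLabels = "integer",
    batchFactors = "numeric", panel = "data.frame"))

## class template mirrors the composition of the emulated 46-peak panel:
## 2 PA, 3 PS, 5 PE, 14 PI, 2 PG, 1 LPI change under treatment, the rest are
## unaffected lipid peaks. Effects are log2 fold changes on cell pixels.
.lipidClassTemplate <- data.frame(
    class = c("PA", "PS", "PE", "PI", "PG", "LPI", "other"),
    count46 = c(2L, 3L, 5L, 14L, 2L, 1L, 19L),
    effectLog2 = c(-1, -0.8, -0.8, -1, 1, 1.2, 0))

#' Generate the synthetic lipid feature panel
#'
#' Builds the per-feature ground truth shared by all samples of one simulated
#' experiment: feature m/z positions, lipid class labels, on-cell and
#' background mean intensities, the cell-specific flag, and the default
#' treatment effect map. Roughly three quarters of the features are
#' cell-specific lipid peaks whose TIC-normalized cell/background intensity
#' ratio is planted in [6, 15]; the remainder emulate MALDI matrix clusters
#' that dominate the cell-free background (normalized ratio < 1), so the 5x
#' cell-specificity filter has signal to reject. Background matrix intensity
#' is scaled so cell pixels carry about twice the raw TIC of background
#' pixels.
#'
#' @param nFeatures total number of features.
#' @param mzRange m/z interval (Da).
#' @param seed RNG seed (the panel is deterministic given its arguments).
#' @return data.frame with columns \code{mz}, \code{class}, \code{cellMean},
#'   \code{bgMean}, \code{cellSpecific}, \code{effectLog2}.
#' @export
lipidFeaturePanel <- function(nFeatures = 60L, mzRange = c(500, 1000),
                              seed = 20260101L) {
    stopifnot(nFeatures >= 4L)
    old <- .Random.seed.save()
    on.exit(.Random.seed.restore(old))
    set.seed(seed)
    nMatrix <- max(2L, round(nFeatures * 14 / 60))
    nLipid <- nFeatures - nMatrix
    tmpl <- .lipidClassTemplate
    counts <- floor(tmpl$count46 / 46 * nLipid)
    rem <- nLipid - sum(counts)
    if (rem > 0) { # largest remainders first
        fr <- tmpl$count46 / 46 * nLipid - counts
        counts[order(fr, decreasing = TRUE)[seq_len(rem)]] <-
            counts[order(fr, decreasing = TRUE)[seq_len(rem)]] + 1L
    }
    lipidClass <- rep(tmpl$class, counts)
    lipidEffect <- rep(tmpl$effectLog2, counts)

    ## evenly spaced centres with jitter keeps features >~ 1 Da apart
    grid <- seq(mzRange[1L] + 2, mzRange[2L] - 2, length.out = nFeatures)
    mz <- sort(grid + stats::runif(nFeatures, -0.3, 0.3))

    rho <- 2                        # target raw TIC ratio, cell over background
    cellMeanLipid <- stats::rlnorm(nLipid, log(200), 0.5)
    ratioNorm <- stats::runif(nLipid, 6, 15)
    bgMeanLipid <- cellMeanLipid / (ratioNorm * rho)
    u <- stats::runif(nMatrix, 0.6, 1.5) # on-cell attenuation of matrix peaks
    w <- stats::rlnorm(nMatrix, log(100), 0.4)
    ## scale matrix background so total background TIC = total cell TIC / rho
    s <- (sum(cellMeanLipid) - rho * sum(bgMeanLipid)) /
        (rho * sum(w) - sum(u * w))
    bgMeanMatrix <- s * w
    cellMeanMatrix <- u * bgMeanMatrix

    idx <- sample.int(nFeatures)    # interleave lipid and matrix features
    panel <- data.frame(
        mz = mz,
        class = c(lipidClass, rep("matrix", nMatrix))[idx],
        cellMean = c(cellMeanLipid, cellMeanMatrix)[idx],
        bgMean = c(bgMeanLipid, bgMeanMatrix)[idx],
        cellSpecific = c(rep(TRUE, nLipid), rep(FALSE, nMatrix))[idx],
        effectLog2 = c(lipidEffect, rep(0, nMatrix))[idx])
    rownames(panel) <- sprintf("mz%.4f", panel$mz)
    panel
}

.Random.seed.save <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed.restore <- function(old) {
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

## mean-preserving multiplicative log-normal noise
.lnNoise <- function(n, cv) {
    if (cv <= 0) return(rep(1, n))
    s2 <- log(1 + cv^2)
    exp(stats::rnorm(n, -s2 / 2, sqrt(s2)))
}

## Place discs (singletons) and multi-disc colonies without overlap and with
## >= sepPx pixels of background between any two objects. Returns a list of
## objects, each a data.frame of disc centres (um) and radii (um).
.placeObjects <- function(cfg) {
    rows <- cfg@gridShape[1L]; cols <- cfg@gridShape[2L]; px <- cfg@pixelUm
    sepUm <- 3 * px                     # centre-to-edge safety margin
    objects <- list(); kinds <- character(0)

    colonyR <- stats::runif(cfg@nColonies, cfg@colonyRadiusPx[1L],
                            cfg@colonyRadiusPx[2L]) * px
    ## um^2, well inside the 100-2500 single-cell window so that blur-induced
    ## shrinkage of the measured area never straddles the filter boundary
    singleArea <- stats::runif(cfg@nSingletons, 250, 650)
    singleR <- sqrt(singleArea / pi)

    ## effective radius of each object (colony span ~ 2 discs overlapping)
    effR <- c(colonyR * 2.2, singleR)
    kind <- c(rep("cohesive", cfg@nColonies), rep("dispersed", cfg@nSingletons))
    baseR <- c(colonyR, singleR)
    margin <- effR + px
    if (length(margin) && 2 * max(margin) >= min(rows, cols) * px)
        stop("objects cannot fit in the grid without wrapping")

    centres <- matrix(NA_real_, length(effR), 2L)
    for (i in seq_along(effR)) {
        placed <- FALSE
        for (try in seq_len(4000L)) {
            if (kind[i] == "dispersed") {
                ## snap near a pixel centre so small discs always cover one
                pr <- sample.int(rows, 1L) - 1L; pc <- sample.int(cols, 1L) - 1L
                cand <- c((pr + 0.5) * px, (pc + 0.5) * px) +
                    stats::runif(2L, -2, 2)
            } else {
                cand <- c(stats::runif(1L, margin[i], rows * px - margin[i]),
                          stats::runif(1L, margin[i], cols * px - margin[i]))
            }
            if (cand[1L] < margin[i] || cand[1L] > rows * px - margin[i] ||
                cand[2L] < margin[i] || cand[2L] > cols * px - margin[i])
                next
            ok <- TRUE
            for (j in seq_len(i - 1L)) {
                if (sqrt(sum((cand - centres[j, ])^2)) <
                    effR[i] + effR[j] + sepUm) { ok <- FALSE; break }
            }
            if (ok) { centres[i, ] <- cand; placed <- TRUE; break }
        }
        if (!placed)
            stop("could not place all objects without overlap; ",
                 "reduce counts or enlarge the grid")
    }

    for (i in seq_along(effR)) {
        if (kind[i] == "dispersed") {
            objects[[i]] <- data.frame(y = centres[i, 1L], x = centres[i, 2L],
                                       r = baseR[i])
        } else {
            nd <- sample(2:4, 1L)
            ## overlapping discs strung around the colony centre
            ang <- stats::runif(nd, 0, 2 * pi)
            off <- stats::runif(nd, 0.3, 0.9) * baseR[i]
            objects[[i]] <- data.frame(y = centres[i, 1L] + off * sin(ang),
                                       x = centres[i, 2L] + off * cos(ang),
                                       r = baseR[i] *
                                           stats::runif(nd, 0.8, 1.1))
        }
        kinds[i] <- kind[i]
    }
    list(objects = objects, kind = kinds)
}

## id map over the full grid from disc unions; pixel centre membership
.rasterizeObjects <- function(objects, gridShape, pixelUm) {
    rows <- gridShape[1L]; cols <- gridShape[2L]
    idMap <- matrix(0L, rows, cols)
    yc <- (seq_len(rows) - 0.5) * pixelUm
    xc <- (seq_len(cols) - 0.5) * pixelUm
    for (i in seq_along(objects)) {
        d <- objects[[i]]
        for (k in seq_len(nrow(d))) {
            rs <- which(abs(yc - d$y[k]) <= d$r[k])
            cs <- which(abs(xc - d$x[k]) <= d$r[k])
            if (!length(rs) || !length(cs)) next
            dd <- outer((yc[rs] - d$y[k])^2, (xc[cs] - d$x[k])^2, "+")
            hit <- which(dd <= d$r[k]^2, arr.ind = TRUE)
            if (nrow(hit))
                idMap[cbind(rs[hit[, 1L]], cs[hit[, 2L]])] <- i
        }
    }
    idMap
}

#' Simulate one MSI acquisition with matched brightfield image
#'
#' Generates a full synthetic sample: an \linkS4class{MSIDataset} of centroided
#' peak heights over the shared feature axis, a co-registered
#' \linkS4class{BrightfieldImage} rendering cells as dark blobs on a bright
#' background, and the \linkS4class{SimTruth}. Background pixels carry only
#' the matrix-like background levels of the panel; cell pixels carry the
#' cell-specific features at the planted >= 5x normalized ratio; EGF treatment
#' effects, subpopulation shifts and the batch factor act multiplicatively on
#' the appropriate intensities.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list with elements \code{msi}, \code{brightfield}, \code{truth}.
#' @examples
#' sim <- simulateExperiment(simConfig(gridShape = c(60, 60), nColonies = 2,
#'                                     nSingletons = 5, seed = 11))
#' sim$msi
#' sum(sim$truth@cellMask)
#' @export
simulateExperiment <- function(config) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    panel <- lipidFeaturePanel(config@nFeatures, config@mzRange,
                               config@panelSeed)
    effect <- if (length(config@effectMap)) config@effectMap else
        panel$effectLog2
    set.seed(config@seed)

    if (config@nColonies + config@nSingletons > 0L) {
        pl <- .placeObjects(config)
        idMap <- .rasterizeObjects(pl$objects, config@gridShape, config@pixelUm)
        orgMap <- pl$kind
        names(orgMap) <- as.character(seq_along(pl$objects))
    } else {
        pl <- list(objects = list(), kind = character(0))
        idMap <- matrix(0L, config@gridShape[1L], config@gridShape[2L])
        orgMap <- character(0)
    }
    mask <- idMap > 0L

    nObj <- length(pl$objects)
    nSub <- length(config@subpopSpec)
    subLab <- integer(0)
    if (nObj) {
        fr <- vapply(config@subpopSpec, function(s) s$fraction, numeric(1))
        subLab <- sample.int(nSub, nObj, replace = TRUE, prob = fr)
        names(subLab) <- as.character(seq_len(nObj))
    }

    rows <- config@gridShape[1L]; cols <- config@gridShape[2L]
    coords <- cbind(row = rep(seq_len(rows) - 1L, times = cols),
                    col = rep(seq_len(cols) - 1L, each = rows))
    nPix <- nrow(coords)
    nF <- config@nFeatures
    pixId <- as.vector(idMap)       # column-major matches coords above
    means <- matrix(rep(panel$bgMean, each = nPix), nPix, nF)
    cellPix <- pixId > 0L
    if (any(cellPix)) {
        cellMeans <- matrix(rep(panel$cellMean, each = sum(cellPix)),
                            sum(cellPix), nF)
        if (config@treatment == "EGF")
            cellMeans <- sweep(cellMeans, 2L, 2^effect, "*")
        if (nSub > 1L || any(vapply(config@subpopSpec,
                                    function(s) any(s$shift != 0), logical(1)))) {
            shiftIdx <- which(panel$cellSpecific)
            for (s in seq_len(nSub)) {
                rowsS <- which(subLab[pixId[cellPix]] == s)
                sh <- config@subpopSpec[[s]]$shift
                if (length(rowsS) && any(sh != 0)) {
                    sh <- rep_len(sh, length(shiftIdx))
                    cellMeans[rowsS, shiftIdx] <-
                        sweep(cellMeans[rowsS, shiftIdx, drop = FALSE], 2L,
                              2^sh, "*")
                }
            }
        }
        means[cellPix, ] <- cellMeans
    }
    vals <- means * config@batchScale *
        matrix(.lnNoise(nPix * nF, config@noiseCv), nPix, nF)

    msi <- MSIDataset(vals, panel$mz, coords, config@gridShape,
                      pixelUm = config@pixelUm,
                      sampleId = paste0(config@treatment, "_", config@pairId),
                      treatment = config@treatment, pairId = config@pairId,
                      metadata = list(centroided = TRUE))

    bf <- .renderBrightfield(pl$objects, config)

    truth <- new("SimTruth", cellMask = matrix(as.vector(mask), rows, cols),
                 cellIdMap = idMap, organizationMap = orgMap,
                 cellSpecificFeatures = which(panel$cellSpecific),
                 subpopLabels = subLab,
                 batchFactors = stats::setNames(config@batchScale,
                                                config@pairId),
                 panel = panel)
    list(msi = msi, brightfield = bf, truth = truth)
}

.renderBrightfield <- function(objects, cfg) {
    bfRows <- ceiling(cfg@gridShape[1L] * cfg@pixelUm / cfg@bfUmPerPx)
    bfCols <- ceiling(cfg@gridShape[2L] * cfg@pixelUm / cfg@bfUmPerPx)
    img <- matrix(0.85, bfRows, bfCols)
    yc <- (seq_len(bfRows) - 0.5) * cfg@bfUmPerPx
    xc <- (seq_len(bfCols) - 0.5) * cfg@bfUmPerPx
    for (d in objects) {
        for (k in seq_len(nrow(d))) {
            rs <- which(abs(yc - d$y[k]) <= d$r[k])
            cs <- which(abs(xc - d$x[k]) <= d$r[k])
            if (!length(rs) || !length(cs)) next
            dd <- outer((yc[rs] - d$y[k])^2, (xc[cs] - d$x[k])^2, "+")
            hit <- which(dd <= d$r[k]^2, arr.ind = TRUE)
            if (nrow(hit))
                img[cbind(rs[hit[, 1L]], cs[hit[, 2L]])] <- 0.25
        }
    }
    if (cfg@noiseCv > 0)
        img <- img + matrix(stats::rnorm(length(img), 0, 0.02),
                            nrow(img), ncol(img))
    BrightfieldImage(img, cfg@bfUmPerPx)
}

#' Simulate a single-cell feature matrix directly
#'
#' Bypasses imaging: draws \code{nCells} cells from the planted subpopulation
#' mixture and produces their lipid feature matrix (cell-specific features
#' only) with treatment effects, subpopulation shifts, the batch factor and
#' mean-preserving log-normal noise applied. Used to exercise batch
#' correction and the consensus clustering with exact ground truth.
#'
#' @param config a \linkS4class{SimConfig}; \code{subpopSpec} must be
#'   non-empty.
#' @param nCells number of cells to draw (must be >= the number of planted
#'   subpopulations).
#' @return list with \code{matrix} (a \linkS4class{CellFeatureMatrix}) and
#'   \code{truth} (a \linkS4class{SimTruth} carrying \code{subpopLabels}).
#' @examples
#' cfg <- simConfig(subpopSpec = list(list(fraction = 0.5, shift = 1),
#'                                    list(fraction = 0.5, shift = -1)),
#'                  noiseCv = 0.1, seed = 3)
#' sim <- simulateSingleCellMatrix(cfg, 100)
#' table(sim$truth@subpopLabels)
#' @export
simulateSingleCellMatrix <- function(config, nCells) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    if (!length(config@subpopSpec)) stop("subpopSpec must be non-empty")
    nSub <- length(config@subpopSpec)
    if (nCells < nSub)
        stop("nCells must be at least the number of subpopulations")
    panel <- lipidFeaturePanel(config@nFeatures, config@mzRange,
                               config@panelSeed)
    feat <- which(panel$cellSpecific)
    effect <- if (length(config@effectMap)) config@effectMap[feat] else
        panel$effectLog2[feat]
    set.seed(config@seed)
    fr <- vapply(config@subpopSpec, function(s) s$fraction, numeric(1))
    lab <- sample.int(nSub, nCells, replace = TRUE, prob = fr)

    base <- panel$cellMean[feat]
    if (config@treatment == "EGF") base <- base * 2^effect
    m <- matrix(rep(base, each = nCells), nCells, length(feat))
    for (s in seq_len(nSub)) {
        sh <- rep_len(config@subpopSpec[[s]]$shift, length(feat))
        if (any(sh != 0))
            m[lab == s, ] <- sweep(m[lab == s, , drop = FALSE], 2L, 2^sh, "*")
    }
    m <- m * config@batchScale *
        matrix(.lnNoise(nCells * length(feat), config@noiseCv),
               nCells, length(feat))
    ann <- data.frame(
        sample_id = paste0(config@treatment, "_", config@pairId),
        treatment = config@treatment, pair_id = config@pairId,
        organization = "dispersed")
    cfm <- CellFeatureMatrix(m, ann[rep(1L, nCells), , drop = FALSE],
                             featureMz = panel$mz[feat])
    truth <- new("SimTruth", cellMask = matrix(FALSE, 0, 0),
                 cellIdMap = matrix(0L, 0, 0), organizationMap = character(0),
                 cellSpecificFeatures = feat, subpopLabels = lab,
                 batchFactors = stats::setNames(config@batchScale,
                                                config@pairId),
                 panel = panel)
    list(matrix = cfm, truth = truth)
}

#' Simulate a profile-mode spectrum with Gaussian peak shapes
#'
#' Renders peaks of given centres and heights as Gaussians of fixed FWHM on a
#' regular m/z axis, plus i.i.d. Gaussian baseline noise. Only used to
#' exercise peak picking; the imaging simulator emits centroided intensities
#' directly.
#'
#' @param peaks data.frame with columns \code{mz} and \code{height}.
#' @param mzRange,stepDa axis interval and spacing.
#' @param fwhmDa peak full width at half maximum.
#' @param noiseSd baseline noise standard deviation.
#' @param seed RNG seed.
#' @return list with \code{mz} and \code{intensity} vectors.
#' @export
simulateProfileSpectrum <- function(peaks, mzRange = c(500, 1000),
                                    stepDa = 0.05, fwhmDa = 0.3,
                                    noiseSd = 1, seed = 1L) {
    set.seed(seed)
    mz <- seq(mzRange[1L], mzRange[2L], by = stepDa)
    y <- stats::rnorm(length(mz), 0, noiseSd)
    sigma <- fwhmDa / (2 * sqrt(2 * log(2)))
    for (i in seq_len(nrow(peaks)))
        y <- y + peaks$height[i] * exp(-(mz - peaks$mz[i])^2 / (2 * sigma^2))
    list(mz = mz, intensity = y)
}
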