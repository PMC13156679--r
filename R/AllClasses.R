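#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
NULL

## ---------------------------------------------------------------------------
## Virtual pixel-grid scaffold shared by all per-pixel containers
## ---------------------------------------------------------------------------

#' Virtual base class for objects living on an MSI pixel grid
#'
#' Stores 0-based (row, col) pixel coordinates, the rectangular grid shape and
#' the pixel pitch in micrometres. Not instantiated directly.
#'
#' @slot coords integer matrix with columns \code{row}, \code{col} (0-based).
#' @slot gridShape integer vector (rows, cols) of the acquisition grid.
#' @slot pixelUm pixel pitch in micrometres (10 for the emulated assay).
#' @name PixelGrid-class
#' @exportClass PixelGrid
setClass("PixelGrid", representation("VIRTUAL",
    coords = "matrix",
    gridShape = "integer",
    pixelUm = "numeric"))

.validPixelGrid <- function(object) {
    msg <- NULL
    co <- object@coords
    if (ncol(co) != 2L)
        msg <- c(msg, "'coords' must have two columns (row, col)")
    if (length(object@gridShape) != 2L || any(object@gridShape < 1L))
        msg <- c(msg, "'gridShape' must be two positive integers")
    if (length(object@pixelUm) != 1L || object@pixelUm <= 0)
        msg <- c(msg, "'pixelUm' must be a positive scalar")
    if (nrow(co)) {
        if (anyDuplicated(co[, 1L] * object@gridShape[2L] + co[, 2L]))
            msg <- c(msg, "pixel coordinates must be unique")
        if (min(co) < 0L || any(co[, 1L] >= object@gridShape[1L]) ||
            any(co[, 2L] >= object@gridShape[2L]))
            msg <- c(msg, "coordinates outside the grid")
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("PixelGrid", .validPixelGrid)

## ---------------------------------------------------------------------------
## MSIDataset
## ---------------------------------------------------------------------------

#' Per-pixel MSI spectra on a rectangular grid
#'
#' Holds one spectrum per retained pixel over a shared, strictly increasing
#' m/z axis, together with the sample annotations used downstream (treatment
#' group and the matrix-application pair that defines the batch). Spectra may
#' be profile mode (dense m/z axis) or centroided peak heights; the axis is
#' shared either way.
#'
#' @slot spectra numeric matrix, pixels x m/z bins, non-negative.
#' @slot mz shared m/z axis in Da, strictly increasing.
#' @slot sampleId,treatment,pairId sample annotations; \code{treatment} is
#'   \code{"CTR"} or \code{"EGF"}, \code{pairId} identifies the matrix
#'   application round shared by a CTR/EGF slide pair.
#' @slot metadata free-form list (the simulator stores its ground truth here
#'   is \emph{not} the case -- truth travels separately; this holds flags such
#'   as the TIC normalization target).
#' @seealso [simulateExperiment()], [ticNormalize()], [asPeakTable()]
#' @name MSIDataset-class
#' @exportClass MSIDataset
setClass("MSIDataset", contains = "PixelGrid", representation(
    spectra = "matrix",
    mz = "numeric",
    sampleId = "character",
    treatment = "character",
    pairId = "character",
    metadata = "list"))

setValidity("MSIDataset", function(object) {
    msg <- NULL
    if (nrow(object@spectra) != nrow(object@coords))
        msg <- c(msg, "one spectrum per pixel required")
    if (ncol(object@spectra) != length(object@mz))
        msg <- c(msg, "spectra columns must match the m/z axis")
    if (length(object@mz) > 1L && any(diff(object@mz) <= 0))
        msg <- c(msg, "m/z axis must be strictly increasing")
    if (nrow(object@spectra) && min(object@spectra) < 0)
        msg <- c(msg, "intensities must be non-negative")
    if (is.null(msg)) TRUE else msg
})

#' @param spectra,mz,coords,gridShape,pixelUm,sampleId,treatment,pairId,metadata
#'   see the class slots.
#' @rdname MSIDataset-class
#' @export
MSIDataset <- function(spectra, mz, coords, gridShape,
                       pixelUm = 10, sampleId = "sample1",
                       treatment = "CTR", pairId = "pair1",
                       metadata = list()) {
    co <- as.matrix(coords)
    storage.mode(co) <- "integer"
    colnames(co) <- c("row", "col")
    new("MSIDataset", spectra = as.matrix(spectra), mz = as.numeric(mz),
        coords = co, gridShape = as.integer(gridShape),
        pixelUm = as.numeric(pixelUm), sampleId = sampleId,
        treatment = treatment, pairId = pairId, metadata = metadata)
}

## ---------------------------------------------------------------------------
## PeakTable
## ---------------------------------------------------------------------------

#' Centroided pixel x feature intensity table
#'
#' The product of peak picking and alignment (or of [asPeakTable()] on already
#' centroided data): consensus feature m/z centres, a non-negative pixels x
#' features matrix, and the per-pixel total ion current \emph{before} TIC
#' normalization, which downstream cell detection uses to identify the cell
#' cluster.
#'
#' @slot intensities pixels x features matrix.
#' @slot featureMz consensus feature centres (Da), ascending.
#' @slot tic per-pixel raw TIC recorded before any normalization.
#' @slot normalized logical flag set by [ticNormalize()].
#' @slot sampleId,treatment,pairId,metadata as in \linkS4class{MSIDataset}.
#' @name PeakTable-class
#' @exportClass PeakTable
setClass("PeakTable", contains = "PixelGrid", representation(
    intensities = "matrix",
    featureMz = "numeric",
    tic = "numeric",
    normalized = "logical",
    sampleId = "character",
    treatment = "character",
    pairId = "character",
    metadata = "list"))

setValidity("PeakTable", function(object) {
    msg <- NULL
    if (nrow(object@intensities) != nrow(object@coords))
        msg <- c(msg, "one row per pixel required")
    if (ncol(object@intensities) != length(object@featureMz))
        msg <- c(msg, "columns must match featureMz")
    if (length(object@featureMz) > 1L && is.unsorted(object@featureMz))
        msg <- c(msg, "featureMz must be ascending")
    if (length(object@tic) != nrow(object@intensities))
        msg <- c(msg, "tic must have one entry per pixel")
    if (nrow(object@intensities) && min(object@intensities) < 0)
        msg <- c(msg, "intensities must be non-negative")
    if (is.null(msg)) TRUE else msg
})

#' @param intensities,featureMz,coords,gridShape,pixelUm,tic,normalized,sampleId,treatment,pairId,metadata
#'   see the class slots; \code{tic} defaults to the row sums.
#' @rdname PeakTable-class
#' @export
PeakTable <- function(intensities, featureMz, coords, gridShape,
                      pixelUm = 10, tic = NULL, normalized = FALSE,
                      sampleId = "sample1", treatment = "CTR",
                      pairId = "pair1", metadata = list()) {
    intensities <- as.matrix(intensities)
    if (is.null(tic)) tic <- rowSums(intensities)
    co <- as.matrix(coords)
    storage.mode(co) <- "integer"
    colnames(co) <- c("row", "col")
    new("PeakTable", intensities = intensities,
        featureMz = as.numeric(featureMz), coords = co,
        gridShape = as.integer(gridShape), pixelUm = as.numeric(pixelUm),
        tic = as.numeric(tic), normalized = normalized, sampleId = sampleId,
        treatment = treatment, pairId = pairId, metadata = metadata)
}

## ---------------------------------------------------------------------------
## PixelPartition
## ---------------------------------------------------------------------------

#' Pixel clustering into cell and background classes
#'
#' Result of [spatialKmeans()]: an integer cluster label per pixel plus the
#' identity of the cluster deemed to contain cells (highest mean raw TIC,
#' ties broken towards the larger cluster).
#'
#' @slot labels integer cluster label per pixel (1..k).
#' @slot cellLabel the label of the cell cluster.
#' @name PixelPartition-class
#' @exportClass PixelPartition
setClass("PixelPartition", contains = "PixelGrid", representation(
    labels = "integer",
    cellLabel = "integer"))

setValidity("PixelPartition", function(object) {
    msg <- NULL
    if (length(object@labels) != nrow(object@coords))
        msg <- c(msg, "one label per pixel required")
    if (length(object@cellLabel) != 1L ||
        !(object@cellLabel %in% object@labels))
        msg <- c(msg, "cellLabel must be one of the labels")
    if (is.null(msg)) TRUE else msg
})

## ---------------------------------------------------------------------------
## BrightfieldImage
## ---------------------------------------------------------------------------

#' Grayscale brightfield micrograph co-registered to an MSI grid
#'
#' Registration to the MSI grid is an axis-aligned scale plus translation
#' (optionally with axis flips): a brightfield pixel (r, c) maps to physical
#' position \code{originOffsetUm + (r + 0.5, c + 0.5) * umPerPx}, and MSI
#' pixel (R, C) covers \code{[R, R+1) x [C, C+1) * pixelUm}.
#'
#' @slot pixels numeric matrix of gray levels (any scale).
#' @slot umPerPx micrometres per brightfield pixel.
#' @slot originOffsetUm translation (row, col) of the brightfield origin
#'   relative to the MSI origin, in micrometres.
#' @slot flip logical (row, col): whether each axis is mirrored.
#' @name BrightfieldImage-class
#' @exportClass BrightfieldImage
setClass("BrightfieldImage", representation(
    pixels = "matrix",
    umPerPx = "numeric",
    originOffsetUm = "numeric",
    flip = "logical"))

setValidity("BrightfieldImage", function(object) {
    msg <- NULL
    if (!length(object@pixels)) msg <- c(msg, "empty image")
    if (length(object@umPerPx) != 1L || object@umPerPx <= 0)
        msg <- c(msg, "'umPerPx' must be a positive scalar")
    if (length(object@originOffsetUm) != 2L)
        msg <- c(msg, "'originOffsetUm' must have length 2")
    if (length(object@flip) != 2L) msg <- c(msg, "'flip' must have length 2")
    if (is.null(msg)) TRUE else msg
})

#' @param pixels,umPerPx,originOffsetUm,flip see the class slots.
#' @rdname BrightfieldImage-class
#' @export
BrightfieldImage <- function(pixels, umPerPx, originOffsetUm = c(0, 0),
                             flip = c(FALSE, FALSE)) {
    new("BrightfieldImage", pixels = as.matrix(pixels),
        umPerPx = as.numeric(umPerPx),
        originOffsetUm = as.numeric(originOffsetUm), flip = as.logical(flip))
}

## ---------------------------------------------------------------------------
## CellContours
## ---------------------------------------------------------------------------

#' Candidate cell outlines from a binary brightfield mask
#'
#' Each contour is an 8-connected foreground component, represented by its
#' filled pixel set together with the bounding-box statistics used by the
#' single-cell filter. Areas are component pixel counts times the squared
#' pixel size.
#'
#' @slot pixelIdx list of integer vectors: linear indices (column-major) of
#'   each component's pixels in the source image.
#' @slot areaUm2 component areas in square micrometres.
#' @slot bbox integer matrix with columns rmin, rmax, cmin, cmax (0-based,
#'   inclusive).
#' @slot aspectRatio bounding-box width / height (columns over rows).
#' @slot accepted logical filter verdict (all TRUE before filtering).
#' @slot umPerPx,imageDim geometry of the source image.
#' @name CellContours-class
#' @exportClass CellContours
setClass("CellContours", representation(
    pixelIdx = "list",
    areaUm2 = "numeric",
    bbox = "matrix",
    aspectRatio = "numeric",
    accepted = "logical",
    umPerPx = "numeric",
    imageDim = "integer"))

setValidity("CellContours", function(object) {
    n <- length(object@pixelIdx)
    msg <- NULL
    if (length(object@areaUm2) != n || length(object@aspectRatio) != n ||
        length(object@accepted) != n ||
        (n > 0L && nrow(object@bbox) != n))
        msg <- c(msg, "per-contour slots must have equal length")
    if (n && min(object@areaUm2) <= 0) msg <- c(msg, "areas must be positive")
    if (n && min(object@aspectRatio) <= 0)
        msg <- c(msg, "aspect ratios must be positive")
    if (is.null(msg)) TRUE else msg
})

## ---------------------------------------------------------------------------
## CellAssignment
## ---------------------------------------------------------------------------

#' Per-pixel cell identity and organization labels
#'
#' Produced by [assignPixels()]. Every pixel is either background
#' (organization \code{"none"}) or a cell pixel labelled \code{"dispersed"}
#' (belongs to exactly one accepted single-cell contour whose pixels form one
#' whole 4-connected component) or \code{"cohesive"} (part of a multi-cell
#' area). \code{cellId} is 0 for background and for cohesive areas not
#' traceable to a unique accepted contour.
#'
#' @slot isCell logical per pixel.
#' @slot cellId integer per pixel, 0 = unassigned.
#' @slot organization character per pixel: none / dispersed / cohesive.
#' @slot sampleId,treatment,pairId sample annotations carried through.
#' @name CellAssignment-class
#' @exportClass CellAssignment
setClass("CellAssignment", contains = "PixelGrid", representation(
    isCell = "logical",
    cellId = "integer",
    organization = "character",
    sampleId = "character",
    treatment = "character",
    pairId = "character"))

setValidity("CellAssignment", function(object) {
    msg <- NULL
    n <- nrow(object@coords)
    if (length(object@isCell) != n || length(object@cellId) != n ||
        length(object@organization) != n)
        msg <- c(msg, "per-pixel slots must match the pixel count")
    if (any(object@cellId > 0L & !object@isCell))
        msg <- c(msg, "cellId > 0 implies isCell")
    if (any((object@organization == "none") != !object@isCell))
        msg <- c(msg, "organization 'none' must coincide with background")
    if (!all(object@organization %in% c("none", "dispersed", "cohesive")))
        msg <- c(msg, "invalid organization label")
    if (is.null(msg)) TRUE else msg
})

## ---------------------------------------------------------------------------
## CellFeatureMatrix
## ---------------------------------------------------------------------------

#' Cells (or pooled regions) x lipid features
#'
#' A thin wrapper around \linkS4class{SingleCellExperiment}: lipid features
#' are rows, observational units (single dispersed cells, pooled
#' cohesive/dispersed regions or whole-sample means) are columns. The
#' \code{"intensities"} assay holds normalized, units-free intensities on the
#' linear scale; [zscoreScale()] adds a \code{"scaled"} assay. Column data
#' carries \code{sample_id}, \code{treatment}, \code{pair_id} and
#' \code{organization}.
#'
#' @name CellFeatureMatrix-class
#' @exportClass CellFeatureMatrix
setClass("CellFeatureMatrix", contains = "SingleCellExperiment")

.cfmRequiredCols <- c("sample_id", "treatment", "pair_id", "organization")

setValidity("CellFeatureMatrix", function(object) {
    msg <- NULL
    if (!"intensities" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "an 'intensities' assay is required")
    missing <- setdiff(.cfmRequiredCols,
                       colnames(SummarizedExperiment::colData(object)))
    if (length(missing))
        msg <- c(msg, paste("missing column annotations:",
                            paste(missing, collapse = ", ")))
    else {
        cd <- SummarizedExperiment::colData(object)[, .cfmRequiredCols]
        if (any(vapply(cd, function(x) anyNA(x), logical(1))))
            msg <- c(msg, "column annotations must be complete")
    }
    if ("intensities" %in% SummarizedExperiment::assayNames(object) &&
        anyNA(SummarizedExperiment::assay(object, "intensities")))
        msg <- c(msg, "missing values are not allowed")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "feature labels must be unique")
    if (is.null(msg)) TRUE else msg
})

#' @param values numeric matrix, units (cells) x features.
#' @param annotations data.frame with one row per unit and columns
#'   \code{sample_id}, \code{treatment}, \code{pair_id}, \code{organization}
#'   (plus any extras).
#' @param featureMz optional numeric feature m/z used as feature labels.
#' @rdname CellFeatureMatrix-class
#' @export
CellFeatureMatrix <- function(values, annotations, featureMz = NULL) {
    values <- as.matrix(values)
    if (nrow(values) != nrow(annotations))
        stop("'annotations' must have one row per unit")
    if (is.null(featureMz)) {
        labels <- colnames(values)
        if (is.null(labels))
            labels <- sprintf("feature%03d", seq_len(ncol(values)))
    } else {
        labels <- sprintf("mz%.4f", featureMz)
    }
    assay <- t(values)
    rownames(assay) <- labels
    if (is.null(rownames(values)))
        colnames(assay) <- sprintf("unit%04d", seq_len(ncol(assay)))
    rd <- S4Vectors::DataFrame(row.names = labels)
    if (!is.null(featureMz)) rd$mz <- as.numeric(featureMz)
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(intensities = assay),
        colData = S4Vectors::DataFrame(annotations, row.names = colnames(assay)),
        rowData = rd)
    out <- new("CellFeatureMatrix", sce)
    metadata(out)$scaled <- FALSE
    out
}

## ---------------------------------------------------------------------------
## CombatModel
## ---------------------------------------------------------------------------

#' Fitted empirical-Bayes batch correction model
#'
#' Parameters of the parametric location/scale batch model fitted by
#' [combatCorrect()] on log intensities: per-feature grand mean and pooled
#' variance, raw and shrunk per-batch location (\code{gammaHat},
#' \code{gammaStar}) and scale (\code{deltaHat}, \code{deltaStar})
#' adjustments, and the method-of-moments hyperparameters per batch.
#'
#' @slot grandMean,varPooled per-feature standardization parameters.
#' @slot gammaHat,gammaStar,deltaHat,deltaStar batches x features matrices.
#' @slot hyper list with per-batch gamma.bar, tau2, lambda (a.prior) and
#'   theta (b.prior).
#' @slot batches batch labels; @slot iterations EB iterations used per batch.
#' @name CombatModel-class
#' @exportClass CombatModel
setClass("CombatModel", representation(
    grandMean = "numeric",
    varPooled = "numeric",
    gammaHat = "matrix",
    gammaStar = "matrix",
    deltaHat = "matrix",
    deltaStar = "matrix",
    hyper = "list",
    batches = "character",
    iterations = "numeric"))

setValidity("CombatModel", function(object) {
    if (length(object@deltaStar) && min(object@deltaStar) <= 0)
        "delta_star must be positive" else TRUE
})

## ---------------------------------------------------------------------------
## ConsensusClustering
## ---------------------------------------------------------------------------

#' Subsampled SNN/Leiden consensus clustering result
#'
#' For every retained candidate cluster number K: the consensus matrix
#' (fraction of co-sampled runs in which two cells co-clustered, among
#' partitions whose realized cluster count was K), its McQuitty (WPGMA) cut,
#' and the mean silhouette of that cut on a PCA embedding. \code{ranking}
#' orders candidates by silhouette; \code{labels} is the cut at
#' \code{selectedK}.
#'
#' @slot consensus named list of symmetric matrices, one per candidate K.
#' @slot support partitions observed per candidate K.
#' @slot nImputed never-co-sampled entries imputed per candidate K.
#' @slot cuts named list of integer label vectors per candidate K.
#' @slot silhouettes mean silhouette per candidate K.
#' @slot ranking data.frame (K, support, mean_silhouette) sorted best-first.
#' @slot selectedK,labels the selected cluster number and its labels.
#' @slot kGrid,resGrid,nIter,subsample,seed the procedure's parameters.
#' @name ConsensusClustering-class
#' @exportClass ConsensusClustering
setClass("ConsensusClustering", representation(
    consensus = "list",
    support = "integer",
    nImputed = "integer",
    cuts = "list",
    silhouettes = "numeric",
    ranking = "data.frame",
    selectedK = "integer",
    labels = "integer",
    kGrid = "numeric",
    resGrid = "numeric",
    nIter = "integer",
    subsample = "numeric",
    seed = "integer"))

setValidity("ConsensusClustering", function(object) {
    msg <- NULL
    for (C in object@consensus) {
        if (nrow(C) != ncol(C) || max(abs(C - t(C))) > 1e-8)
            msg <- c(msg, "consensus matrices must be symmetric")
        if (min(C) < -1e-12 || max(C) > 1 + 1e-12)
            msg <- c(msg, "consensus entries must lie in [0, 1]")
    }
    if (is.null(msg)) TRUE else msg
})

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "MSIDataset", function(object) {
    cat(sprintf("MSIDataset: %d pixels on a %d x %d grid (%.0f um pitch)\n",
                nrow(object@coords), object@gridShape[1L], object@gridShape[2L],
                object@pixelUm))
    cat(sprintf("  m/z axis: %d points in [%.2f, %.2f]\n", length(object@mz),
                min(object@mz), max(object@mz)))
    cat(sprintf("  sample: %s (%s, pair %s)\n", object@sampleId,
                object@treatment, object@pairId))
})

setMethod("show", "PeakTable", function(object) {
    cat(sprintf("PeakTable: %d pixels x %d features%s\n",
                nrow(object@intensities), length(object@featureMz),
                if (object@normalized) " (TIC-normalized)" else ""))
    cat(sprintf("  sample: %s (%s, pair %s)\n", object@sampleId,
                object@treatment, object@pairId))
})

setMethod("show", "PixelPartition", function(object) {
    tab <- table(object@labels)
    cat(sprintf("PixelPartition: %d pixels, %d clusters (cell cluster = %d, %d pixels)\n",
                length(object@labels), length(tab), object@cellLabel,
                sum(object@labels == object@cellLabel)))
})

setMethod("show", "CellAssignment", function(object) {
    org <- table(factor(object@organization,
                        c("none", "dispersed", "cohesive")))
    cat(sprintf("CellAssignment: %s (%s): %d pixels, %d cell pixels (%d dispersed, %d cohesive), %d cell ids\n",
                object@sampleId, object@treatment, length(object@isCell),
                sum(object@isCell), org[["dispersed"]], org[["cohesive"]],
                length(setdiff(unique(object@cellId), 0L))))
})

setMethod("show", "ConsensusClustering", function(object) {
    cat(sprintf("ConsensusClustering: %d cells, %d iterations at subsample %.2f\n",
                length(object@labels), object@nIter, object@subsample))
    cat(sprintf("  candidate K: %s\n",
                paste(names(object@consensus), collapse = ", ")))
    cat(sprintf("  selected K = %d (mean silhouette %.3f)\n", object@selectedK,
                object@silhouettes[[as.character(object@selectedK)]]))
})

## ---------------------------------------------------------------------------
## Accessor methods
## ---------------------------------------------------------------------------

#' @rdname accessors
setMethod("intensityMatrix", "MSIDataset", function(object, ...) object@spectra)
#' @rdname accessors
setMethod("intensityMatrix", "PeakTable", function(object, ...) object@intensities)
#' @rdname accessors
setMethod("intensityMatrix", "CellFeatureMatrix", function(object, assay = "intensities", ...)
    t(SummarizedExperiment::assay(object, assay)))
#' @rdname accessors
setMethod("pixelCoords", "PixelGrid", function(object) object@coords)
#' @rdname accessors
setMethod("gridShape", "PixelGrid", function(object) object@gridShape)
#' @rdname accessors
setMethod("pixelSize", "PixelGrid", function(object) object@pixelUm)
#' @rdname accessors
setMethod("mzValues", "MSIDataset", function(object) object@mz)
#' @rdname accessors
setMethod("featureMz", "PeakTable", function(object) object@featureMz)
#' @rdname accessors
setMethod("rawTic", "PeakTable", function(object) object@tic)
#' @rdname accessors
setMethod("isCell", "PixelPartition", function(object)
    object@labels == object@cellLabel)
#' @rdname accessors
setMethod("isCell", "CellAssignment", function(object) object@isCell)
#' @rdname accessors
setMethod("cellIds", "CellAssignment", function(object) object@cellId)
#' @rdname accessors
setMethod("organization", "CellAssignment", function(object) object@organization)
#' @rdname accessors
setMethod("sampleInfo", "MSIDataset", function(object)
    data.frame(sample_id = object@sampleId, treatment = object@treatment,
               pair_id = object@pairId))
#' @rdname accessors
setMethod("sampleInfo", "PeakTable", function(object)
    data.frame(sample_id = object@sampleId, treatment = object@treatment,
               pair_id = object@pairId))
#' @rdname accessors
setMethod("sampleInfo", "CellAssignment", function(object)
    data.frame(sample_id = object@sampleId, treatment = object@treatment,
               pair_id = object@pairId))
#' @rdname accessors
setMethod("consensusMatrix", "ConsensusClustering", function(object, K)
    object@consensus[[as.character(K)]])
#' @rdname accessors
setMethod("selectedK", "ConsensusClustering", function(object) object@selectedK)
#' @rdname accessors
setMethod("clusterLabels", "ConsensusClustering", function(object) object@labels)
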