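## Raw spectra -> TIC-normalized, peak-picked, aligned pixel x feature table,
## plus detection of cell-containing pixels and cell-specific peaks.

#' TIC normalization
#'
#' Scales every pixel spectrum so its total ion current equals the dataset's
#' mean raw TIC. Using the mean raw TIC (rather than 1) as the common target
#' preserves the intensity scale, which the downstream 5x cell-specificity
#' ratio filter relies on. Pixels with zero TIC are left at zero and their
#' count recorded under \code{metadata(x)$nZeroTic}. The operation is
#' idempotent.
#'
#' @param object an \linkS4class{MSIDataset} or \linkS4class{PeakTable}.
#' @param ... unused.
#' @return an object of the same class, normalized; a \code{PeakTable} keeps
#'   its original raw TIC in the \code{tic} slot.
#' @rdname ticNormalize
#' @export
setMethod("ticNormalize", "MSIDataset", function(object, ...) {
    res <- .ticNorm(object@spectra)
    object@spectra <- res$x
    object@metadata$nZeroTic <- res$nZero
    object@metadata$ticTarget <- res$target
    object
})

#' @rdname ticNormalize
#' @export
setMethod("ticNormalize", "PeakTable", function(object, ...) {
    res <- .ticNorm(object@intensities)
    object@intensities <- res$x
    object@normalized <- TRUE
    object@metadata$nZeroTic <- res$nZero
    object@metadata$ticTarget <- res$target
    object
})

.ticNorm <- function(x) {
    tic <- rowSums(x)
    if (all(tic == 0)) stop("all spectra have zero TIC")
    target <- mean(tic)
    nz <- tic > 0
    x[nz, ] <- x[nz, , drop = FALSE] * (target / tic[nz])
    list(x = x, nZero = sum(!nz), target = target)
}

#' Treat an already centroided dataset as a peak table
#'
#' When spectra are already centroided on a shared feature axis (as the
#' simulator produces, mirroring processed-mode acquisitions), the dataset
#' maps one-to-one onto a \linkS4class{PeakTable}; the per-pixel raw TIC is
#' recorded for later cell-cluster identification.
#'
#' @param ds an \linkS4class{MSIDataset} with centroided spectra.
#' @return a \linkS4class{PeakTable}.
#' @export
asPeakTable <- function(ds) {
    stopifnot(is(ds, "MSIDataset"))
    PeakTable(ds@spectra, ds@mz, ds@coords, ds@gridShape,
              pixelUm = ds@pixelUm, sampleId = ds@sampleId,
              treatment = ds@treatment, pairId = ds@pairId,
              metadata = ds@metadata)
}

#' Robust noise estimate of a spectrum
#'
#' Detrends the spectrum by subtracting a running median (window 101 points,
#' shrunk for short spectra) and returns 1.4826 times the median absolute
#' deviation of the residual -- a robust estimate of the baseline noise
#' standard deviation, insensitive to sparse peaks.
#'
#' @param intensity numeric intensity vector, length >= 16.
#' @return the estimated noise SD (0 for a constant spectrum).
#' @export
estimateNoise <- function(intensity) {
    n <- length(intensity)
    if (n < 16L) stop("spectrum too short for noise estimation")
    k <- min(101L, if (n %% 2L == 1L) n else n - 1L)
    baseline <- stats::runmed(intensity, k, endrule = "median")
    stats::mad(intensity - baseline)
}

#' Pick peaks above a signal-to-noise threshold
#'
#' Finds local maxima whose intensity is at least \code{snrMin} times the
#' robust noise estimate of the spectrum ([estimateNoise()]) and centroids
#' each by three-point parabolic interpolation around the apex.
#'
#' @param intensity,mz the spectrum on a strictly increasing m/z axis.
#' @param snrMin signal-to-noise threshold (default 6).
#' @return data.frame with columns \code{mz} and \code{intensity}; zero rows
#'   when nothing passes.
#' @export
pickPeaks <- function(intensity, mz, snrMin = 6) {
    stopifnot(length(intensity) == length(mz), !is.unsorted(mz, strictly = TRUE))
    n <- length(intensity)
    if (n < 16L) return(data.frame(mz = numeric(0), intensity = numeric(0)))
    noise <- estimateNoise(intensity)
    thr <- snrMin * noise
    if (noise == 0) thr <- 0            # flat spectrum: only true maxima > 0
    y <- intensity
    apex <- which(y[2:(n - 1L)] > y[1:(n - 2L)] &
                  y[2:(n - 1L)] >= y[3:n]) + 1L
    apex <- apex[y[apex] >= thr & y[apex] > 0]
    if (!length(apex)) return(data.frame(mz = numeric(0), intensity = numeric(0)))
    ## parabolic centroid through the apex and its two neighbours
    ym <- y[apex - 1L]; y0 <- y[apex]; yp <- y[apex + 1L]
    denom <- ym - 2 * y0 + yp
    delta <- ifelse(denom == 0, 0, 0.5 * (ym - yp) / denom)
    delta <- pmin(pmax(delta, -0.5), 0.5)
    step <- (mz[apex + 1L] - mz[apex - 1L]) / 2
    data.frame(mz = mz[apex] + delta * step, intensity = y0)
}

#' Align per-pixel peak lists onto consensus features
#'
#' Pools all picked peaks, sorts them by m/z and opens a new feature whenever
#' the gap to the previous peak exceeds \code{tolDa} (greedy one-dimensional
#' clustering). Each pixel's intensity for a feature is the sum of its peaks
#' assigned to that feature. Features observed in fewer than \code{minFrac}
#' of the pixels are dropped.
#'
#' @param peakLists list of data.frames as returned by [pickPeaks()], one per
#'   pixel.
#' @param coords,gridShape,pixelUm pixel geometry for the resulting table.
#' @param tolDa gap tolerance in Da (default 0.1, a typical reflector-TOF
#'   peak width over m/z 500-1000).
#' @param minFrac minimum fraction of pixels a feature must appear in.
#' @param ... sample annotations passed to [PeakTable()].
#' @return a \linkS4class{PeakTable}; feature centres are the mean m/z of the
#'   member peaks.
#' @export
alignPeaks <- function(peakLists, coords, gridShape, pixelUm = 10,
                       tolDa = 0.1, minFrac = 0.01, ...) {
    stopifnot(tolDa > 0, length(peakLists) == nrow(coords))
    nPix <- length(peakLists)
    counts <- vapply(peakLists, nrow, integer(1))
    if (sum(counts) == 0L)
        return(PeakTable(matrix(0, nPix, 0), numeric(0), coords, gridShape,
                         pixelUm = pixelUm, ...))
    allMz <- unlist(lapply(peakLists, `[[`, "mz"), use.names = FALSE)
    allInt <- unlist(lapply(peakLists, `[[`, "intensity"), use.names = FALSE)
    pix <- rep.int(seq_len(nPix), counts)
    o <- order(allMz)
    allMz <- allMz[o]; allInt <- allInt[o]; pix <- pix[o]
    feature <- cumsum(c(1L, diff(allMz) > tolDa))
    nFeat <- feature[length(feature)]
    centre <- as.numeric(tapply(allMz, feature, mean))
    m <- matrix(0, nPix, nFeat)
    m[cbind(pix, feature)] <- m[cbind(pix, feature)] + allInt
    ## accumulate duplicates (several peaks of one pixel in one feature)
    if (anyDuplicated(cbind(pix, feature))) {
        m <- matrix(0, nPix, nFeat)
        for (i in seq_along(pix))
            m[pix[i], feature[i]] <- m[pix[i], feature[i]] + allInt[i]
    }
    observed <- colSums(m > 0) / nPix
    keep <- observed >= minFrac
    PeakTable(m[, keep, drop = FALSE], centre[keep], coords, gridShape,
              pixelUm = pixelUm, ...)
}

#' Spatially smoothed k-means detection of cell pixels
#'
#' Clusters pixels by k-means on z-scored feature vectors augmented with
#' Gaussian-weighted neighbourhood means (radius \code{rPx}), a smooth
#' variant of spatial k-means segmentation. The cluster with the highest
#' mean \emph{raw} TIC is declared the cell cluster (cells dominate ion
#' yield); ties are broken towards the larger cluster. Pixels are processed
#' in canonical (row, col) order internally, so the partition is invariant to
#' the input pixel ordering.
#'
#' @param pt a \linkS4class{PeakTable} (normalized or not; the raw TIC slot is
#'   used for cell-cluster identification).
#' @param k number of clusters (default 2: cells vs background).
#' @param rPx neighbourhood radius in pixels for the spatial augmentation.
#' @param seed RNG seed for the k-means restarts.
#' @param nstart k-means restarts (default 10).
#' @return a \linkS4class{PixelPartition}.
#' @export
spatialKmeans <- function(pt, k = 2L, rPx = 1L, seed = 1L, nstart = 10L) {
    stopifnot(is(pt, "PeakTable"), k >= 2L)
    n <- nrow(pt@intensities)
    if (n < k) stop("fewer pixels than clusters")
    ord <- order(pt@coords[, 1L], pt@coords[, 2L])
    x <- pt@intensities[ord, , drop = FALSE]
    sm <- .neighbourhoodMeans(x, pt@coords[ord, , drop = FALSE],
                              pt@gridShape, rPx)
    z <- function(m) {
        s <- apply(m, 2L, stats::sd)
        s[s == 0] <- 1
        sweep(sweep(m, 2L, colMeans(m)), 2L, s, "/")
    }
    aug <- cbind(z(x), z(sm))
    set.seed(seed)
    km <- stats::kmeans(aug, centers = k, nstart = nstart, iter.max = 100L)
    labels <- integer(n)
    labels[ord] <- km$cluster
    ticMean <- tapply(pt@tic, labels, mean)
    sizes <- table(labels)
    best <- order(-ticMean, -as.numeric(sizes))[1L]
    new("PixelPartition", coords = pt@coords, gridShape = pt@gridShape,
        pixelUm = pt@pixelUm, labels = labels,
        cellLabel = as.integer(names(ticMean))[best])
}

## Gaussian-weighted neighbourhood mean of each pixel's feature vector,
## over offsets within Chebyshev radius rPx (sigma = rPx), self included.
.neighbourhoodMeans <- function(x, coords, gridShape, rPx) {
    rows <- gridShape[1L]; cols <- gridShape[2L]
    idx <- matrix(NA_integer_, rows, cols)
    idx[cbind(coords[, 1L] + 1L, coords[, 2L] + 1L)] <- seq_len(nrow(x))
    acc <- matrix(0, nrow(x), ncol(x))
    wsum <- numeric(nrow(x))
    for (dr in -rPx:rPx) for (dc in -rPx:rPx) {
        w <- exp(-(dr^2 + dc^2) / (2 * rPx^2))
        rSrc <- seq_len(rows) + dr
        cSrc <- seq_len(cols) + dc
        okR <- rSrc >= 1L & rSrc <= rows
        okC <- cSrc >= 1L & cSrc <= cols
        tgt <- idx[okR, okC, drop = FALSE]
        src <- idx[rSrc[okR], cSrc[okC], drop = FALSE]
        keep <- !is.na(tgt) & !is.na(src)
        if (!any(keep)) next
        acc[tgt[keep], ] <- acc[tgt[keep], , drop = FALSE] +
            w * x[src[keep], , drop = FALSE]
        wsum[tgt[keep]] <- wsum[tgt[keep]] + w
    }
    acc / wsum
}

#' Cell-specific peak filter
#'
#' Retains features whose mean intensity over cell pixels is at least
#' \code{ratioMin} times (inclusive) their mean over cell-free pixels.
#' Features with zero background mean but positive cell mean are retained.
#'
#' @param pt a (normalized) \linkS4class{PeakTable}.
#' @param part a \linkS4class{PixelPartition} from [spatialKmeans()].
#' @param ratioMin minimum cell/background mean ratio (default 5, inclusive).
#' @return integer indices of the retained features.
#' @export
cellSpecificPeaks <- function(pt, part, ratioMin = 5) {
    stopifnot(is(pt, "PeakTable"), is(part, "PixelPartition"))
    cell <- isCell(part)
    if (!any(!cell)) stop("no background pixels present")
    if (!any(cell)) stop("no cell pixels present")
    mCell <- colMeans(pt@intensities[cell, , drop = FALSE])
    mBg <- colMeans(pt@intensities[!cell, , drop = FALSE])
    which((mBg == 0 & mCell > 0) | (mBg > 0 & mCell >= ratioMin * mBg))
}

#' Mean spectrum over a pixel subset
#'
#' @param pt a \linkS4class{PeakTable}.
#' @param pixels integer indices (rows of the table) or a logical vector.
#' @return named numeric vector, the arithmetic per-feature mean.
#' @export
meanSpectrum <- function(pt, pixels) {
    stopifnot(is(pt, "PeakTable"))
    sub <- pt@intensities[pixels, , drop = FALSE]
    if (!nrow(sub)) stop("empty pixel subset")
    stats::setNames(colMeans(sub), sprintf("mz%.4f", pt@featureMz))
}
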