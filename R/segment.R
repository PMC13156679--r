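## Brightfield-guided classification of cell pixels into dispersed single
## cells vs cohesive groups, and assignment of single-cell ids to MSI pixels.

#' Gaussian blur with reflective borders
#'
#' Separable Gaussian convolution (kernel truncated at 3 sigma and normalized
#' to unit sum, so total image mass is preserved); borders are handled by
#' mirror reflection.
#'
#' @param img numeric matrix.
#' @param sigmaPx kernel standard deviation in pixels.
#' @return blurred matrix of the same size.
#' @export
gaussianBlur <- function(img, sigmaPx) {
    stopifnot(sigmaPx > 0)
    h <- ceiling(3 * sigmaPx)
    g <- stats::dnorm(-h:h, sd = sigmaPx)
    g <- g / sum(g)
    blur1d <- function(m) {
        n <- nrow(m)
        top <- m[pmin(h:1, n), , drop = FALSE]
        bot <- m[pmax(n - seq_len(h) + 1L, 1L), , drop = FALSE]
        padded <- rbind(top, m, bot)
        out <- stats::filter(padded, g, sides = 2)
        matrix(out[(h + 1L):(h + n), ], n, ncol(m))
    }
    t(blur1d(t(blur1d(img))))
}

#' Otsu's threshold
#'
#' Computes the threshold maximizing the between-class variance on a
#' \code{nbins}-bin histogram of the values. The returned threshold is the
#' upper edge of the best split bin, so \code{x <= threshold} is the lower
#' class.
#'
#' @param x numeric values (matrix or vector).
#' @param nbins histogram bins (default 256).
#' @return the threshold value.
#' @export
otsuThreshold <- function(x, nbins = 256L) {
    x <- as.numeric(x)
    rng <- range(x)
    if (rng[1L] == rng[2L]) stop("constant image: no threshold exists")
    breaks <- seq(rng[1L], rng[2L], length.out = nbins + 1L)
    cnt <- tabulate(pmin(findInterval(x, breaks, rightmost.closed = TRUE),
                         nbins), nbins)
    p <- cnt / sum(cnt)
    mids <- (breaks[-1L] + breaks[-(nbins + 1L)]) / 2
    w0 <- cumsum(p)
    mu0 <- cumsum(p * mids)
    muT <- mu0[nbins]
    ## between-class variance for split after bin t (t = 1..nbins-1)
    t <- seq_len(nbins - 1L)
    valid <- w0[t] > 0 & w0[t] < 1
    bc <- rep(-Inf, nbins - 1L)
    bc[valid] <- (muT * w0[t][valid] - mu0[t][valid])^2 /
        (w0[t][valid] * (1 - w0[t][valid]))
    best <- which.max(bc)
    breaks[best + 1L]
}

#' Blur and binarize a brightfield image
#'
#' Gaussian blur (sigma 5 px by default) followed by Otsu thresholding on a
#' 256-bin histogram. Cells appear dark in transmitted-light brightfield, so
#' the foreground defaults to the sub-threshold side; set
#' \code{darkForeground = FALSE} for bright objects.
#'
#' @param img a \linkS4class{BrightfieldImage} or a numeric matrix.
#' @param sigmaPx blur standard deviation in pixels (default 5).
#' @param darkForeground polarity flag (default TRUE).
#' @return logical foreground mask.
#' @export
blurAndThreshold <- function(img, sigmaPx = 5, darkForeground = TRUE) {
    m <- if (is(img, "BrightfieldImage")) img@pixels else as.matrix(img)
    if (length(unique(as.vector(m))) < 2L)
        stop("image has fewer than two distinct gray levels")
    b <- gaussianBlur(m, sigmaPx)
    thr <- otsuThreshold(b)
    if (darkForeground) b <= thr else b > thr
}

#' Candidate cell contours from a binary mask
#'
#' Extracts 8-connected foreground components (holes are ignored: only the
#' external extent of each component is reported) with their areas and
#' bounding-box statistics.
#'
#' @param mask logical matrix.
#' @param umPerPx micrometres per pixel of the mask's image.
#' @return a \linkS4class{CellContours} object.
#' @export
findCellContours <- function(mask, umPerPx) {
    stopifnot(is.matrix(mask), umPerPx > 0)
    lab <- .labelComponents(mask, 8L)
    n <- max(lab)
    pixelIdx <- vector("list", n)
    area <- numeric(n); aspect <- numeric(n)
    bbox <- matrix(0L, n, 4L,
                   dimnames = list(NULL, c("rmin", "rmax", "cmin", "cmax")))
    if (n > 0L) {
        idxAll <- which(lab > 0L)
        byComp <- split(idxAll, lab[idxAll])
        for (i in seq_len(n)) {
            idx <- byComp[[as.character(i)]]
            r <- (idx - 1L) %% nrow(mask)
            c <- (idx - 1L) %/% nrow(mask)
            pixelIdx[[i]] <- idx
            area[i] <- length(idx) * umPerPx^2
            bbox[i, ] <- c(min(r), max(r), min(c), max(c))
            aspect[i] <- (bbox[i, "cmax"] - bbox[i, "cmin"] + 1) /
                (bbox[i, "rmax"] - bbox[i, "rmin"] + 1)
        }
    }
    new("CellContours", pixelIdx = pixelIdx, areaUm2 = area, bbox = bbox,
        aspectRatio = aspect, accepted = rep(TRUE, n),
        umPerPx = as.numeric(umPerPx), imageDim = dim(mask))
}

#' Filter contours down to single-cell candidates
#'
#' A contour is accepted iff its area lies in \code{areaRange} (square
#' micrometres) and its bounding-box aspect ratio (width over height) lies in
#' \code{aspectRange}; both intervals are inclusive. Defaults follow typical
#' single-cell dimensions of adherent carcinoma cells: 100-2500 um^2 and
#' aspect between 0.75 and 1.25. Idempotent.
#'
#' @param cs a \linkS4class{CellContours} object.
#' @param areaRange,aspectRange inclusive acceptance intervals.
#' @return the object with its \code{accepted} slot updated.
#' @export
filterSingleCellContours <- function(cs, areaRange = c(100, 2500),
                                     aspectRange = c(0.75, 1.25)) {
    stopifnot(is(cs, "CellContours"))
    cs@accepted <- cs@areaUm2 >= areaRange[1L] & cs@areaUm2 <= areaRange[2L] &
        cs@aspectRatio >= aspectRange[1L] & cs@aspectRatio <= aspectRange[2L]
    cs
}

## map brightfield pixel linear indices to MSI (row, col), honouring the
## registration model (axis-aligned scale + translation + optional flips)
.bfToMsi <- function(idx, img, imageDim, pixelUm) {
    r <- (idx - 1L) %% imageDim[1L]
    c <- (idx - 1L) %/% imageDim[1L]
    if (img@flip[1L]) r <- imageDim[1L] - 1L - r
    if (img@flip[2L]) c <- imageDim[2L] - 1L - c
    yUm <- img@originOffsetUm[1L] + (r + 0.5) * img@umPerPx
    xUm <- img@originOffsetUm[2L] + (c + 0.5) * img@umPerPx
    cbind(row = floor(yUm / pixelUm), col = floor(xUm / pixelUm))
}

#' Assign single-cell ids to MSI pixels
#'
#' Maps every accepted contour through the brightfield-to-MSI registration;
#' cell pixels covered by exactly one accepted contour receive that contour's
#' id, remaining cell pixels 4-connected to pixels of a unique id are flood
#' filled, and each 4-connected component of cell pixels is labelled
#' \code{dispersed} iff it ended up wholly and exclusively covered by exactly
#' one id (the classic single-cell case) -- every other cell pixel is
#' \code{cohesive}. An optional override table records what would otherwise
#' be manual curation.
#'
#' @param cs a filtered \linkS4class{CellContours}.
#' @param part the \linkS4class{PixelPartition} defining cell pixels.
#' @param img the \linkS4class{BrightfieldImage} carrying the registration.
#' @param sampleId,treatment,pairId sample annotations for the result.
#' @param overrides optional data.frame with columns \code{cell_id} and
#'   \code{organization} applied after the deterministic rules.
#' @param connectivity 4 (default) or 8 for component analysis / flood fill.
#' @return a \linkS4class{CellAssignment}.
#' @export
assignPixels <- function(cs, part, img, sampleId = "sample1",
                         treatment = "CTR", pairId = "pair1",
                         overrides = NULL, connectivity = 4L) {
    stopifnot(is(cs, "CellContours"), is(part, "PixelPartition"),
              is(img, "BrightfieldImage"))
    if (img@umPerPx <= 0 || part@pixelUm <= 0)
        stop("degenerate registration transform")
    rows <- part@gridShape[1L]; cols <- part@gridShape[2L]

    ## contour footprints on the MSI grid
    cover <- matrix(0L, rows, cols)   # number of accepted contours covering
    idGrid <- matrix(0L, rows, cols)  # id where coverage is unique
    for (i in which(cs@accepted)) {
        msi <- unique(.bfToMsi(cs@pixelIdx[[i]], img, cs@imageDim,
                               part@pixelUm))
        ok <- msi[, 1L] >= 0L & msi[, 1L] < rows &
              msi[, 2L] >= 0L & msi[, 2L] < cols
        msi <- msi[ok, , drop = FALSE]
        lin <- msi[, 1L] + 1L + msi[, 2L] * rows
        newCover <- cover[lin] + 1L
        cover[lin] <- newCover
        idGrid[lin] <- ifelse(newCover == 1L, i, 0L)
    }

    cellGrid <- matrix(FALSE, rows, cols)
    cellGrid[cbind(part@coords[, 1L] + 1L, part@coords[, 2L] + 1L)] <-
        isCell(part)
    idGrid[!cellGrid] <- 0L
    cover[!cellGrid] <- 0L

    ## flood fill: propagate unique neighbouring ids into unassigned cell px
    shifts <- if (connectivity == 8L)
        list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
             c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
    else list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
    repeat {
        cand <- NULL; candId <- NULL; conflict <- NULL
        first <- matrix(0L, rows, cols); multi <- matrix(FALSE, rows, cols)
        for (s in shifts) {
            nb <- .shiftMatrix(idGrid, s[1L], s[2L])
            hit <- nb > 0L & cellGrid & idGrid == 0L
            newHit <- hit & first == 0L
            first[newHit] <- nb[newHit]
            multi[hit & first != nb & first != 0L] <- TRUE
        }
        grow <- first > 0L & !multi
        if (!any(grow)) break
        idGrid[grow] <- first[grow]
    }

    comp <- .labelComponents(cellGrid, as.integer(connectivity))
    org <- matrix("none", rows, cols)
    if (max(comp) > 0L) {
        cellIdxAll <- which(comp > 0L)
        compOf <- comp[cellIdxAll]
        idOf <- idGrid[cellIdxAll]
        ## how many components does each id touch?
        idComp <- unique(cbind(idOf, compOf))
        idComp <- idComp[idComp[, 1L] > 0L, , drop = FALSE]
        compsPerId <- table(idComp[, 1L])
        for (cc in seq_len(max(comp))) {
            inC <- compOf == cc
            ids <- unique(idOf[inC])
            dispersed <- length(ids) == 1L && ids[1L] > 0L &&
                compsPerId[[as.character(ids[1L])]] == 1L
            org[cellIdxAll[inC]] <- if (dispersed) "dispersed" else "cohesive"
        }
    }

    co <- part@coords
    lin <- co[, 1L] + 1L + co[, 2L] * rows
    cellId <- idGrid[lin]
    organization <- org[lin]
    isCellVec <- cellGrid[lin]

    ca <- new("CellAssignment", coords = co, gridShape = part@gridShape,
              pixelUm = part@pixelUm, isCell = isCellVec,
              cellId = as.integer(cellId), organization = organization,
              sampleId = sampleId, treatment = treatment, pairId = pairId)
    if (!is.null(overrides)) {
        for (i in seq_len(nrow(overrides))) {
            sel <- ca@cellId == overrides$cell_id[i]
            ca@organization[sel & ca@isCell] <- overrides$organization[i]
        }
        validObject(ca)
    }
    ca
}

.shiftMatrix <- function(m, dr, dc) {
    out <- matrix(0L, nrow(m), ncol(m))
    rSrc <- seq_len(nrow(m)) - dr
    cSrc <- seq_len(ncol(m)) - dc
    okR <- rSrc >= 1L & rSrc <= nrow(m)
    okC <- cSrc >= 1L & cSrc <= ncol(m)
    out[okR, okC] <- m[rSrc[okR], cSrc[okC]]
    out
}

#' Per-sample cell population summary
#'
#' For each sample: the percentage of pixels containing cells and the
#' percentage of cell pixels labelled dispersed; plus Welch two-sample t
#' tests comparing the treatment groups on both quantities (when both groups
#' have at least two samples).
#'
#' @param assignments list of \linkS4class{CellAssignment} objects.
#' @return list with \code{perSample} (data.frame) and \code{tests}
#'   (data.frame of t statistics and p values, possibly empty).
#' @export
populationSummary <- function(assignments) {
    stopifnot(length(assignments) >= 1L)
    perSample <- do.call(rbind, lapply(assignments, function(a) {
        nCell <- sum(a@isCell)
        data.frame(sample_id = a@sampleId, treatment = a@treatment,
                   pair_id = a@pairId,
                   pct_cell_pixels = 100 * nCell / length(a@isCell),
                   pct_dispersed = if (nCell)
                       100 * sum(a@organization == "dispersed") / nCell
                   else NA_real_)
    }))
    rownames(perSample) <- NULL
    tests <- NULL
    groups <- split(perSample, perSample$treatment)
    if (length(groups) == 2L && all(vapply(groups, nrow, integer(1)) >= 2L)) {
        tests <- do.call(rbind, lapply(
            c("pct_cell_pixels", "pct_dispersed"), function(v) {
                tt <- twoSampleTTest(groups[[1L]][[v]], groups[[2L]][[v]])
                data.frame(metric = v, t = tt$t, df = tt$df, p = tt$p)
            }))
    }
    list(perSample = perSample, tests = tests)
}

#' Group shares of pooled cells
#'
#' Given per-group analyzed-cell counts, returns each group's percentage of
#' the pooled cells.
#'
#' @param counts named numeric vector of cell counts.
#' @return named numeric vector of percentages summing to 100.
#' @examples
#' groupShares(c(CTR = 446, EGF = 893))
#' @export
groupShares <- function(counts) {
    stopifnot(all(counts >= 0), sum(counts) > 0)
    100 * counts / sum(counts)
}
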