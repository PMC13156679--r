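## Per-cell / per-region feature matrices, empirical-Bayes batch correction
## across matrix-application rounds, and scaling for multivariate analysis.

#' @importFrom SummarizedExperiment assay assay<- assayNames colData rowData
NULL

#' Extract observational units from a segmented sample
#'
#' Builds the rows of a \linkS4class{CellFeatureMatrix} from one sample:
#' either one whole-sample mean spectrum over all cell pixels
#' (\code{"sample_mean"}), one pooled mean per cell organization
#' (\code{"organization_mean"}: cohesive and dispersed pools), or one mean
#' spectrum per dispersed single cell (\code{"single_cell"}). Values are
#' [meanSpectrum()] over the unit's pixels, restricted to the cell-specific
#' features. Empty pools are omitted with a warning.
#'
#' @param pt the sample's (normalized) \linkS4class{PeakTable}.
#' @param ca the sample's \linkS4class{CellAssignment}.
#' @param mode one of \code{"sample_mean"}, \code{"organization_mean"},
#'   \code{"single_cell"}.
#' @param features integer feature indices (from [cellSpecificPeaks()]);
#'   defaults to all features.
#' @return a \linkS4class{CellFeatureMatrix} whose \code{colData} carries
#'   \code{sample_id}, \code{treatment}, \code{pair_id}, \code{organization}
#'   and \code{n_pixels}.
#' @export
extractUnits <- function(pt, ca,
                         mode = c("single_cell", "organization_mean",
                                  "sample_mean"),
                         features = seq_along(pt@featureMz)) {
    mode <- match.arg(mode)
    stopifnot(is(pt, "PeakTable"), is(ca, "CellAssignment"),
              nrow(pt@intensities) == length(ca@isCell))
    cell <- ca@isCell
    if (!any(cell)) stop("sample has no cell pixels")
    units <- switch(mode,
        sample_mean = list(all = which(cell)),
        organization_mean = {
            u <- list(cohesive = which(cell & ca@organization == "cohesive"),
                      dispersed = which(cell & ca@organization == "dispersed"))
            empty <- !vapply(u, length, integer(1))
            if (any(empty))
                warning("omitting empty pool(s): ",
                        paste(names(u)[empty], collapse = ", "))
            u[!empty]
        },
        single_cell = {
            ids <- sort(setdiff(unique(
                ca@cellId[cell & ca@organization == "dispersed"]), 0L))
            if (!length(ids)) {
                warning("sample has no dispersed single cells")
                list()
            } else {
                stats::setNames(lapply(ids, function(i)
                    which(cell & ca@cellId == i &
                          ca@organization == "dispersed")),
                    paste0("cell", ids))
            }
        })
    if (!length(units))
        return(NULL)
    vals <- t(vapply(units, function(px)
        unname(meanSpectrum(pt, px))[features], numeric(length(features))))
    org <- switch(mode, sample_mean = "all",
                  organization_mean = names(units),
                  single_cell = "dispersed")
    ann <- data.frame(
        sample_id = ca@sampleId, treatment = ca@treatment,
        pair_id = ca@pairId, organization = org,
        n_pixels = vapply(units, length, integer(1)),
        unit = names(units))
    rownames(vals) <- paste(ca@sampleId, names(units), sep = ".")
    CellFeatureMatrix(vals, ann, featureMz = pt@featureMz[features])
}

#' Combine unit matrices from several samples
#'
#' Column-binds \linkS4class{CellFeatureMatrix} objects sharing one feature
#' axis; \code{NULL} entries (samples whose pools were empty) are dropped.
#'
#' @param ... objects or a single list of objects.
#' @return a combined \linkS4class{CellFeatureMatrix}.
#' @export
combineUnits <- function(...) {
    xs <- list(...)
    if (length(xs) == 1L && is.list(xs[[1L]]) && !is(xs[[1L]], "CellFeatureMatrix"))
        xs <- xs[[1L]]
    xs <- xs[!vapply(xs, is.null, logical(1))]
    stopifnot(length(xs) >= 1L)
    feats <- rownames(xs[[1L]])
    for (x in xs)
        if (!identical(rownames(x), feats))
            stop("unit matrices disagree on the feature axis")
    vals <- do.call(rbind, lapply(xs, function(x)
        t(assay(x, "intensities"))))
    rownames(vals) <- make.unique(unlist(lapply(xs, colnames)))
    ann <- do.call(rbind, lapply(xs, function(x)
        as.data.frame(colData(x))))
    rownames(ann) <- rownames(vals)
    mz <- rowData(xs[[1L]])$mz
    out <- CellFeatureMatrix(vals, ann, featureMz = mz)
    if (is.null(mz)) rownames(out) <- feats
    metadata(out)$scaled <- FALSE
    out
}

#' Empirical-Bayes batch correction (parametric location/scale model)
#'
#' Removes multiplicative batch effects between matrix-application rounds by
#' the classic parametric empirical-Bayes model: intensities are logged
#' (\code{log(x + eps)} with \code{eps} = half the smallest positive value),
#' standardized per feature with the batch and covariate design, per-batch
#' location and scale deviations are shrunk towards their method-of-moments
#' normal / inverse-gamma priors by iterated conditional posterior means
#' (convergence when both adjustments move less than \code{tol}), and the
#' corrected values are back-transformed to the linear scale. The treatment
#' covariate is part of the design, so treatment differences are preserved.
#'
#' @param m a \linkS4class{CellFeatureMatrix}.
#' @param batch name of the batch column in \code{colData} (default
#'   \code{"pair_id"}, the matrix-application pair).
#' @param covariates character vector of covariate columns to protect
#'   (default \code{"treatment"}; use \code{NULL} for none).
#' @param tol,maxIter EB iteration control (default 1e-6, 500).
#' @return the corrected \linkS4class{CellFeatureMatrix}; the fitted
#'   \linkS4class{CombatModel} is stored in \code{metadata(m)$combat}.
#' @export
combatCorrect <- function(m, batch = "pair_id", covariates = "treatment",
                          tol = 1e-6, maxIter = 500L) {
    stopifnot(is(m, "CellFeatureMatrix"))
    cd <- colData(m)
    bat <- factor(cd[[batch]])
    if (nlevels(bat) < 2L) {
        message("single batch: nothing to correct")
        return(m)
    }
    x <- assay(m, "intensities")       # features x units, linear scale
    pos <- x[x > 0]
    eps <- if (length(pos)) min(pos) * 0.5 else 1e-6
    dat <- log(x + eps)

    fit <- .combatFit(dat, bat, .covariateDesign(cd, covariates, bat),
                      tol = tol, maxIter = maxIter)
    out <- exp(fit$corrected) - eps
    out[out < 0] <- 0
    assay(m, "intensities") <- out
    metadata(m)$combat <- fit$model
    m
}

.covariateDesign <- function(cd, covariates, bat) {
    if (is.null(covariates) || !length(covariates)) return(NULL)
    df <- as.data.frame(cd[, covariates, drop = FALSE])
    keep <- vapply(df, function(v) length(unique(v)) > 1L, logical(1))
    if (!any(keep)) return(NULL)
    mm <- stats::model.matrix(~., data = df[, keep, drop = FALSE])
    mm <- mm[, -1L, drop = FALSE]
    ## drop covariates confounded with batch
    full <- cbind(stats::model.matrix(~ -1 + bat), mm)
    if (qr(full)$rank < ncol(full)) {
        warning("covariates confounded with batch were dropped")
        return(NULL)
    }
    mm
}

## Parametric EB fit on a features x samples matrix (additive scale).
.combatFit <- function(dat, bat, covars, tol = 1e-6, maxIter = 500L) {
    G <- nrow(dat); n <- ncol(dat)
    B <- nlevels(bat)
    nB <- tabulate(bat, B)
    batchmod <- stats::model.matrix(~ -1 + bat)
    design <- if (is.null(covars)) batchmod else cbind(batchmod, covars)

    constG <- apply(dat, 1L, function(r) stats::var(r) == 0)
    Bhat <- solve(crossprod(design), t(design) %*% t(dat))   # (B+q) x G
    grand <- as.numeric(crossprod(nB / n, Bhat[seq_len(B), , drop = FALSE]))
    resid <- dat - t(design %*% Bhat)
    varPooled <- rowSums(resid^2) / n
    varPooled[varPooled == 0] <- 1    # constant features pass through

    standMean <- matrix(grand, G, n)
    if (!is.null(covars)) {
        tmp <- design
        tmp[, seq_len(B)] <- 0
        standMean <- standMean + t(tmp %*% Bhat)
    }
    s <- (dat - standMean) / sqrt(varPooled)

    gammaHat <- matrix(NA_real_, B, G)
    deltaHat <- matrix(NA_real_, B, G)
    gammaStar <- matrix(NA_real_, B, G)
    deltaStar <- matrix(1, B, G)
    hyper <- vector("list", B)
    iters <- numeric(B)
    for (b in seq_len(B)) {
        idx <- which(bat == levels(bat)[b])
        ni <- length(idx)
        sb <- s[, idx, drop = FALSE]
        gammaHat[b, ] <- rowMeans(sb)
        if (ni < 2L) {
            warning("batch '", levels(bat)[b],
                    "' has a single unit: location-only correction")
            gammaStar[b, ] <- gammaHat[b, ]
            deltaHat[b, ] <- NA_real_
            hyper[[b]] <- list(gamma.bar = mean(gammaHat[b, ]), tau2 = NA,
                               lambda = NA, theta = NA)
            next
        }
        deltaHat[b, ] <- apply(sb, 1L, stats::var)
        gbar <- mean(gammaHat[b, ])
        t2 <- stats::var(gammaHat[b, ])
        mD <- mean(deltaHat[b, ]); s2D <- stats::var(deltaHat[b, ])
        aPrior <- (2 * s2D + mD^2) / s2D
        bPrior <- (mD * s2D + mD^3) / s2D
        gOld <- gammaHat[b, ]
        dOld <- deltaHat[b, ]
        it <- 0L
        repeat {
            it <- it + 1L
            gNew <- (t2 * ni * gammaHat[b, ] + dOld * gbar) /
                (t2 * ni + dOld)
            sum2 <- rowSums((sb - matrix(gNew, G, ni))^2)
            dNew <- (0.5 * sum2 + bPrior) / (ni / 2 + aPrior - 1)
            if ((max(abs(gNew - gOld)) < tol && max(abs(dNew - dOld)) < tol) ||
                it >= maxIter) {
                gOld <- gNew; dOld <- dNew
                break
            }
            gOld <- gNew; dOld <- dNew
        }
        gammaStar[b, ] <- gOld
        deltaStar[b, ] <- dOld
        hyper[[b]] <- list(gamma.bar = gbar, tau2 = t2, lambda = aPrior,
                           theta = bPrior)
        iters[b] <- it
        s[, idx] <- (sb - matrix(gOld, G, ni)) / sqrt(dOld)
    }
    ## location-only batches adjusted after the loop (deltaStar stays 1)
    for (b in which(nB < 2L)) {
        idx <- which(bat == levels(bat)[b])
        s[, idx] <- s[, idx, drop = FALSE] - gammaStar[b, ]
    }
    corrected <- s * sqrt(varPooled) + standMean
    corrected[constG, ] <- dat[constG, ]
    model <- new("CombatModel", grandMean = grand, varPooled = varPooled,
                 gammaHat = gammaHat, gammaStar = gammaStar,
                 deltaHat = deltaHat, deltaStar = deltaStar,
                 hyper = hyper, batches = levels(bat), iterations = iters)
    list(corrected = corrected, model = model)
}

#' Z-score scaling of features
#'
#' Centres every feature to mean 0 and scales to standard deviation 1
#' (denominator n - 1), writing the result into a \code{"scaled"} assay.
#' Zero-variance features are dropped with a warning.
#'
#' @param m a \linkS4class{CellFeatureMatrix} with at least two units.
#' @return the object with a \code{"scaled"} assay and
#'   \code{metadata(m)$scaled = TRUE}.
#' @export
zscoreScale <- function(m) {
    stopifnot(is(m, "CellFeatureMatrix"))
    if (ncol(m) < 2L) stop("scaling requires at least two units")
    x <- assay(m, "intensities")
    sds <- apply(x, 1L, stats::sd)
    if (any(sds == 0)) {
        warning(sum(sds == 0), " zero-variance feature(s) dropped")
        m <- m[sds > 0, ]
        x <- assay(m, "intensities")
        sds <- sds[sds > 0]
    }
    assay(m, "scaled") <- (x - rowMeans(x)) / sds
    metadata(m)$scaled <- TRUE
    m
}

#' PCA embedding with deterministic orientation
#'
#' Principal components of the scaled data (units as observations). Each
#' component's sign is fixed by making its largest-magnitude loading
#' positive, so embeddings are reproducible across platforms.
#'
#' @param m a scaled \linkS4class{CellFeatureMatrix} (see [zscoreScale()]) or
#'   a numeric units x features matrix assumed already scaled.
#' @param nComponents number of components (default
#'   \code{min(10, rank)}).
#' @return list with \code{scores} (units x components),
#'   \code{explained} (fraction of variance per component) and
#'   \code{rotation}.
#' @export
pcaEmbed <- function(m, nComponents = NULL) {
    if (is(m, "CellFeatureMatrix")) {
        if (!isTRUE(metadata(m)$scaled))
            stop("scale the matrix first (zscoreScale)")
        x <- t(assay(m, "scaled"))
    } else x <- as.matrix(m)
    maxComp <- min(nrow(x) - 1L, ncol(x))
    if (is.null(nComponents)) nComponents <- min(10L, maxComp)
    if (nComponents > maxComp)
        stop("nComponents exceeds min(rows - 1, cols)")
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    rot <- pc$rotation[, seq_len(nComponents), drop = FALSE]
    flip <- vapply(seq_len(ncol(rot)), function(j) {
        v <- rot[, j]
        sign(v[which.max(abs(v))])
    }, numeric(1))
    rot <- sweep(rot, 2L, flip, "*")
    scores <- sweep(x, 2L, colMeans(x)) %*% rot
    list(scores = scores,
         explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(nComponents)],
         rotation = rot)
}
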