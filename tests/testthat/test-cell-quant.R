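## shared fixture: a segmented synthetic sample
quantFixture <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            sim <- simulateExperiment(simConfig(gridShape = c(70, 70),
                                                nColonies = 2L,
                                                nSingletons = 8L, seed = 31L))
            pt <- ticNormalize(asPeakTable(sim$msi))
            part <- spatialKmeans(pt, seed = 1L)
            mask <- blurAndThreshold(sim$brightfield, 5)
            cs <- filterSingleCellContours(
                findCellContours(mask, sim$brightfield@umPerPx))
            ca <- assignPixels(cs, part, sim$brightfield)
            cache <<- list(sim = sim, pt = pt, ca = ca,
                           feats = cellSpecificPeaks(pt, part))
        }
        cache
    }
})

test_that("extracted units are brute-force pixel means and conserve totals", {
    fx <- quantFixture()
    sc <- extractUnits(fx$pt, fx$ca, "single_cell", fx$feats)
    ids <- sort(setdiff(unique(fx$ca@cellId[
        fx$ca@organization == "dispersed"]), 0L))
    expect_equal(ncol(sc), length(ids))
    for (j in seq_along(ids)) {
        px <- which(fx$ca@cellId == ids[j] &
                    fx$ca@organization == "dispersed")
        manual <- colMeans(fx$pt@intensities[px, fx$feats, drop = FALSE])
        expect_equal(unname(assay(sc, "intensities")[, j]), unname(manual))
    }

    om <- extractUnits(fx$pt, fx$ca, "organization_mean", fx$feats)
    sm <- extractUnits(fx$pt, fx$ca, "sample_mean", fx$feats)
    w <- colData(om)$n_pixels
    pooled <- as.numeric(assay(om, "intensities") %*% w)
    total <- as.numeric(assay(sm, "intensities")) * sum(isCell(fx$ca))
    expect_equal(pooled, total, tolerance = 1e-9)
})

test_that("single-pixel cells and cohesive-only samples extract cleanly", {
    co <- cbind(row = 0:3, col = rep(0L, 4))
    m <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), 4)
    pt <- PeakTable(m, c(600, 700), co, c(4L, 1L))
    ca1 <- new("CellAssignment", coords = co, gridShape = c(4L, 1L),
               pixelUm = 10, isCell = c(TRUE, FALSE, FALSE, FALSE),
               cellId = c(5L, 0L, 0L, 0L),
               organization = c("dispersed", "none", "none", "none"),
               sampleId = "s", treatment = "CTR", pairId = "p")
    u <- extractUnits(pt, ca1, "single_cell")
    expect_equal(unname(assay(u, "intensities")[, 1L]), m[1L, ])

    caC <- new("CellAssignment", coords = co, gridShape = c(4L, 1L),
               pixelUm = 10, isCell = c(TRUE, TRUE, FALSE, FALSE),
               cellId = c(0L, 0L, 0L, 0L),
               organization = c("cohesive", "cohesive", "none", "none"),
               sampleId = "s", treatment = "CTR", pairId = "p")
    om <- suppressWarnings(extractUnits(pt, caC, "organization_mean"))
    expect_equal(ncol(om), 1L)
    expect_equal(colData(om)$organization, "cohesive")
})

test_that("batch correction is inert for a single batch and harmless without batch effects", {
    b <- simulateSingleCellMatrix(simConfig(noiseCv = 0.2, seed = 41L),
                                  60L)$matrix
    expect_message(out <- combatCorrect(b), "single batch")
    expect_equal(assay(out, "intensities"), assay(b, "intensities"),
                 tolerance = 1e-10)

    ## two batches, identical generating process: correction stays within
    ## the noise scale (no-harm)
    b1 <- simulateSingleCellMatrix(simConfig(noiseCv = 0.2, pairId = "p1",
                                             seed = 42L), 250L)$matrix
    b2 <- simulateSingleCellMatrix(simConfig(noiseCv = 0.2, pairId = "p2",
                                             seed = 43L), 250L)$matrix
    mm <- combineUnits(b1, b2)
    out2 <- combatCorrect(mm)
    pre <- log(intensityMatrix(mm))
    post <- log(intensityMatrix(out2) + 1e-12)
    change <- apply(abs(pre - post), 2L, max)
    expect_lt(max(change / apply(pre, 2L, sd)), 1)
})

test_that("planted location and scale batch effects are removed, treatment preserved", {
    cv1 <- 0.2
    cv2 <- sqrt(exp(4 * log(1 + cv1^2)) - 1)   # doubles the log-noise SD
    mk <- function(pair, cv, scale, tr, seed)
        simulateSingleCellMatrix(simConfig(noiseCv = cv, pairId = pair,
                                           batchScale = scale,
                                           treatment = tr, seed = seed),
                                 250L)$matrix
    mm <- combineUnits(mk("p1", cv1, 1, "CTR", 51L),
                       mk("p1", cv1, 1, "EGF", 52L),
                       mk("p2", cv2, 2.5, "CTR", 53L),
                       mk("p2", cv2, 2.5, "EGF", 54L))
    cd <- as.data.frame(colData(mm))
    out <- combatCorrect(mm)
    x <- log(intensityMatrix(out) + 1e-12)
    b1 <- cd$pair_id == "p1"
    d <- colMeans(x[b1, ]) - colMeans(x[!b1, ])
    se <- sqrt(apply(x[b1, ], 2L, var) / sum(b1) +
               apply(x[!b1, ], 2L, var) / sum(!b1))
    expect_lt(stats::median(abs(d) / se), 3)
    vr <- apply(x[!b1, ], 2L, var) / apply(x[b1, ], 2L, var)
    expect_gt(mean(vr), 0.9); expect_lt(mean(vr), 1.1)

    ## planted treatment log2 fold changes survive within 10%
    lfc <- (colMeans(x[cd$treatment == "EGF", ]) -
            colMeans(x[cd$treatment == "CTR", ])) / log(2)
    panel <- lipidFeaturePanel()
    truth <- panel$effectLog2[panel$cellSpecific]
    sel <- abs(truth) > 0
    expect_lt(max(abs(lfc[sel] - truth[sel]) / abs(truth[sel])), 0.1)
})

test_that("our EB fit agrees with the reference implementation", {
    skip_if_not_installed("sva")
    set.seed(77)
    G <- 30L; n <- 40L
    bat <- rep(c("A", "B"), each = n / 2)
    dat <- matrix(rnorm(G * n, 8, 1), G, n)
    dat[, bat == "B"] <- dat[, bat == "B"] * 1.3 + 0.7
    ref <- sva::ComBat(dat, batch = bat)
    fit <- scLipidMSI:::.combatFit(dat, factor(bat), NULL)
    expect_equal(fit$corrected, ref, tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("z-scoring hits exact column moments and is idempotent", {
    ann <- data.frame(sample_id = "s", treatment = "CTR", pair_id = "p",
                      organization = "dispersed")
    m <- CellFeatureMatrix(cbind(a = c(1, 3), b = c(5, 9)), ann[c(1, 1), ])
    s <- zscoreScale(m)
    expect_equal(unname(assay(s, "scaled")[1L, ]),
                 c(-1 / sqrt(2), 1 / sqrt(2)))

    set.seed(8)
    big <- CellFeatureMatrix(matrix(rnorm(300), 30),
                             ann[rep(1, 30), ])
    sb <- zscoreScale(big)
    z <- t(assay(sb, "scaled"))
    expect_lt(max(abs(colMeans(z))), 1e-12)
    expect_lt(max(abs(apply(z, 2L, sd) - 1)), 1e-12)
    ## scaling the scaled values changes nothing
    z2 <- CellFeatureMatrix(z, ann[rep(1, 30), ])
    expect_lt(max(abs(t(assay(zscoreScale(z2), "scaled")) - z)), 1e-12)

    expect_error(zscoreScale(CellFeatureMatrix(matrix(1, 1, 3), ann)),
                 "two units")
    expect_warning(zscoreScale(CellFeatureMatrix(
        cbind(c(1, 1), c(1, 2)), ann[c(1, 1), ])), "zero-variance")
})

test_that("PCA explains a line fully, reconstructs at full rank, and decorrelates scores", {
    line <- cbind(1:20, 2 * (1:20)) + 0
    pc <- pcaEmbed(scale(line), nComponents = 2L)
    expect_equal(pc$explained[1L], 1)

    set.seed(10)
    x <- scale(matrix(rnorm(200), 20))
    pc2 <- pcaEmbed(x, nComponents = 10L)
    recon <- pc2$scores %*% t(pc2$rotation)
    expect_lt(max(abs(sweep(recon, 2L, colMeans(x), "+") - x)), 1e-8)
    cv <- cov(pc2$scores)
    expect_lt(max(abs(cv[upper.tri(cv)])), 1e-10)
    expect_true(all(diff(diag(cv)) <= 1e-12))

    expect_error(pcaEmbed(x, nComponents = 15L), "exceeds")
})
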