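makeGridPt <- function(m, pixelUm = 10, ...) {
    n <- nrow(m)
    co <- cbind(row = seq_len(n) - 1L, col = rep(0L, n))
    PeakTable(m, featureMz = seq(600, by = 10, length.out = ncol(m)),
              coords = co, gridShape = c(n, 1L), pixelUm = pixelUm, ...)
}

test_that("TIC normalization equalizes spectra to the mean raw TIC and is idempotent", {
    m <- rbind(c(4, 6), c(10, 20))          # TICs 10 and 30, target 20
    pt <- ticNormalize(makeGridPt(m))
    expect_equal(pt@intensities, rbind(c(8, 12), c(20 / 3, 40 / 3)))

    ## already uniform: identity
    u <- matrix(c(1, 3, 3, 1), 2)
    expect_equal(ticNormalize(makeGridPt(u))@intensities, u)

    set.seed(5)
    r <- matrix(rexp(600), 60)
    pt2 <- ticNormalize(makeGridPt(r))
    tics <- rowSums(pt2@intensities)
    expect_lt(var(tics), 1e-10 * mean(tics)^2)
    pt3 <- ticNormalize(pt2)
    expect_lt(max(abs(pt3@intensities - pt2@intensities)), 1e-12)

    expect_error(ticNormalize(makeGridPt(matrix(0, 4, 3))), "zero")
})

test_that("zero-TIC pixels are left at zero and counted", {
    m <- rbind(c(0, 0), c(2, 2), c(3, 1))
    pt <- ticNormalize(makeGridPt(m))
    expect_equal(pt@intensities[1L, ], c(0, 0))
    expect_equal(pt@metadata$nZeroTic, 1L)
})

test_that("noise estimation is robust and consistent", {
    expect_equal(estimateNoise(rep(3, 100)), 0)
    set.seed(11)
    x <- rnorm(1e5)
    expect_gt(estimateNoise(x), 0.97)
    expect_lt(estimateNoise(x), 1.03)
    ## a single huge spike barely moves the estimate
    y <- x[1:5000]
    ySpike <- y; ySpike[2500] <- 1e4
    expect_lt(abs(estimateNoise(ySpike) - estimateNoise(y)) /
              estimateNoise(y), 0.05)
})

test_that("peak picking finds planted peaks above SNR 6 and centroids them", {
    expect_equal(nrow(pickPeaks(rep(0, 100), seq_len(100))), 0L)

    sp <- simulateProfileSpectrum(data.frame(mz = 700.18, height = 100),
                                  fwhmDa = 0.3, noiseSd = 1, seed = 2L)
    pk <- pickPeaks(sp$intensity, sp$mz)
    near <- pk[abs(pk$mz - 700.18) < 1, ]
    expect_equal(nrow(near), 1L)
    expect_lt(abs(near$mz - 700.18), 0.15)   # within FWHM/2

    ## height 5 on sigma = 1 noise is below the 6x threshold
    lo <- simulateProfileSpectrum(data.frame(mz = 700.18, height = 5),
                                  fwhmDa = 0.3, noiseSd = 1, seed = 2L)
    pkLo <- pickPeaks(lo$intensity, lo$mz)
    expect_equal(nrow(pkLo[abs(pkLo$mz - 700.18) < 0.3, ]), 0L)
})

test_that("peak alignment clusters by gap, pools intensities, and ignores pixel order", {
    co <- cbind(row = 0:1, col = c(0L, 0L))
    ## identical lists across pixels
    pl <- list(data.frame(mz = c(600, 700), intensity = c(1, 2)),
               data.frame(mz = c(600, 700), intensity = c(3, 4)))
    pt <- alignPeaks(pl, co, c(2L, 1L))
    expect_equal(pt@featureMz, c(600, 700))
    expect_equal(pt@intensities, rbind(c(1, 2), c(3, 4)))

    ## 700.00 vs 700.04 merge at tol 0.1
    pl2 <- list(data.frame(mz = 700.00, intensity = 1),
                data.frame(mz = 700.04, intensity = 1))
    expect_length(alignPeaks(pl2, co, c(2L, 1L), tolDa = 0.1)@featureMz, 1L)

    ## jittered planted features are recovered exactly
    set.seed(7)
    centres <- seq(520, 980, by = 20)
    pls <- lapply(1:40, function(i)
        data.frame(mz = centres + rnorm(length(centres), 0, 0.01),
                   intensity = rexp(length(centres))))
    co40 <- cbind(row = 0:39, col = rep(0L, 40))
    ptJ <- alignPeaks(pls, co40, c(40L, 1L))
    expect_length(ptJ@featureMz, length(centres))

    ## permuting pixels permutes rows and nothing else
    perm <- sample(40)
    ptP <- alignPeaks(pls[perm], co40[perm, ], c(40L, 1L))
    expect_equal(ptP@featureMz, ptJ@featureMz)
    expect_equal(ptP@intensities[order(perm), ], ptJ@intensities)
})

test_that("rare features are dropped by the observation-fraction filter", {
    pls <- c(list(data.frame(mz = c(600, 900), intensity = c(1, 1))),
             replicate(99, data.frame(mz = 600, intensity = 1),
                       simplify = FALSE))
    co <- cbind(row = 0:99, col = rep(0L, 100))
    pt <- alignPeaks(pls, co, c(100L, 1L), minFrac = 0.02)
    expect_equal(pt@featureMz, 600)
})

test_that("spatial k-means separates an intensity block and matches planted cell masks", {
    ## two pixel populations on a 10x10 grid: high block vs zero
    co <- cbind(row = rep(0:9, each = 10L), col = rep(0:9, 10L))
    hi <- co[, 1L] < 5L
    m <- matrix(0, 100, 3)
    m[hi, ] <- 50 + matrix(runif(sum(hi) * 3), sum(hi))
    m[!hi, ] <- matrix(runif(sum(!hi) * 3) * 0.1, sum(!hi))
    pt <- PeakTable(m, c(600, 700, 800), co, c(10L, 10L))
    part <- spatialKmeans(pt, seed = 2L)
    expect_identical(isCell(part), hi)

    ## permuting pixel order leaves the partition untouched
    perm <- sample(100)
    pt2 <- PeakTable(m[perm, ], c(600, 700, 800), co[perm, ], c(10L, 10L))
    part2 <- spatialKmeans(pt2, seed = 2L)
    expect_identical(isCell(part2), hi[perm])

    ## planted slide: accuracy vs truth
    sim <- simulateExperiment(simConfig(gridShape = c(60, 60),
                                        nColonies = 2L, nSingletons = 8L,
                                        seed = 5L))
    ptS <- ticNormalize(asPeakTable(sim$msi))
    partS <- spatialKmeans(ptS, seed = 3L)
    acc <- mean(isCell(partS) == as.vector(sim$truth@cellMask))
    expect_gte(acc, 0.95)

    expect_error(spatialKmeans(PeakTable(m[1, , drop = FALSE],
                                         c(600, 700, 800),
                                         co[1, , drop = FALSE],
                                         c(10L, 10L)), k = 2L), "fewer")
})

test_that("the 5x filter is inclusive, monotone in its threshold, and recovers planted features", {
    co <- cbind(row = 0:3, col = rep(0L, 4))
    m <- rbind(c(10, 9.9, 5), c(10, 9.9, 5),    # cell pixels
               c(2, 2, 0), c(2, 2, 0))          # background pixels
    pt <- PeakTable(m, c(600, 700, 800), co, c(4L, 1L))
    part <- new("PixelPartition", coords = co, gridShape = c(4L, 1L),
                pixelUm = 10, labels = c(1L, 1L, 2L, 2L), cellLabel = 1L)
    keep <- cellSpecificPeaks(pt, part)
    expect_identical(keep, c(1L, 3L))            # ratio 5 kept, 4.95 dropped,
                                                 # zero background kept
    ## monotone in ratioMin
    prev <- seq_len(3L)
    for (r in c(1, 2, 5, 6)) {
        cur <- cellSpecificPeaks(pt, part, ratioMin = r)
        expect_true(all(cur %in% prev))
        prev <- cur
    }

    sim <- simulateExperiment(simConfig(gridShape = c(60, 60),
                                        nColonies = 2L, nSingletons = 8L,
                                        noiseCv = 0.1, seed = 6L))
    ptS <- ticNormalize(asPeakTable(sim$msi))
    partS <- spatialKmeans(ptS, seed = 3L)
    expect_identical(cellSpecificPeaks(ptS, partS),
                     sim$truth@cellSpecificFeatures)

    allCell <- new("PixelPartition", coords = co, gridShape = c(4L, 1L),
                   pixelUm = 10, labels = rep(1L, 4), cellLabel = 1L)
    expect_error(cellSpecificPeaks(pt, allCell), "background")
})

test_that("mean spectra equal brute-force column means", {
    co <- cbind(row = 0:1, col = c(0L, 0L))
    pt <- makeGridPt(rbind(c(0, 2), c(4, 0)))
    expect_equal(unname(meanSpectrum(pt, 1L)), c(0, 2))
    expect_equal(unname(meanSpectrum(pt, c(1L, 2L))), c(2, 1))
    set.seed(3)
    big <- makeGridPt(matrix(rnorm(200, 10), 20))
    sub <- sample(20, 7)
    expect_lt(max(abs(meanSpectrum(big, sub) -
                      apply(big@intensities[sub, ], 2, mean))), 1e-12)
    expect_error(meanSpectrum(big, integer(0)), "empty")
})
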