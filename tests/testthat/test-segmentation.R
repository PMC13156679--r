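test_that("Gaussian blur preserves total mass and Otsu separates bimodal images", {
    img <- matrix(0, 41, 41)
    img[21, 21] <- 7
    expect_equal(sum(gaussianBlur(img, 5)), 7, tolerance = 1e-6)

    bi <- matrix(10, 20, 20)
    bi[5:12, 5:12] <- 200
    thr <- otsuThreshold(bi)
    expect_gt(thr, 10); expect_lt(thr, 200)
    mask <- blurAndThreshold(bi, sigmaPx = 0.5, darkForeground = FALSE)
    expect_identical(unname(which(mask)), unname(which(bi == 200)))

    expect_error(blurAndThreshold(matrix(1, 5, 5)), "distinct")
})

test_that("Otsu matches the exhaustive brute-force threshold on random images", {
    set.seed(42)
    for (i in 1:30) {
        x <- c(rnorm(150, 0, 1), rnorm(100, sample(2:6, 1), runif(1, 0.5, 2)))
        expect_equal(otsuThreshold(x), oracleOtsu(x), tolerance = 1e-10)
    }
})

test_that("contours report components, areas and ignore holes", {
    m <- matrix(FALSE, 20, 20)
    m[3:12, 3:12] <- TRUE                      # 10x10 square
    cs <- findCellContours(m, umPerPx = 1)
    expect_length(cs@accepted, 1L)
    expect_equal(cs@areaUm2, 100)
    expect_equal(cs@aspectRatio, 1)

    m2 <- m; m2[15:18, 15:17] <- TRUE          # second blob
    expect_length(findCellContours(m2, 1)@accepted, 2L)

    ring <- matrix(FALSE, 20, 20)
    ring[5:15, 5:15] <- TRUE
    ring[8:12, 8:12] <- FALSE                  # hole
    csR <- findCellContours(ring, 1)
    expect_length(csR@accepted, 1L)
    expect_equal(csR@areaUm2, 11^2 - 5^2)      # pixel count of the ring only
})

test_that("the single-cell filter applies inclusive area and aspect bounds", {
    mk <- function(area, aspect) {
        new("CellContours", pixelIdx = list(1L), areaUm2 = area,
            bbox = matrix(0L, 1, 4), aspectRatio = aspect, accepted = TRUE,
            umPerPx = 1, imageDim = c(10L, 10L))
    }
    expect_false(filterSingleCellContours(mk(99, 1))@accepted)
    expect_true(filterSingleCellContours(mk(100, 1))@accepted)
    expect_true(filterSingleCellContours(mk(2500, 1))@accepted)
    expect_false(filterSingleCellContours(mk(2501, 1))@accepted)
    expect_false(filterSingleCellContours(mk(500, 1.30))@accepted)
    expect_true(filterSingleCellContours(mk(500, 1.25))@accepted)

    ## random contour sets match the brute-force predicate; filter idempotent
    set.seed(9)
    n <- 200
    cs <- new("CellContours", pixelIdx = as.list(seq_len(n)),
              areaUm2 = runif(n, 0, 3000),
              bbox = matrix(0L, n, 4),
              aspectRatio = runif(n, 0.4, 1.6),
              accepted = rep(TRUE, n), umPerPx = 1, imageDim = c(10L, 10L))
    f1 <- filterSingleCellContours(cs)
    manual <- cs@areaUm2 >= 100 & cs@areaUm2 <= 2500 &
        cs@aspectRatio >= 0.75 & cs@aspectRatio <= 1.25
    expect_identical(f1@accepted, manual)
    expect_identical(filterSingleCellContours(f1)@accepted, f1@accepted)
})

## a tiny constructed scene: one isolated 2x2 blob, one 3x3 blob
makeScene <- function() {
    rows <- 12L; cols <- 12L
    cellGrid <- matrix(FALSE, rows, cols)
    cellGrid[2:3, 2:3] <- TRUE
    cellGrid[7:9, 7:9] <- TRUE
    co <- cbind(row = rep(0:(rows - 1L), times = cols),
                col = rep(0:(cols - 1L), each = rows))
    labels <- ifelse(as.vector(cellGrid), 1L, 2L)
    part <- new("PixelPartition", coords = co, gridShape = c(rows, cols),
                pixelUm = 10, labels = labels, cellLabel = 1L)
    ## brightfield at 5 um/px, blobs rendered exactly over the MSI pixels
    bfDim <- c(24L, 24L)
    bf <- matrix(1, bfDim[1L], bfDim[2L])
    bf[3:6, 3:6] <- 0       # covers MSI rows 1:2, cols 1:2 (0-based 1..2)
    bf[13:18, 13:18] <- 0
    list(part = part, img = BrightfieldImage(bf, umPerPx = 5),
         cellGrid = cellGrid)
}

test_that("pixel assignment labels isolated singly-contoured blobs dispersed", {
    sc <- makeScene()
    cs <- findCellContours(sc$img@pixels < 0.5, sc$img@umPerPx)
    ca <- assignPixels(cs, sc$part, sc$img)
    ## conservation: assignment never changes which pixels are cells
    expect_identical(isCell(ca), as.vector(sc$cellGrid))
    org <- organization(ca)[isCell(ca)]
    expect_true(all(org == "dispersed"))
    expect_equal(length(setdiff(unique(cellIds(ca)), 0L)), 2L)
})

test_that("a component overlapped by two accepted contours becomes cohesive", {
    sc <- makeScene()
    ## two contours split the 3x3 blob: multiplet rule must fire
    bf <- sc$img@pixels
    cs <- findCellContours(bf < 0.5, 5)
    ## fabricate: duplicate the second contour shifted by one bf pixel
    idx2 <- cs@pixelIdx[[2L]]
    cs2 <- new("CellContours",
               pixelIdx = c(cs@pixelIdx, list(idx2 + 1L)),
               areaUm2 = c(cs@areaUm2, cs@areaUm2[2L]),
               bbox = rbind(cs@bbox, cs@bbox[2L, ]),
               aspectRatio = c(cs@aspectRatio, cs@aspectRatio[2L]),
               accepted = rep(TRUE, 3L), umPerPx = 5,
               imageDim = cs@imageDim)
    ca <- assignPixels(cs2, sc$part, sc$img)
    org <- organization(ca)[isCell(ca)]
    comp2 <- cellIds(ca) == 0L | TRUE          # just look at the big blob
    expect_true("cohesive" %in% org)
    ## the small blob keeps its unique contour and stays dispersed
    expect_true("dispersed" %in% org)
})

test_that("synthetic scenes get 100% correct organization labels", {
    for (seed in c(2L, 13L)) {
        sim <- simulateExperiment(simConfig(gridShape = c(80, 80),
                                            nColonies = 3L,
                                            nSingletons = 10L, seed = seed))
        pt <- ticNormalize(asPeakTable(sim$msi))
        part <- spatialKmeans(pt, seed = 1L)
        mask <- blurAndThreshold(sim$brightfield, 5)
        cs <- filterSingleCellContours(
            findCellContours(mask, sim$brightfield@umPerPx))
        ca <- assignPixels(cs, part, sim$brightfield)
        lin <- pt@coords[, 1L] + 1L + pt@coords[, 2L] * 80L
        planted <- as.vector(sim$truth@cellIdMap)[lin]
        for (pid in setdiff(unique(planted), 0L)) {
            sel <- planted == pid & isCell(ca)
            if (!any(sel)) next
            lab <- unique(organization(ca)[sel])
            expect_identical(lab, unname(
                sim$truth@organizationMap[[as.character(pid)]]))
        }
        ## dispersed ids are unique per component and never exceed cell count
        expect_lte(sum(organization(ca) == "dispersed"), sum(isCell(ca)))
    }
})

test_that("population summaries report pixel percentages and group shares", {
    co <- cbind(row = rep(0:9, times = 10L), col = rep(0:9, each = 10L))
    org <- rep("none", 100); org[1:12] <- "cohesive"; org[1:3] <- "dispersed"
    ca <- new("CellAssignment", coords = co, gridShape = c(10L, 10L),
              pixelUm = 10, isCell = org != "none",
              cellId = integer(100), organization = org,
              sampleId = "s1", treatment = "CTR", pairId = "p1")
    ps <- populationSummary(list(ca))
    expect_equal(ps$perSample$pct_cell_pixels, 12)
    expect_equal(ps$perSample$pct_dispersed, 25)

    shares <- groupShares(c(CTR = 446, EGF = 893))
    expect_equal(round(shares[["CTR"]], 1), 33.3)
    expect_equal(round(shares[["EGF"]], 1), 66.7)
})
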