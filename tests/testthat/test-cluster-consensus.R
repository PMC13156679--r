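test_that("SNN weights match exhaustive set arithmetic", {
    ## two identical points far from the rest share their whole k=1 hood
    x <- rbind(c(0, 0), c(0, 0), c(10, 0), c(0, 10), c(10, 10))
    g <- snnGraph(x, k = 1L)
    w <- igraph::as_data_frame(g)
    pair <- w[w$from == "1" & w$to == "2", ]
    expect_equal(pair$weight, 1)

    set.seed(14)
    y <- matrix(rnorm(250), 50)
    for (k in c(3L, 7L)) {
        gk <- snnGraph(y, k = k)
        W <- matrix(0, 50, 50)
        ed <- igraph::as_data_frame(gk)
        idx <- cbind(as.integer(ed$from), as.integer(ed$to))
        W[idx] <- ed$weight; W[idx[, 2:1]] <- ed$weight
        expect_lt(max(abs(W - oracleSnnWeights(y, k))), 1e-10)
    }
    expect_error(snnGraph(y, k = 0L), "positive")
})

test_that("Leiden resolves cliques, collapses at low resolution, and is seed-stable", {
    ## two 5-cliques joined by one weak edge
    edges <- rbind(t(combn(1:5, 2)), t(combn(6:10, 2)), c(5, 6))
    wts <- c(rep(1, 20), 0.05)
    g <- igraph::graph_from_data_frame(
        data.frame(from = edges[, 1], to = edges[, 2], weight = wts),
        directed = FALSE, vertices = data.frame(name = 1:10))
    lab <- leidenPartition(g, resolution = 1, seed = 3L)
    expect_equal(length(unique(lab)), 2L)
    expect_equal(length(unique(lab[1:5])), 1L)
    expect_equal(length(unique(lab[6:10])), 1L)

    expect_equal(length(unique(leidenPartition(g, resolution = 1e-4,
                                               seed = 3L))), 1L)
    expect_identical(leidenPartition(g, 0.8, seed = 11L),
                     leidenPartition(g, 0.8, seed = 11L))
})

test_that("consensus matrices are valid, block-structured for separated blobs, and MC-stable", {
    blobs <- makeBlobs(60, rbind(c(0, 0, 0), c(6, 6, 6)), sd = 0.3,
                       seed = 2L)
    cc <- consensusCluster(scale(blobs$x), kGrid = c(5, 10),
                          resGrid = seq(0.2, 1.2, by = 0.2), nIter = 60L,
                          seed = 5L, minSupport = 10L)
    C <- consensusMatrix(cc, 2L)
    expect_false(is.null(C))
    expect_equal(diag(C), rep(1, 60))
    expect_lt(max(abs(C - t(C))), 1e-12)
    expect_true(all(C >= 0 & C <= 1))
    same <- outer(blobs$labels, blobs$labels, "==")
    expect_lt(max(abs(C[same] - 1)), 0.05)
    expect_lt(max(C[!same]), 0.05)

    ## a different seed stream moves entries only within MC noise
    cc2 <- consensusCluster(scale(blobs$x), kGrid = c(5, 10),
                           resGrid = seq(0.2, 1.2, by = 0.2), nIter = 60L,
                           seed = 1005L, minSupport = 10L)
    expect_lt(max(abs(consensusMatrix(cc2, 2L) - C)), 0.05)
})

test_that("a single iteration with a single grid point yields {0, 1, imputed} entries", {
    blobs <- makeBlobs(24, rbind(c(0, 0), c(5, 5)), sd = 0.3, seed = 3L)
    cc <- suppressMessages(consensusCluster(
        scale(blobs$x), kGrid = 5, resGrid = 0.5, nIter = 1L, seed = 2L,
        minSupport = 1L))
    C <- cc@consensus[[1L]]
    offdiag <- C[upper.tri(C)]
    fill <- mean(offdiag[offdiag > 0 & offdiag < 1])  # the imputed value
    expect_true(all(offdiag %in% c(0, 1, fill)))
    expect_gt(cc@nImputed[[1L]], 0L)
})

test_that("McQuitty cuts recover perfect blocks and match the recursive oracle", {
    C <- matrix(0, 6, 6); C[1:3, 1:3] <- 1; C[4:6, 4:6] <- 1; diag(C) <- 1
    lab <- consensusCut(C, 2L)
    expect_equal(length(unique(lab[1:3])), 1L)
    expect_equal(length(unique(lab[4:6])), 1L)
    expect_false(lab[1L] == lab[4L])

    set.seed(21)
    for (i in 1:20) {
        D <- matrix(0, 6, 6)
        D[upper.tri(D)] <- runif(15)
        D <- D + t(D)
        hc <- hclust(as.dist(D), method = "mcquitty")
        expect_lt(max(abs(hc$height - oracleWpgmaHeights(D))), 1e-10)
    }

    ## K = n: every point its own cluster
    expect_equal(sort(unique(consensusCut(C, 6L))), 1:6)
    expect_error(consensusCut(C, 7L), "exceeds")

    ## permutation equivariance
    set.seed(4)
    Cr <- cov2cor(crossprod(matrix(runif(100), 10)))
    p <- sample(10)
    labA <- consensusCut(Cr, 3L)
    labB <- consensusCut(Cr[p, p], 3L)
    expect_equal(mclust::adjustedRandIndex(labA[p], labB), 1)
})

test_that("silhouettes match the formula and handle degenerate cases", {
    blobs <- makeBlobs(40, rbind(c(0, 0), c(8, 8)), sd = 0.2, seed = 6L)
    s <- silhouetteScore(blobs$x, blobs$labels)
    expect_gt(s$mean, 0.9)

    same <- matrix(1, 6, 2)
    expect_equal(silhouetteScore(same, rep(1:2, 3))$mean, 0)

    set.seed(30)
    x8 <- matrix(rnorm(16), 8)
    lab8 <- c(1, 1, 1, 2, 2, 3, 3, 3)
    expect_lt(max(abs(silhouetteScore(x8, lab8)$widths -
                      oracleSilhouette(x8, lab8))), 1e-10)
    if (requireNamespace("cluster", quietly = TRUE)) {
        ref <- cluster::silhouette(lab8, dist(x8))[, "sil_width"]
        expect_lt(max(abs(silhouetteScore(x8, lab8)$widths - ref)), 1e-10)
    }
    expect_error(silhouetteScore(x8, rep(1, 8)), "two clusters")
})

test_that("selectK ranks the planted blob count first and honours overrides", {
    blobs <- makeBlobs(60, rbind(c(0, 0, 0), c(6, 6, 6)), sd = 0.3,
                       seed = 2L)
    x <- scale(blobs$x)
    cc <- consensusCluster(x, kGrid = c(5, 10),
                          resGrid = seq(0.2, 1.6, by = 0.2), nIter = 50L,
                          seed = 5L, minSupport = 10L)
    emb <- pcaEmbed(x, nComponents = 2L)$scores
    cc <- selectK(cc, emb)
    expect_equal(cc@ranking$K[1L], 2L)
    expect_equal(selectedK(cc), 2L)
    expect_equal(mclust::adjustedRandIndex(clusterLabels(cc),
                                           blobs$labels), 1)

    other <- cc@ranking$K[2L]
    ccO <- selectK(cc, emb, override = other)
    expect_equal(selectedK(ccO), other)
    expect_identical(clusterLabels(ccO), cc@cuts[[as.character(other)]])
    expect_error(selectK(cc, emb, override = 999L), "candidate")
})

test_that("off-block consensus decreases as separation grows", {
    offblock <- vapply(c(1.5, 3, 6), function(sep) {
        blobs <- makeBlobs(40, rbind(c(0, 0), c(sep, sep)), sd = 0.5,
                           seed = 7L)
        cc <- consensusCluster(scale(blobs$x), kGrid = c(5, 10),
                              resGrid = c(0.4, 0.8, 1.2), nIter = 40L,
                              seed = 3L, minSupport = 5L)
        C <- consensusMatrix(cc, 2L)
        if (is.null(C)) return(NA_real_)
        same <- outer(blobs$labels, blobs$labels, "==")
        mean(C[!same])
    }, numeric(1))
    expect_true(all(diff(offblock) <= 0))
})

test_that("t-SNE is deterministic, 2-D, and keeps duplicated rows together", {
    set.seed(40)
    x <- scale(matrix(rnorm(40 * 5), 40))
    x[40, ] <- x[1, ]                         # exact duplicate
    y1 <- tsneEmbed(x, seed = 2L, nIter = 250L)
    y2 <- tsneEmbed(x, seed = 2L, nIter = 250L)
    expect_identical(y1, y2)
    expect_equal(dim(y1), c(40L, 2L))
    D <- as.matrix(dist(y1))
    expect_lt(D[1L, 40L], quantile(D[upper.tri(D)], 0.05))
})
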