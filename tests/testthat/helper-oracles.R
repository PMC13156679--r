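## Independent brute-force oracles used across the suite. These deliberately
## take the slow, literal route so they share no code with the package.

suppressMessages({
    library(SummarizedExperiment)
})

## Otsu: try every split of the 256-bin histogram, computing class weights
## and means from bin counts and mids with explicit loops.
oracleOtsu <- function(x, nbins = 256L) {
    x <- as.numeric(x)
    breaks <- seq(min(x), max(x), length.out = nbins + 1L)
    bin <- pmin(findInterval(x, breaks, rightmost.closed = TRUE), nbins)
    cnt <- tabulate(bin, nbins)
    mids <- (breaks[-1L] + breaks[-(nbins + 1L)]) / 2
    best <- -Inf; bestThr <- NA_real_
    for (t in seq_len(nbins - 1L)) {
        n0 <- sum(cnt[1:t]); n1 <- sum(cnt[(t + 1L):nbins])
        if (n0 == 0 || n1 == 0) next
        mu0 <- sum(cnt[1:t] * mids[1:t]) / n0
        mu1 <- sum(cnt[(t + 1L):nbins] * mids[(t + 1L):nbins]) / n1
        bc <- (n0 / length(x)) * (n1 / length(x)) * (mu0 - mu1)^2
        if (bc > best) { best <- bc; bestThr <- breaks[t + 1L] }
    }
    bestThr
}

## WPGMA by literal recursion on the dissimilarity matrix; returns merge
## heights in order.
oracleWpgmaHeights <- function(D) {
    D <- as.matrix(D)
    n <- nrow(D)
    active <- as.list(seq_len(n))
    heights <- numeric(0)
    while (length(active) > 1L) {
        m <- length(active)
        best <- c(NA, NA); bestD <- Inf
        for (i in seq_len(m - 1L)) for (j in (i + 1L):m)
            if (D[i, j] < bestD) { bestD <- D[i, j]; best <- c(i, j) }
        heights <- c(heights, bestD)
        i <- best[1L]; j <- best[2L]
        newRow <- (D[i, ] + D[j, ]) / 2
        keep <- setdiff(seq_len(m), c(i, j))
        D <- rbind(cbind(D[keep, keep, drop = FALSE], newRow[keep]),
                   c(newRow[keep], 0))
        active <- c(active[keep], list(c(active[[i]], active[[j]])))
    }
    heights
}

## silhouette by definition, one point at a time
oracleSilhouette <- function(x, labels) {
    D <- as.matrix(dist(x))
    n <- nrow(D)
    s <- numeric(n)
    for (i in seq_len(n)) {
        own <- which(labels == labels[i])
        if (length(own) == 1L) { s[i] <- 0; next }
        a <- mean(D[i, setdiff(own, i)])
        b <- Inf
        for (k in setdiff(unique(labels), labels[i]))
            b <- min(b, mean(D[i, labels == k]))
        s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }
    s
}

## SNN Jaccard weights from exhaustive self-inclusive k-NN lists
oracleSnnWeights <- function(x, k) {
    n <- nrow(x)
    D <- as.matrix(dist(x))
    sets <- lapply(seq_len(n), function(i) {
        d <- D[i, ]; d[i] <- -1
        order(d, seq_len(n))[seq_len(k + 1L)]
    })
    W <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        inter <- length(intersect(sets[[i]], sets[[j]]))
        if (inter > 0)
            W[i, j] <- W[j, i] <-
                inter / length(union(sets[[i]], sets[[j]]))
    }
    W
}

## type-7 quartiles by hand, then literal interval intersection
oracleIqrOverlap <- function(x, y) {
    q7 <- function(v, p) {
        v <- sort(v); n <- length(v)
        h <- (n - 1) * p + 1
        lo <- floor(h); hi <- ceiling(h)
        v[lo] + (h - lo) * (v[hi] - v[lo])
    }
    ix <- c(q7(x, 0.25), q7(x, 0.75))
    iy <- c(q7(y, 0.25), q7(y, 0.75))
    !(ix[2] < iy[1] || iy[2] < ix[1])
}

## Welch and paired t statistics from the textbook formulas
oracleWelch <- function(x, y) {
    vx <- var(x) / length(x); vy <- var(y) / length(y)
    t <- (mean(x) - mean(y)) / sqrt(vx + vy)
    df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
    list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
oraclePaired <- function(x, y) {
    d <- x - y
    t <- mean(d) / (sd(d) / sqrt(length(d)))
    list(t = t, df = length(d) - 1, p = 2 * pt(-abs(t), length(d) - 1))
}

## simple blob mixture for clustering checks
makeBlobs <- function(n, centers, sd = 0.2, seed = 1) {
    set.seed(seed)
    lab <- rep(seq_len(nrow(centers)), length.out = n)
    x <- centers[lab, , drop = FALSE] +
        matrix(rnorm(n * ncol(centers), 0, sd), n)
    list(x = x, labels = lab)
}

## subpopulation specs with block shifts (one feature block per subpop)
blockSubpops <- function(nSub, nFeat = 46L, shift = 1.5, block = 6L,
                         fractions = NULL) {
    if (is.null(fractions)) fractions <- rep(1 / nSub, nSub)
    lapply(seq_len(nSub), function(s) {
        v <- rep(0, nFeat)
        idx <- (((s - 1L) * block) %% nFeat) + seq_len(block)
        v[((idx - 1L) %% nFeat) + 1L] <- shift
        list(fraction = fractions[s], shift = v)
    })
}
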