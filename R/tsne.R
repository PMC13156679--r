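## Compact exact t-SNE, used only for visualization of single-cell matrices.

#' t-SNE embedding
#'
#' Exact (non-approximate) t-distributed stochastic neighbour embedding into
#' two dimensions: per-point Gaussian bandwidths are calibrated to the target
#' perplexity by bisection, and the embedding is optimized by gradient
#' descent with momentum and early exaggeration. O(n^2) per iteration, which
#' is adequate for the cell counts this package targets (hundreds to a few
#' thousand); deterministic under the seed. Used for plots only -- no
#' downstream statistic depends on it.
#'
#' @param m scaled \linkS4class{CellFeatureMatrix} or units x features
#'   matrix.
#' @param seed RNG seed for the initialization.
#' @param perplexity target perplexity (default 30, reduced automatically
#'   when n is small).
#' @param nIter gradient iterations (default 500).
#' @return an n x 2 coordinate matrix.
#' @export
tsneEmbed <- function(m, seed = 1L, perplexity = 30, nIter = 500L) {
    x <- .asCellMatrix(m)
    n <- nrow(x)
    stopifnot(n >= 4L)
    perplexity <- min(perplexity, floor((n - 1) / 3))
    d2 <- as.matrix(stats::dist(x))^2

    ## per-point precision by bisection to the target entropy
    P <- matrix(0, n, n)
    logU <- log(perplexity)
    for (i in seq_len(n)) {
        beta <- 1; lo <- -Inf; hi <- Inf
        di <- d2[i, -i]
        for (it in seq_len(50L)) {
            p <- exp(-di * beta)
            sp <- sum(p)
            if (sp == 0) { H <- 0; p[] <- 0 }
            else {
                H <- log(sp) + beta * sum(di * p) / sp
                p <- p / sp
            }
            if (abs(H - logU) < 1e-5) break
            if (H > logU) { lo <- beta; beta <- if (is.finite(hi))
                (beta + hi) / 2 else beta * 2 }
            else { hi <- beta; beta <- if (is.finite(lo))
                (beta + lo) / 2 else beta / 2 }
        }
        P[i, -i] <- p
    }
    P <- (P + t(P)) / (2 * n)
    P <- pmax(P, 1e-12)

    set.seed(seed)
    Y <- matrix(stats::rnorm(n * 2L, sd = 1e-4), n, 2L)
    G <- matrix(0, n, 2L)
    exag <- 12; lr <- 200
    for (it in seq_len(nIter)) {
        Pit <- if (it <= 100L) P * exag else P
        num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
        diag(num) <- 0
        Q <- pmax(num / sum(num), 1e-12)
        L <- (Pit - Q) * num
        grad <- 4 * (diag(rowSums(L)) %*% Y - L %*% Y)
        mom <- if (it <= 250L) 0.5 else 0.8
        G <- mom * G - lr * grad
        Y <- Y + G
        Y <- sweep(Y, 2L, colMeans(Y))
    }
    Y
}
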