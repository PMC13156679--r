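## Single-cell clustering: SNN graph, Leiden partitions over a parameter
## grid, subsampled consensus matrices per realized cluster number, McQuitty
## consensus cuts, and silhouette-based selection of K.

#' @importFrom igraph graph_from_data_frame cluster_leiden membership E gorder
NULL

.asCellMatrix <- function(m) {
    if (is(m, "CellFeatureMatrix")) {
        if (!isTRUE(metadata(m)$scaled))
            stop("scale the matrix first (zscoreScale)")
        t(assay(m, "scaled"))
    } else as.matrix(m)
}

#' Shared-nearest-neighbour graph
#'
#' k-nearest neighbours by Euclidean distance (ties broken by index; each
#' point's neighbour set includes itself), connected by an edge whenever two
#' points share at least one neighbour, weighted by the Jaccard index of
#' their neighbour sets: \code{|N(i) & N(j)| / |N(i) | N(j)|}.
#'
#' @param m scaled \linkS4class{CellFeatureMatrix} or a units x features
#'   matrix.
#' @param k number of neighbours (excluding self), \code{0 < k < n}.
#' @return an undirected weighted \code{igraph} graph with \code{n} vertices.
#' @export
snnGraph <- function(m, k) {
    x <- .asCellMatrix(m)
    n <- nrow(x)
    if (k <= 0L) stop("k must be positive")
    if (k >= n) stop("k must be below the number of units")
    D <- as.matrix(stats::dist(x))
    diag(D) <- -1                     # self is always the first neighbour
    nb <- .knnOrder(D, as.integer(k + 1L))
    .snnFromNeighbours(nb, n)
}

## nb: (k+1) x n matrix of 1-based self-inclusive neighbour indices.
## Returns the SNN edge list and Jaccard weights as plain vectors.
.snnEdges <- function(nb, n) {
    k1 <- nrow(nb)
    A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k1),
                              j = as.vector(nb), x = 1, dims = c(n, n))
    S <- Matrix::tcrossprod(A)
    S <- methods::as(S, "TsparseMatrix")
    keep <- S@i < S@j
    inter <- S@x[keep]
    list(i = S@i[keep] + 1L, j = S@j[keep] + 1L,
         w = inter / (2 * k1 - inter))
}

.snnFromNeighbours <- function(nb, n) {
    e <- .snnEdges(nb, n)
    g <- igraph::make_graph(rbind(e$i, e$j), n = n, directed = FALSE)
    igraph::E(g)$weight <- e$w
    g$k <- nrow(nb) - 1L
    g
}

#' Leiden community detection
#'
#' Runs the Leiden algorithm with the resolution-parameterized modularity
#' objective on a weighted SNN graph; deterministic under a fixed seed.
#'
#' @param g an \code{igraph} graph (weights used when present).
#' @param resolution resolution parameter (larger = more communities).
#' @param seed RNG seed.
#' @param nIterations Leiden refinement sweeps (default 2).
#' @return integer community labels, one per vertex.
#' @export
leidenPartition <- function(g, resolution = 1, seed = 1L, nIterations = 2L) {
    if (igraph::gorder(g) == 0L) stop("empty graph")
    set.seed(seed)
    cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution,
                                 weights = igraph::E(g)$weight,
                                 n_iterations = nIterations)
    as.integer(igraph::membership(cl))
}

#' Subsampled SNN/Leiden consensus clustering
#'
#' In each of \code{nIter} iterations a fraction \code{subsample} of the
#' cells is drawn without replacement and partitioned once for every
#' combination of the neighbour grid (default 8 values) and resolution grid
#' (default 19 values). Every partition is binned by its \emph{realized}
#' number of clusters K, and for each retained K a consensus matrix is
#' accumulated: entry (i, j) is the fraction of partitions with that K, among
#' those where i and j were co-sampled, in which they co-clustered. Candidate
#' K values supported by fewer than \code{minSupport} partitions are
#' discarded; never-co-sampled entries are imputed with the matrix mean (the
#' count is recorded).
#'
#' Per-iteration and per-partition seeds are derived from the master seed by
#' counter, so results do not depend on scheduling.
#'
#' @param m scaled \linkS4class{CellFeatureMatrix} or units x features
#'   matrix.
#' @param kGrid neighbour counts (default \code{c(5, 10, 15, 20, 25, 30, 40,
#'   50)}).
#' @param resGrid resolutions (default \code{seq(0.1, 1.9, by = 0.1)}).
#' @param nIter subsampling iterations (default 500).
#' @param subsample resampling rate (default 0.8).
#' @param seed master seed.
#' @param minSupport minimum partitions per retained K (default 10).
#' @return a \linkS4class{ConsensusClustering}; run [selectK()] to cut and
#'   rank the candidates.
#' @export
consensusCluster <- function(m, kGrid = c(5, 10, 15, 20, 25, 30, 40, 50),
                             resGrid = seq(0.1, 1.9, by = 0.1),
                             nIter = 500L, subsample = 0.8, seed = 1L,
                             minSupport = 10L) {
    x <- .asCellMatrix(m)
    n <- nrow(x)
    stopifnot(length(kGrid) >= 1L, length(resGrid) >= 1L, n >= 4L)
    kGrid <- kGrid[kGrid < ceiling(subsample * n)]
    if (!length(kGrid)) stop("all kGrid values exceed the subsample size")
    nk <- length(kGrid); nr <- length(resGrid)
    co <- new.env(parent = emptyenv())   # coclust counts per K
    ns <- new.env(parent = emptyenv())   # cosample counts per K
    support <- integer(0)

    getMat <- function(env, key) {
        if (is.null(env[[key]])) env[[key]] <- matrix(0, n, n)
        env[[key]]
    }
    m0 <- ceiling(subsample * n)
    for (iter in seq_len(nIter)) {
        set.seed(seed + iter)
        idx <- sort(sample.int(n, m0))
        D <- as.matrix(stats::dist(x[idx, , drop = FALSE]))
        diag(D) <- -1
        nb <- .knnOrder(D, as.integer(max(kGrid) + 1L))
        countK <- integer(0)
        for (ki in seq_len(nk)) {
            e <- .snnEdges(nb[seq_len(kGrid[ki] + 1L), , drop = FALSE], m0)
            g <- igraph::make_graph(rbind(e$i, e$j), n = m0,
                                    directed = FALSE)
            for (ri in seq_len(nr)) {
                pseed <- seed + nIter +
                    ((iter - 1L) * nk + (ki - 1L)) * nr + ri
                ## one Leiden sweep per partition, weights passed as a plain
                ## vector: the consensus averages thousands of partitions, so
                ## extra refinement sweeps (and per-call attribute fetches)
                ## buy nothing but runtime
                set.seed(pseed)
                lab <- as.integer(igraph::membership(igraph::cluster_leiden(
                    g, objective_function = "modularity",
                    resolution = resGrid[ri], weights = e$w,
                    n_iterations = 1L)))
                K <- length(unique(lab))
                if (K < 2L) next
                key <- as.character(K)
                M <- getMat(co, key)
                for (cl in split(idx, lab)) .ccAddBlock(M, cl, 1)
                countK[key] <- if (is.na(countK[key])) 1L else
                    countK[key] + 1L
            }
        }
        for (key in names(countK)) {
            M <- getMat(ns, key)
            .ccAddBlock(M, idx, countK[[key]])
            support[key] <- if (is.na(support[key])) countK[[key]] else
                support[key] + countK[[key]]
        }
    }

    keys <- names(support)[support >= minSupport]
    keys <- keys[order(as.integer(keys))]
    consensus <- list(); nImputed <- integer(0)
    for (key in keys) {
        num <- co[[key]]; den <- ns[[key]]
        C <- matrix(0, n, n)
        defined <- den > 0
        C[defined] <- num[defined] / den[defined]
        miss <- sum(!defined)
        if (miss) {
            C[!defined] <- mean(C[defined])
            message(sprintf("K=%s: imputed %d never-co-sampled entries",
                            key, miss))
        }
        diag(C) <- 1
        C <- pmin(pmax((C + t(C)) / 2, 0), 1)
        consensus[[key]] <- C
        nImputed[key] <- miss
    }
    if (!length(consensus))
        stop("no candidate cluster number reached the support threshold")
    new("ConsensusClustering", consensus = consensus,
        support = support[keys], nImputed = nImputed,
        cuts = list(), silhouettes = numeric(0),
        ranking = data.frame(), selectedK = 0L, labels = integer(0),
        kGrid = as.numeric(kGrid), resGrid = as.numeric(resGrid),
        nIter = as.integer(nIter), subsample = subsample,
        seed = as.integer(seed))
}

#' Cut a consensus matrix into K clusters
#'
#' Agglomerative clustering with McQuitty (WPGMA) linkage on the
#' dissimilarity \code{1 - consensus}, cut into K clusters.
#'
#' @param cc a \linkS4class{ConsensusClustering} or a consensus matrix.
#' @param K the number of clusters (\code{2 <= K <= n}); when \code{cc} is a
#'   \linkS4class{ConsensusClustering}, its consensus matrix for this K is
#'   used.
#' @return integer cluster labels.
#' @export
consensusCut <- function(cc, K) {
    C <- if (is(cc, "ConsensusClustering")) {
        M <- consensusMatrix(cc, K)
        if (is.null(M)) stop("no consensus matrix for K = ", K)
        M
    } else as.matrix(cc)
    if (K > nrow(C)) stop("K exceeds the number of units")
    if (K < 2L) stop("K must be at least 2")
    hc <- stats::hclust(stats::as.dist(1 - C), method = "mcquitty")
    stats::cutree(hc, k = K)
}

#' Silhouette widths
#'
#' Per-point silhouette \code{s(i) = (b(i) - a(i)) / max(a(i), b(i))}, where
#' \code{a} is the mean distance to the point's own cluster and \code{b} the
#' smallest mean distance to another cluster. Singleton clusters get
#' \code{s = 0}, as do points with \code{a = b = 0} (coincident points).
#'
#' @param embedding numeric matrix of coordinates (e.g. PCA scores).
#' @param labels cluster labels, at least two distinct values.
#' @return list with \code{widths} (per point) and \code{mean}.
#' @export
silhouetteScore <- function(embedding, labels) {
    x <- as.matrix(embedding)
    labels <- as.integer(factor(labels))
    if (length(unique(labels)) < 2L)
        stop("silhouette requires at least two clusters")
    stopifnot(nrow(x) == length(labels))
    D <- as.matrix(stats::dist(x))
    n <- nrow(D)
    ks <- sort(unique(labels))
    ## mean distance from every point to every cluster
    sums <- vapply(ks, function(k) rowSums(D[, labels == k, drop = FALSE]),
                   numeric(n))
    sizes <- tabulate(labels)
    widths <- numeric(n)
    for (i in seq_len(n)) {
        k <- labels[i]
        if (sizes[k] == 1L) { widths[i] <- 0; next }
        a <- sums[i, k] / (sizes[k] - 1L)
        b <- min(sums[i, -k] / sizes[-k])
        widths[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }
    list(widths = widths, mean = mean(widths))
}

#' Rank candidate cluster numbers and select K
#'
#' Cuts every retained candidate K ([consensusCut()]), scores each cut by
#' mean silhouette on the supplied embedding, and selects the top-ranked K
#' unless overridden. The full ranking is kept so a run-up candidate can be
#' chosen deliberately (e.g. to expose heterogeneity beyond a dominant
#' two-group split).
#'
#' @param cc a \linkS4class{ConsensusClustering}.
#' @param embedding PCA scores of the same cells (e.g.
#'   \code{pcaEmbed(m)$scores}).
#' @param override optional K forced as the selection (must be a retained
#'   candidate).
#' @return the updated \linkS4class{ConsensusClustering} with cuts,
#'   silhouettes, ranking, \code{selectedK} and \code{labels} filled in.
#' @export
selectK <- function(cc, embedding, override = NULL) {
    stopifnot(is(cc, "ConsensusClustering"))
    keys <- names(cc@consensus)
    if (!length(keys)) stop("no candidate cluster numbers")
    cuts <- list(); sil <- numeric(0)
    for (key in keys) {
        K <- as.integer(key)
        lab <- consensusCut(cc, K)
        cuts[[key]] <- lab
        sil[key] <- silhouetteScore(embedding, lab)$mean
    }
    ord <- order(-sil)
    ranking <- data.frame(K = as.integer(keys)[ord],
                          support = as.integer(cc@support[keys][ord]),
                          mean_silhouette = as.numeric(sil[ord]))
    sel <- if (!is.null(override)) {
        if (!as.character(override) %in% keys)
            stop("override K = ", override, " is not a retained candidate")
        as.integer(override)
    } else ranking$K[1L]
    cc@cuts <- cuts
    cc@silhouettes <- sil
    cc@ranking <- ranking
    cc@selectedK <- sel
    cc@labels <- cuts[[as.character(sel)]]
    cc
}
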