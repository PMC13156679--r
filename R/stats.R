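## Hypothesis tests, the three-criterion marker-lipid caller, and qPCR ddCt.

#' Paired t test
#'
#' One-sample t test on the paired differences, two-sided. Exactly zero
#' differences return t = 0, p = 1 (no effect); zero-variance differences
#' with nonzero mean have no defined t distribution and return NA with a
#' warning.
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @return list with \code{t}, \code{df}, \code{p}.
#' @export
pairedTTest <- function(x, y) {
    stopifnot(length(x) == length(y), length(x) >= 2L)
    d <- x - y
    if (stats::sd(d) == 0) {
        if (all(d == 0)) return(list(t = 0, df = length(d) - 1L, p = 1))
        warning("zero-variance nonzero differences: p undefined")
        return(list(t = NA_real_, df = length(d) - 1L, p = NA_real_))
    }
    tt <- stats::t.test(x, y, paired = TRUE)
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value)
}

#' Two-sample t test
#'
#' Welch's t test by default (Student's pooled-variance test with
#' \code{equalVar = TRUE}). Two identical constant groups return t = 0,
#' p = 1.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param equalVar assume equal variances (default FALSE).
#' @return list with \code{t}, \code{df}, \code{p}.
#' @export
twoSampleTTest <- function(x, y, equalVar = FALSE) {
    stopifnot(length(x) >= 2L, length(y) >= 2L)
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        if (mean(x) == mean(y))
            return(list(t = 0, df = length(x) + length(y) - 2L, p = 1))
        warning("both groups constant but unequal: p undefined")
        return(list(t = NA_real_, df = length(x) + length(y) - 2L,
                    p = NA_real_))
    }
    tt <- stats::t.test(x, y, var.equal = equalVar)
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value)
}

#' Bonferroni adjustment
#'
#' @param p vector of p values in [0, 1].
#' @return \code{pmin(1, p * length(p))}, preserving NA.
#' @export
bonferroniAdjust <- function(p) {
    stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
    stats::p.adjust(p, method = "bonferroni")
}

#' Interquartile-range overlap
#'
#' TRUE iff the [Q1, Q3] intervals of the two groups intersect; quartiles by
#' linear interpolation (quantile type 7).
#'
#' @param x,y numeric vectors, each of length >= 4.
#' @return logical.
#' @export
iqrOverlap <- function(x, y) {
    stopifnot(length(x) >= 4L, length(y) >= 4L)
    qx <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
    qy <- stats::quantile(y, c(0.25, 0.75), names = FALSE, type = 7)
    max(qx[1L], qy[1L]) <= min(qx[2L], qy[2L])
}

#' Marker-lipid calling between two cell groups
#'
#' For every feature: mean intensity in each group (linear scale,
#' normalized/batch-corrected intensities), fold change A/B, Welch two-sample
#' t test with Bonferroni adjustment over the tested features, and the IQR
#' overlap flag. A feature is a marker iff all three criteria hold: fold
#' change above \code{fcHigh} or below \code{fcLow}, adjusted p below
#' \code{alpha}, and non-overlapping interquartile ranges. When a group is a
#' set of clusters its cells are pooled as single datapoints, so larger
#' clusters weigh more. A \code{strong} column additionally flags markers at
#' the stricter 0.001 level used for highlighting.
#'
#' @param m a \linkS4class{CellFeatureMatrix} (unscaled intensities are
#'   used).
#' @param labels cluster (or group) label per unit.
#' @param groupA,groupB label sets defining the comparison; cells of all
#'   listed labels are pooled per side.
#' @param alpha adjusted-p threshold (default 0.01).
#' @param fcHigh,fcLow fold-change thresholds (defaults 1.5 and 0.667).
#' @param useLog compute means and tests on log intensities instead of the
#'   linear scale (default FALSE; fold change is then back-transformed from
#'   the mean log difference).
#' @return data.frame (one row per feature): \code{feature}, \code{mean_A},
#'   \code{mean_B}, \code{fold_change}, \code{t_stat}, \code{p_raw},
#'   \code{p_adj}, \code{iqr_overlap}, \code{is_marker}, \code{direction},
#'   \code{strong}.
#' @export
findMarkers <- function(m, labels, groupA, groupB, alpha = 0.01,
                        fcHigh = 1.5, fcLow = 0.667, useLog = FALSE) {
    stopifnot(is(m, "CellFeatureMatrix"), length(labels) == ncol(m))
    if (length(intersect(groupA, groupB)))
        stop("groups must be disjoint")
    selA <- labels %in% groupA
    selB <- labels %in% groupB
    if (!any(selA) || !any(selB)) stop("empty group")
    if (sum(selA) < 4L || sum(selB) < 4L)
        stop("both groups need at least 4 cells")
    x <- assay(m, "intensities")
    xa <- x[, selA, drop = FALSE]
    xb <- x[, selB, drop = FALSE]
    if (useLog) {
        eps <- min(x[x > 0]) * 0.5
        xa <- log2(xa + eps); xb <- log2(xb + eps)
    }
    res <- lapply(seq_len(nrow(x)), function(f) {
        a <- xa[f, ]; b <- xb[f, ]
        tt <- twoSampleTTest(a, b)
        fc <- if (useLog) 2^(mean(a) - mean(b)) else mean(a) / mean(b)
        data.frame(feature = rownames(x)[f], mean_A = mean(a),
                   mean_B = mean(b), fold_change = fc, t_stat = tt$t,
                   p_raw = tt$p, iqr_overlap = iqrOverlap(a, b))
    })
    out <- do.call(rbind, res)
    out$p_adj <- bonferroniAdjust(out$p_raw)
    fcPass <- out$fold_change > fcHigh | out$fold_change < fcLow
    out$is_marker <- fcPass & !is.na(out$p_adj) & out$p_adj < alpha &
        !out$iqr_overlap
    out$direction <- ifelse(out$fold_change > 1, "up", "down")
    out$direction[!out$is_marker] <- NA_character_
    out$strong <- out$is_marker & out$p_adj < 0.001
    out[, c("feature", "mean_A", "mean_B", "fold_change", "t_stat",
            "p_raw", "p_adj", "iqr_overlap", "is_marker", "direction",
            "strong")]
}

#' Relative expression by the delta-delta-Ct method
#'
#' Per sample, \code{dCt = Ct(target) - Ct(reference)}; per target gene and
#' treatment group, \code{ddCt = mean dCt(group) - mean dCt(control)} and
#' fold change \code{2^-ddCt}. Each group is compared to the control by a
#' two-sample t test on the dCt values, Bonferroni-adjusted across the
#' non-control groups of that gene. Samples missing the reference gene are
#' dropped with a warning.
#'
#' @param ct data.frame with columns \code{gene}, \code{sample},
#'   \code{group}, \code{ct}.
#' @param referenceGene name of the reference (housekeeping) gene.
#' @param controlGroup name of the control group.
#' @return data.frame with one row per (gene, group): \code{gene},
#'   \code{group}, \code{ddct}, \code{fold_change}, \code{t}, \code{p_raw},
#'   \code{p_adj} (control rows carry fold change 1 and NA tests).
#' @export
ddctFoldChange <- function(ct, referenceGene, controlGroup) {
    stopifnot(all(c("gene", "sample", "group", "ct") %in% colnames(ct)))
    ref <- ct[ct$gene == referenceGene, ]
    if (!nrow(ref)) stop("reference gene not found")
    refCt <- stats::setNames(ref$ct, ref$sample)
    targets <- setdiff(unique(ct$gene), referenceGene)
    keep <- ct$sample %in% names(refCt)[!is.na(refCt)]
    if (!all(keep)) {
        warning("dropping ", sum(!keep), " row(s) without a reference Ct")
        ct <- ct[keep, ]
    }
    out <- list()
    for (g in targets) {
        sub <- ct[ct$gene == g, ]
        dct <- sub$ct - refCt[sub$sample]
        groups <- split(dct, sub$group)
        if (!controlGroup %in% names(groups))
            stop("control group absent for gene ", g)
        ctrl <- groups[[controlGroup]]
        others <- setdiff(names(groups), controlGroup)
        rows <- data.frame(gene = g, group = c(controlGroup, others),
                           ddct = NA_real_, fold_change = NA_real_,
                           t = NA_real_, p_raw = NA_real_, p_adj = NA_real_)
        rows$ddct[1L] <- 0; rows$fold_change[1L] <- 1
        praw <- numeric(length(others))
        for (i in seq_along(others)) {
            gi <- groups[[others[i]]]
            dd <- mean(gi) - mean(ctrl)
            rows$ddct[i + 1L] <- dd
            rows$fold_change[i + 1L] <- 2^(-dd)
            if (length(gi) >= 2L && length(ctrl) >= 2L) {
                tt <- twoSampleTTest(gi, ctrl)
                rows$t[i + 1L] <- tt$t
                praw[i] <- tt$p
            } else praw[i] <- NA_real_
        }
        rows$p_raw[-1L] <- praw
        rows$p_adj[-1L] <- bonferroniAdjust(praw)
        out[[g]] <- rows
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
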