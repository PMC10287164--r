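## Gene grouping and mechanistic diagnosis: up/down calls, decapping
## activator dependence, decay- vs transcription-driven labels, TE deciles,
## notched-box group summaries, and hierarchical clustering of fold-change
## patterns.

#' Call up/down groups from a differential result
#'
#' UP requires `log2fc > log2(fcThreshold)` with `padj < fdr`; DN is the
#' mirror image; everything else (including low-count flagged genes, which
#' carry an NA reason) is NONE.
#'
#' @param diff a result from [nbDiff()] or [deltaTETest()]
#' @param fcThreshold fold-change threshold (default 1.4)
#' @param fdr adjusted-p threshold (default 0.1; 0.01 is the convention for
#'   spike-in normalized absolute comparisons)
#' @return data.frame with `gene_id`, `group` (`UP`/`DN`/`NONE`) and
#'   `reason` (NA, or why the gene was not callable)
#' @export
callGroups <- function(diff, fcThreshold = 1.4, fdr = 0.1) {
    lfcCut <- log2(fcThreshold)
    group <- rep("NONE", nrow(diff))
    reason <- rep(NA_character_, nrow(diff))
    callable <- !diff$low_count_flag & !is.na(diff$padj)
    group[callable & diff$log2fc > lfcCut & diff$padj < fdr] <- "UP"
    group[callable & diff$log2fc < -lfcCut & diff$padj < fdr] <- "DN"
    reason[diff$low_count_flag] <- "low_count"
    reason[!diff$low_count_flag & is.na(diff$padj)] <- "not_tested"
    data.frame(gene_id = diff$gene_id, group = group, reason = reason,
               stringsAsFactors = FALSE)
}

#' Call decapping-activator dependence for derepressed genes
#'
#' For genes up-regulated in the decapping-null comparison, dependence on
#' the activator (e.g. Dhh1) is called from the activator-null comparison:
#' `DHH1_DEP` when the activator-null fold change is at least
#' `fcThreshold` with `padj < fdr` (the gene is derepressed without the
#' activator, so the activator is required for its repression in wild
#' type); `DHH1_INDEP` otherwise.  Genes missing from a comparison are NA.
#' An epistasis consistency flag marks genes whose double-mutant fold
#' change differs from the decapping-null fold change by more than
#' `fcThreshold`-fold, which under the one-pathway model should not occur.
#'
#' @param upGenes character vector of gene ids in the UP set of the
#'   decapping-null comparison
#' @param diffDcp2,diffDhh1,diffDouble [nbDiff()] results for the
#'   decapping-null, activator-null and double-mutant comparisons vs wild
#'   type
#' @param fcThreshold,fdr thresholds as in [callGroups()]
#' @return data.frame with `gene_id`, `dependence` (`DHH1_DEP`,
#'   `DHH1_INDEP`, or NA) and `epistasis_consistent`
#' @export
callDependence <- function(upGenes, diffDcp2, diffDhh1, diffDouble,
                           fcThreshold = 1.4, fdr = 0.1) {
    lfcCut <- log2(fcThreshold)
    idx <- function(d) match(upGenes, d$gene_id)
    i1 <- idx(diffDcp2); i2 <- idx(diffDhh1); i3 <- idx(diffDouble)
    dep <- rep(NA_character_, length(upGenes))
    consistent <- rep(NA, length(upGenes))
    ok <- !is.na(i2) & !is.na(diffDhh1$padj[i2])
    dep[ok] <- ifelse(diffDhh1$log2fc[i2[ok]] >= lfcCut &
                      diffDhh1$padj[i2[ok]] < fdr,
                      "DHH1_DEP", "DHH1_INDEP")
    both <- !is.na(i1) & !is.na(i3) &
        !is.na(diffDcp2$log2fc[i1]) & !is.na(diffDouble$log2fc[i3])
    consistent[both] <- abs(diffDouble$log2fc[i3[both]] -
                            diffDcp2$log2fc[i1[both]]) <= lfcCut
    data.frame(gene_id = upGenes, dependence = dep,
               epistasis_consistent = consistent, stringsAsFactors = FALSE)
}

#' Diagnose decay-driven vs transcription-driven derepression
#'
#' For genes up-regulated in the decapping-null mutant, combines the
#' capped-fraction diagnostic with absolute Pol II occupancy: `DECAY` when
#' the gene's C/T increase exceeds the all-gene median change and its
#' spike-normalized Rpb1 change is non-positive (log2); `TXN` when Rpb1
#' rises more than `rpb1Threshold`-fold regardless of C/T; `AMBIGUOUS`
#' otherwise; NA when a modality is missing.  Also reports the per-gene
#' comparison of the CAGE TPM ratio vs the RNA TPM ratio (decay predicts
#' the former exceeds the latter).
#'
#' @param upGenes character vector of up-regulated gene ids
#' @param deltaCt named per-gene log2 change in C/T (mutant vs wild type),
#'   for at least all genes so the population median is meaningful
#' @param deltaRpb1 named per-gene log2 change in spike-normalized Rpb1
#'   occupancy
#' @param deltaCage,deltaRna optional named per-gene log2 TPM ratios
#'   (mutant/WT) from CAGE and RNA, for the ratio comparison
#' @param rpb1Threshold fold threshold on the Rpb1 increase for TXN
#' @return data.frame with `gene_id`, `mechanism`, `delta_ct`,
#'   `delta_rpb1`, and `cage_exceeds_rna` (NA when not supplied)
#' @export
diagnoseMechanism <- function(upGenes, deltaCt, deltaRpb1,
                              deltaCage = NULL, deltaRna = NULL,
                              rpb1Threshold = 1.4) {
    ctMedian <- stats::median(deltaCt, na.rm = TRUE)
    ct <- deltaCt[upGenes]; rpb1 <- deltaRpb1[upGenes]
    mech <- rep("AMBIGUOUS", length(upGenes))
    mech[!is.na(rpb1) & rpb1 > log2(rpb1Threshold)] <- "TXN"
    decay <- !is.na(ct) & !is.na(rpb1) & ct > ctMedian & rpb1 <= 0
    mech[decay & mech != "TXN"] <- "DECAY"
    mech[is.na(ct) | is.na(rpb1)] <- NA_character_
    cmp <- rep(NA, length(upGenes))
    if (!is.null(deltaCage) && !is.null(deltaRna))
        cmp <- deltaCage[upGenes] > deltaRna[upGenes]
    data.frame(gene_id = upGenes, mechanism = mech,
               delta_ct = unname(ct), delta_rpb1 = unname(rpb1),
               cage_exceeds_rna = unname(cmp), stringsAsFactors = FALSE)
}

#' Median TE change across deciles of wild-type TE
#'
#' Genes are ranked by wild-type TE from highest to lowest (ties broken by
#' gene id), split into ten equal-size bins, and the median log2 TE change
#' is reported per bin.  Under limiting-PIC competition the medians fall
#' from the high-TE to the low-TE bins.
#'
#' @param wtTe named per-gene TE in wild type
#' @param deltaTe named per-gene log2 TE change (same genes)
#' @return data.frame with `decile` (1 = highest TE), `n`,
#'   `median_delta_te`
#' @export
teDeciles <- function(wtTe, deltaTe) {
    keep <- !is.na(wtTe) & !is.na(deltaTe)
    wtTe <- wtTe[keep]; deltaTe <- deltaTe[keep]
    if (length(wtTe) < 10) stop("at least 10 genes required for deciles")
    ord <- order(-wtTe, names(wtTe))
    bin <- ceiling(seq_along(ord) / (length(ord) / 10))
    bin <- pmin(bin, 10L)
    med <- tapply(deltaTe[ord], bin, stats::median)
    data.frame(decile = as.integer(names(med)),
               n = as.integer(table(bin)),
               median_delta_te = as.numeric(med))
}

#' Notched-box group summaries with Mann-Whitney comparisons
#'
#' For each group: median, quartiles, and the 95% notch half-width
#' `1.58 * IQR / sqrt(n)` (suppressed for groups smaller than 3), plus a
#' two-sided Mann-Whitney U p-value against the reference group.
#' Non-overlapping notches indicate medians that differ with roughly 95%
#' confidence.
#'
#' @param values numeric vector
#' @param groups factor/character of the same length
#' @param reference name of the reference group (default: first level,
#'   conventionally the all-genes set)
#' @return data.frame with `group`, `n`, `median`, `q1`, `q3`, `notch`,
#'   `p_vs_reference`
#' @export
groupSummary <- function(values, groups, reference = NULL) {
    groups <- factor(groups)
    if (nlevels(groups) < 2) stop("at least two groups required")
    if (is.null(reference)) reference <- levels(groups)[1]
    if (!reference %in% levels(groups)) stop("unknown reference group")
    refVals <- values[groups == reference]
    rows <- lapply(levels(groups), function(g) {
        x <- values[groups == g]
        x <- x[!is.na(x)]
        n <- length(x)
        q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
        notch <- if (n >= 3) 1.58 * (q[3] - q[1]) / sqrt(n) else NA_real_
        p <- if (g == reference) NA_real_ else
            suppressWarnings(stats::wilcox.test(x, refVals)$p.value)
        data.frame(group = g, n = n, median = q[2], q1 = q[1], q3 = q[3],
                   notch = notch, p_vs_reference = p)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Hierarchical clustering of fold-change patterns
#'
#' Complete-linkage agglomeration on Euclidean distances between per-gene
#' fold-change vectors, as used for mutant-pattern heatmaps.  Rows with any
#' |log2 fold change| beyond `exclude` are dropped first (set `exclude =
#' Inf` to keep everything); non-finite entries are an error unless
#' exclusion removes them.
#'
#' @param mat genes x comparisons matrix of log2 fold changes
#' @param exclude drop rows with any |value| above this (default 4)
#' @return list with `hclust` (the tree), `order` (leaf order as row
#'   names), `excluded` (dropped row names)
#' @export
hclusterFoldChanges <- function(mat, exclude = 4) {
    mat <- as.matrix(mat)
    if (is.null(rownames(mat))) rownames(mat) <- sprintf("g%d", seq_len(nrow(mat)))
    badRow <- apply(!is.finite(mat), 1, any)
    overRow <- apply(mat, 1, function(r) any(abs(r) > exclude | !is.finite(r)))
    drop <- if (is.finite(exclude)) overRow else rep(FALSE, nrow(mat))
    if (any(badRow & !drop))
        stop("non-finite fold changes present; enable exclusion or clean input")
    kept <- mat[!drop, , drop = FALSE]
    if (nrow(kept) < 2) stop("fewer than 2 rows to cluster")
    hc <- stats::hclust(stats::dist(kept, method = "euclidean"),
                        method = "complete")
    list(hclust = hc, order = rownames(kept)[hc$order],
         excluded = rownames(mat)[drop])
}
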