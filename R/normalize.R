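## Size factors: median-of-ratios (relative), ERCC spike-in (absolute),
## and foreign-genome ChIP spike-in scaling.

#' Median-of-ratios size factors
#'
#' The classical library-depth estimator: for each sample, the median over
#' genes (with nonzero counts in every sample) of the ratio of the gene's
#' count to its geometric mean across samples.  Factors are rescaled to
#' geometric mean 1, so relative fold changes are centred: after
#' normalization the median change across a mostly-unchanged transcriptome
#' is 1 (log2 = 0).
#'
#' @param counts genes x samples matrix
#' @return list with `factors` (named, > 0, geometric mean 1) and
#'   `method = "MOR"`
#' @examples
#' m <- cbind(a = c(10, 20), b = c(20, 40))
#' sizeFactorsMOR(m)$factors   # b is sequenced twice as deep
#' @export
sizeFactorsMOR <- function(counts) {
    counts <- as.matrix(counts)
    allPos <- rowSums(counts > 0) == ncol(counts)
    if (!any(allPos))
        stop("no gene has nonzero counts in all samples; ",
             "consider a pseudo-reference")
    logGeo <- rowMeans(log(counts[allPos, , drop = FALSE]))
    f <- apply(counts[allPos, , drop = FALSE], 2, function(x)
        exp(stats::median(log(x) - logGeo)))
    f <- f / exp(mean(log(f)))
    list(factors = f, method = "MOR")
}

#' ERCC spike-in size factors (absolute scaling)
#'
#' Computes median-of-ratios factors over the equal-concentration spike
#' subgroup only (subgroup B of the bundled definition) and returns them
#' for application to the biological genes.  Because the spikes were added
#' as a fixed aliquot per library, normalizing to them preserves absolute
#' abundance differences between strains that depth normalization would
#' erase; downstream testing on spike-normalized counts then uses unit size
#' factors.  A `"total"` method (ratio of total subgroup-B reads) is
#' available as an alternative.
#'
#' @param spikeCounts spike x sample count matrix (rownames = spike ids)
#' @param definition spike definition table, see [erccDefinition()]
#' @param subgroup subgroup whose members are in equal concentration in
#'   both mixes
#' @param method `"MOR"` (default) or `"total"`
#' @return list with `factors` (named) and `method = "ERCC"`
#' @export
sizeFactorsERCC <- function(spikeCounts, definition = erccDefinition(),
                            subgroup = "B", method = c("MOR", "total")) {
    method <- match.arg(method)
    spikeCounts <- as.matrix(spikeCounts)
    ids <- definition$spike_id[definition$subgroup == subgroup]
    sub <- spikeCounts[rownames(spikeCounts) %in% ids, , drop = FALSE]
    if (nrow(sub) == 0) stop("no subgroup-", subgroup, " spikes in counts")
    if (any(colSums(sub) == 0))
        stop("a library has zero subgroup-", subgroup, " spike counts")
    if (method == "MOR") {
        f <- sizeFactorsMOR(sub)$factors
    } else {
        tot <- colSums(sub)
        f <- tot / exp(mean(log(tot)))
    }
    list(factors = f, method = "ERCC")
}

#' Foreign-genome ChIP spike-in normalization factors
#'
#' Each sample's factor is the average number of total foreign-genome
#' (e.g. S. pombe) reads across all samples divided by that sample's
#' foreign-genome total; multiplying a sample's host-genome reads by its
#' factor yields spike-normalized occupancies.  The factors conserve the
#' spike average: `mean(factors * totals) = mean(totals)`.
#'
#' @param spikeTotals named per-sample totals of foreign-genome reads
#' @return list with `factors` (named) and `method = "POMBE"`
#' @examples
#' sizeFactorsPombe(c(a = 10e6, b = 20e6, c = 30e6))$factors
#' @export
sizeFactorsPombe <- function(spikeTotals) {
    if (any(spikeTotals <= 0)) stop("spike totals must be > 0")
    list(factors = mean(spikeTotals) / spikeTotals, method = "POMBE")
}

#' Apply normalization factors to counts
#'
#' For MOR/ERCC factors, counts are divided by the per-sample factor; for
#' ChIP spike-in factors, counts are multiplied (the factor is already the
#' scaling to apply).
#'
#' @param counts genes x samples matrix
#' @param sf a size-factor list from one of the `sizeFactors*` functions
#' @return normalized (non-integer) matrix
#' @export
normalizeCounts <- function(counts, sf) {
    f <- sf$factors
    if (length(f) != ncol(counts)) stop("one factor per sample required")
    if (identical(sf$method, "POMBE")) sweep(counts, 2, f, "*")
    else sweep(counts, 2, f, "/")
}
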