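## Expression units: TPM, RPKM, translational efficiency, and the
## capped-to-total (C/T) ratio.

#' Transcripts per million
#'
#' `RPK_i = count_i / (length_i/1000)`; TPM rescales RPK so each sample
#' sums to one million.  CAGE tag tables use unit lengths (one tag per
#' transcript 5' end), making CAGE tags-per-million directly comparable to
#' RNA-Seq TPM.
#'
#' @param counts numeric vector or genes x samples matrix of counts
#' @param lengths per-gene lengths in bp, or `NULL` for unit lengths
#'   (CAGE tags)
#' @return TPM values with the shape of `counts`
#' @examples
#' tpm(c(10, 40), c(1000, 2000))   # 333333.3, 666666.7
#' @export
tpm <- function(counts, lengths = NULL) {
    m <- as.matrix(counts)
    if (any(m < 0)) stop("counts must be >= 0")
    if (is.null(lengths)) lengths <- rep(1000, nrow(m))
    if (any(lengths <= 0)) stop("lengths must be > 0")
    if (length(lengths) != nrow(m)) stop("one length per gene required")
    rpk <- m / (lengths / 1000)
    tot <- colSums(rpk)
    if (any(tot == 0)) stop("all-zero sample: TPM undefined")
    out <- sweep(rpk, 2, tot, "/") * 1e6
    if (is.null(dim(counts))) out[, 1] else out
}

#' Reads per kilobase per million mapped reads
#'
#' @inheritParams tpm
#' @return RPKM values with the shape of `counts`
#' @export
rpkm <- function(counts, lengths) {
    m <- as.matrix(counts)
    if (any(m < 0)) stop("counts must be >= 0")
    if (any(lengths <= 0)) stop("lengths must be > 0")
    depth <- colSums(m)
    if (any(depth == 0)) stop("all-zero sample: RPKM undefined")
    out <- sweep(m / (lengths / 1000), 2, depth / 1e6, "/")
    if (is.null(dim(counts))) out[, 1] else out
}

#' Merge replicate columns by summing raw counts
#'
#' Replicates of a genotype are merged as a single sample by summing raw
#' counts before any normalization, matching how merged CAGE samples are
#' quantified.
#'
#' @param counts genes x samples matrix
#' @param groups factor/character of length `ncol(counts)`
#' @return genes x groups matrix
#' @export
mergeReplicates <- function(counts, groups) {
    groups <- as.character(groups)
    out <- vapply(unique(groups), function(g)
        rowSums(counts[, groups == g, drop = FALSE]),
        numeric(nrow(counts)))
    rownames(out) <- rownames(counts)
    out
}

#' Capped-to-total ratio (C/T)
#'
#' Divides CAGE TPM by RNA-Seq TPM per gene and strain.  Following the
#' zero policy of the C/T framework, genes with zero CAGE reads in either
#' of the two strains being compared are removed before any ratio is
#' computed; genes whose RNA TPM is zero while CAGE TPM is positive are
#' flagged and excluded.  Because each assay is normalized to its own
#' library, the ratios are relative (comparable across genes and strains)
#' rather than absolute capped proportions.
#'
#' @param cageTpm,rnaTpm genes x 2 matrices (columns = the two strains
#'   being compared, same order) of CAGE and RNA TPMs; rownames are gene ids
#' @param cageCounts optional raw CAGE counts (same shape) used for the
#'   zero-read removal rule; defaults to `cageTpm`
#' @return data.frame with per-strain `ct` columns, `log2_delta_ct`
#'   (strain2 vs strain1) and a `flag` column (`"ok"`, `"zero_cage"`,
#'   `"zero_rna"`); excluded genes keep their row with NA ratios
#' @examples
#' cage <- rbind(g1 = c(200, 300), g2 = c(0, 5))
#' rna  <- rbind(g1 = c(400, 300), g2 = c(10, 10))
#' ctRatio(cage, rna)   # g2 removed: zero CAGE in strain 1
#' @export
ctRatio <- function(cageTpm, rnaTpm, cageCounts = cageTpm) {
    cageTpm <- as.matrix(cageTpm); rnaTpm <- as.matrix(rnaTpm)
    if (!identical(rownames(cageTpm), rownames(rnaTpm)))
        stop("cageTpm and rnaTpm must be indexed by the same gene set")
    if (ncol(cageTpm) != 2 || ncol(rnaTpm) != 2)
        stop("C/T compares exactly two strains")
    flag <- rep("ok", nrow(cageTpm))
    flag[apply(as.matrix(cageCounts) == 0, 1, any)] <- "zero_cage"
    flag[flag == "ok" &
         apply(rnaTpm == 0 & cageTpm > 0, 1, any)] <- "zero_rna"
    ct <- cageTpm / rnaTpm
    ct[flag != "ok", ] <- NA_real_
    strains <- colnames(cageTpm)
    if (is.null(strains)) strains <- c("1", "2")
    out <- data.frame(ct1 = ct[, 1], ct2 = ct[, 2],
                      log2_delta_ct = log2(ct[, 2] / ct[, 1]),
                      flag = flag, row.names = rownames(cageTpm))
    colnames(out)[1:2] <- paste0("ct_", strains)
    out
}

#' Translational efficiency
#'
#' TE is the ratio of ribosome-footprint density to mRNA density:
#' `TE = RPF RPKM / mRNA RPKM`, computed on replicate-merged counts per
#' genotype.  Genes with zero mRNA RPKM are flagged undefined (NA), never
#' zero.
#'
#' @param rpfRpkm,mrnaRpkm per-gene RPKM vectors (replicate-merged,
#'   one genotype)
#' @return numeric vector of TEs with NA where undefined
#' @examples
#' teTable(c(20, 4), c(10, 0))   # 2, NA
#' @export
teTable <- function(rpfRpkm, mrnaRpkm) {
    if (any(rpfRpkm < 0, na.rm = TRUE) || any(mrnaRpkm < 0, na.rm = TRUE))
        stop("RPKM inputs must be >= 0")
    ifelse(is.na(mrnaRpkm) | mrnaRpkm == 0, NA_real_, rpfRpkm / mrnaRpkm)
}

#' log2 change in translational efficiency between genotypes
#'
#' @param teMut,teWt per-gene TEs from [teTable()]
#' @param pseudocount added to both TEs before the log ratio; the default 0
#'   keeps the estimate unbiased, a small value (e.g. 0.5 on the RPKM
#'   scale) is useful for display only
#' @return per-gene `log2(TE_mut) - log2(TE_wt)`; NA where either TE is
#'   undefined or zero (unless a pseudocount is used)
#' @export
deltaTE <- function(teMut, teWt, pseudocount = 0) {
    out <- log2(teMut + pseudocount) - log2(teWt + pseudocount)
    out[!is.finite(out)] <- NA_real_
    out
}
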