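## CAGE TSS clustering: per-base tag records -> TSS clusters (putative core
## promoters) -> consensus clusters across samples -> gene-level CAGE TPM.
##
## Coordinates are 1-based inclusive throughout; BED output is 0-based
## half-open (see writeClustersBED).

.checkCTSS <- function(records) {
    need <- c("chrom", "pos", "strand", "count")
    if (!all(need %in% names(records)))
        stop("CTSS records need columns: ", paste(need, collapse = ", "))
    if (any(records$pos < 1)) stop("CTSS positions are 1-based (pos >= 1)")
    if (any(records$count < 0)) stop("CTSS counts must be >= 0")
    if (!all(records$strand %in% c("+", "-")))
        stop("strand must be '+' or '-'")
    invisible(records)
}

#' Tags-per-million for CTSS records
#'
#' Adds (or recomputes) the `tpm` column: tags supporting each TSS per
#' million mapped tags in the sample.
#'
#' @param records CTSS data.frame (`chrom`, `pos`, `strand`, `count`)
#' @return the records with a `tpm` column
#' @export
ctssTpm <- function(records) {
    .checkCTSS(records)
    tot <- sum(records$count)
    if (tot == 0) stop("no tags in sample: TPM undefined")
    records$tpm <- records$count / tot * 1e6
    records
}

#' Filter TSSs by minimum TPM
#'
#' Only TSSs supported by at least `minTpm` tags per million (inclusive,
#' default 0.1) are used to infer TSS clusters.
#'
#' @param records CTSS records with a `tpm` column (see [ctssTpm()])
#' @param minTpm inclusive threshold
#' @return the retained records
#' @export
filterTSS <- function(records, minTpm = 0.1) {
    if (is.null(records$tpm)) stop("records carry no tpm column; run ctssTpm()")
    records[records$tpm >= minTpm, , drop = FALSE]
}

#' Peak-based TSS clustering
#'
#' Groups TSSs into clusters around local signal peaks, independently per
#' chromosome and strand:
#'
#' 1. the unassigned TSS with the highest TPM becomes a peak (ties: the
#'    leftmost);
#' 2. all unassigned TSSs within `peakDistance` bp of the peak join its
#'    cluster;
#' 3. members with TPM below `localThreshold` times the peak TPM are
#'    dropped, unless they lie within `extensionDistance` bp of the peak
#'    (set `extensionExempt = FALSE` to apply the local filter to every
#'    member regardless of distance);
#' 4. repeat until every TSS is assigned or dropped;
#' 5. cluster bounds are the min/max positions of retained members.
#'
#' The procedure is deterministic; dropped TSSs are discarded, not
#' reassigned.
#'
#' @param records CTSS records with `tpm`, sorted by (chrom, strand, pos)
#' @param peakDistance bp window around a peak that recruits members
#' @param extensionDistance bp window exempt from the local filter
#' @param localThreshold fraction of the peak TPM below which distant
#'   members are dropped
#' @param extensionExempt see step 3
#' @return data.frame of clusters: `chrom`, `strand`, `start`, `end`
#'   (1-based inclusive), `dominant_pos`, `tpm_sum`, `member_count`
#' @examples
#' r <- ctssTpm(data.frame(chrom = "chrI", pos = c(100, 130, 180),
#'                         strand = "+", count = c(10, 5, 3)))
#' peakCluster(r)
#' @export
peakCluster <- function(records, peakDistance = 50, extensionDistance = 25,
                        localThreshold = 0.01, extensionExempt = TRUE) {
    .checkCTSS(records)
    if (is.null(records$tpm)) stop("records carry no tpm column; run ctssTpm()")
    if (nrow(records) == 0)
        return(data.frame(chrom = character(), strand = character(),
                          start = integer(), end = integer(),
                          dominant_pos = integer(), tpm_sum = numeric(),
                          member_count = integer()))
    key <- order(records$chrom, records$strand, records$pos)
    if (!identical(key, seq_len(nrow(records))))
        stop("records must be sorted by (chrom, strand, pos)")
    out <- list()
    for (grp in split(records, list(records$chrom, records$strand),
                      drop = TRUE)) {
        pos <- grp$pos; tv <- grp$tpm
        state <- integer(length(pos))          # 0 open, -1 dropped, >0 cluster
        cid <- 0L
        repeat {
            open <- which(state == 0L)
            if (!length(open)) break
            peak <- open[order(-tv[open], pos[open])][1]
            members <- open[abs(pos[open] - pos[peak]) <= peakDistance]
            low <- tv[members] < localThreshold * tv[peak]
            if (extensionExempt)
                low <- low & abs(pos[members] - pos[peak]) > extensionDistance
            retained <- members[!low]
            cid <- cid + 1L
            state[members[low]] <- -1L
            state[retained] <- cid
            out[[length(out) + 1L]] <- data.frame(
                chrom = grp$chrom[1], strand = grp$strand[1],
                start = min(pos[retained]), end = max(pos[retained]),
                dominant_pos = pos[peak], tpm_sum = sum(tv[retained]),
                member_count = length(retained))
        }
    }
    out <- do.call(rbind, out)
    out <- out[order(out$chrom, out$strand, out$start), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Consensus clusters across samples
#'
#' Same-strand clusters from any number of samples whose spans are
#' separated by at most `dis` bp are merged transitively into consensus
#' clusters.  When the per-sample CTSS records are supplied, the TPM of a
#' consensus cluster in a sample is the sum of TPM values of all TSSs
#' within its range, and the dominant position is the position with the
#' highest pooled TPM.
#'
#' @param clusterList list of per-sample cluster tables from
#'   [peakCluster()] (one sample is fine)
#' @param dis maximum gap (bp) between merged spans
#' @param ctssList optional named list of CTSS records (with `tpm`)
#'   parallel to `clusterList`, used for per-sample quantification
#' @return data.frame of consensus clusters with `chrom`, `strand`,
#'   `start`, `end`, `dominant_pos`, `tpm_sum`, and one `tpm.<sample>`
#'   column per sample when `ctssList` is given
#' @export
consensusClusters <- function(clusterList, dis = 100, ctssList = NULL) {
    if (is.data.frame(clusterList)) clusterList <- list(clusterList)
    all <- do.call(rbind, clusterList)
    if (is.null(all) || nrow(all) == 0)
        stop("no clusters supplied")
    gr <- GenomicRanges::GRanges(all$chrom,
                                 IRanges::IRanges(all$start, all$end),
                                 strand = all$strand)
    cons <- GenomicRanges::reduce(gr, min.gapwidth = dis + 1L)
    out <- data.frame(chrom = as.character(GenomicRanges::seqnames(cons)),
                      strand = as.character(GenomicRanges::strand(cons)),
                      start = GenomicRanges::start(cons),
                      end = GenomicRanges::end(cons))
    ## dominant position and tpm: from pooled CTSS when available, else
    ## from the member cluster with the largest tpm_sum
    hit <- GenomicRanges::findOverlaps(gr, cons)
    memberOf <- integer(nrow(all))
    memberOf[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)
    if (is.null(ctssList)) {
        out$dominant_pos <- NA_integer_
        out$tpm_sum <- 0
        for (k in seq_len(nrow(out))) {
            mem <- all[memberOf == k, , drop = FALSE]
            out$dominant_pos[k] <- mem$dominant_pos[which.max(mem$tpm_sum)]
            out$tpm_sum[k] <- sum(mem$tpm_sum)
        }
    } else {
        pool <- do.call(rbind, lapply(ctssList, function(x)
            x[c("chrom", "pos", "strand", "tpm")]))
        pool <- stats::aggregate(tpm ~ chrom + pos + strand, pool, sum)
        pgr <- GenomicRanges::GRanges(pool$chrom,
                                      IRanges::IRanges(pool$pos, pool$pos),
                                      strand = pool$strand)
        ph <- GenomicRanges::findOverlaps(pgr, cons)
        out$dominant_pos <- NA_integer_
        dom <- tapply(S4Vectors::queryHits(ph), S4Vectors::subjectHits(ph),
            function(q) pool$pos[q[order(-pool$tpm[q], pool$pos[q])][1]])
        out$dominant_pos[as.integer(names(dom))] <- as.integer(dom)
        for (nm in names(ctssList)) {
            x <- ctssList[[nm]]
            xgr <- GenomicRanges::GRanges(x$chrom,
                                          IRanges::IRanges(x$pos, x$pos),
                                          strand = x$strand)
            xh <- GenomicRanges::findOverlaps(xgr, cons)
            v <- numeric(nrow(out))
            sums <- tapply(x$tpm[S4Vectors::queryHits(xh)],
                           S4Vectors::subjectHits(xh), sum)
            v[as.integer(names(sums))] <- sums
            out[[paste0("tpm.", nm)]] <- v
        }
        out$tpm_sum <- rowSums(out[, grep("^tpm\\.", names(out)),
                                   drop = FALSE])
    }
    out[order(out$chrom, out$strand, out$start), , drop = FALSE]
}

#' Assign consensus clusters to downstream genes
#'
#' A cluster is assigned to a gene when its dominant position lies within
#' `upstream` bp upstream and `downstream` bp downstream of the gene's
#' start codon, on the same strand (`[start_codon - 1000, start_codon +
#' 50]` on the plus strand by default, mirrored on minus).  A cluster
#' matching several genes goes to the gene with the nearest start codon;
#' exact ties go to the gene the cluster is upstream of.  A gene's CAGE
#' TPM is the sum over all clusters assigned to it.
#'
#' @param consensus consensus cluster table from [consensusClusters()]
#' @param geneModels `GRanges` with `gene_id` and `start_codon` metadata
#'   columns (see [geneModels()])
#' @param upstream,downstream assignment window around the start codon
#' @return list with `assignments` (cluster index, gene_id, distance) and
#'   `geneTpm` (genes x samples matrix of summed cluster TPMs; a single
#'   `tpm_sum` column if the consensus table has no per-sample columns)
#' @export
assignClustersToGenes <- function(consensus, geneModels,
                                  upstream = 1000, downstream = 50) {
    sc <- geneModels$start_codon
    if (is.null(sc)) stop("geneModels must carry a start_codon column")
    gstrand <- as.character(GenomicRanges::strand(geneModels))
    winStart <- ifelse(gstrand == "+", sc - upstream, sc - downstream)
    winEnd <- ifelse(gstrand == "+", sc + downstream, sc + upstream)
    win <- GenomicRanges::GRanges(GenomicRanges::seqnames(geneModels),
                                  IRanges::IRanges(winStart, winEnd),
                                  strand = gstrand)
    dom <- GenomicRanges::GRanges(consensus$chrom,
                                  IRanges::IRanges(consensus$dominant_pos,
                                                   consensus$dominant_pos),
                                  strand = consensus$strand)
    hit <- GenomicRanges::findOverlaps(dom, win)
    q <- S4Vectors::queryHits(hit); s <- S4Vectors::subjectHits(hit)
    dist <- abs(consensus$dominant_pos[q] - sc[s])
    ## cluster is upstream of the gene when the start codon lies downstream
    ## of the dominant position in the direction of transcription
    isUp <- ifelse(gstrand[s] == "+",
                   sc[s] >= consensus$dominant_pos[q],
                   sc[s] <= consensus$dominant_pos[q])
    keep <- unlist(lapply(split(seq_along(q), q), function(ii) {
        ii[order(dist[ii], !isUp[ii])][1]
    }), use.names = FALSE)
    assignments <- data.frame(cluster = q[keep],
                              gene_id = geneModels$gene_id[s[keep]],
                              distance = dist[keep])
    tpmCols <- grep("^tpm\\.", names(consensus), value = TRUE)
    if (!length(tpmCols)) tpmCols <- "tpm_sum"
    geneTpm <- matrix(0, length(geneModels), length(tpmCols),
                      dimnames = list(geneModels$gene_id,
                                      sub("^tpm\\.", "", tpmCols)))
    for (r in seq_len(nrow(assignments))) {
        gi <- assignments$gene_id[r]
        geneTpm[gi, ] <- geneTpm[gi, ] +
            unlist(consensus[assignments$cluster[r], tpmCols])
    }
    list(assignments = assignments, geneTpm = geneTpm)
}

#' Gene-level CAGE TPM from raw CTSS tables
#'
#' Convenience wrapper running the full promoter pipeline: per-sample TPM,
#' TSS filtering, peak clustering, consensus clustering across the
#' supplied samples, and gene assignment.
#'
#' @param ctssList named list of CTSS data.frames (replicates already
#'   merged per strain if desired)
#' @param geneModels `GRanges` with `gene_id` and `start_codon`
#' @param minTpm,peakDistance,extensionDistance,localThreshold,dis,upstream,downstream
#'   pipeline parameters, see the individual steps
#' @return genes x samples matrix of CAGE TPM
#' @export
cageGeneTpm <- function(ctssList, geneModels, minTpm = 0.1,
                        peakDistance = 50, extensionDistance = 25,
                        localThreshold = 0.01, dis = 100,
                        upstream = 1000, downstream = 50) {
    withTpm <- lapply(ctssList, function(x) filterTSS(ctssTpm(x), minTpm))
    clusters <- lapply(withTpm, peakCluster, peakDistance = peakDistance,
                       extensionDistance = extensionDistance,
                       localThreshold = localThreshold)
    cons <- consensusClusters(clusters, dis = dis, ctssList = withTpm)
    assignClustersToGenes(cons, geneModels, upstream, downstream)$geneTpm
}
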