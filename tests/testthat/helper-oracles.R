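# Independent brute-force oracles used by the property tests.  These are
# deliberately naive re-derivations of the stated rules, kept separate from
# the package implementations they check.

# Benjamini-Hochberg by direct definition: padj_i = min over j with
# p_(j) >= p_(i) of p_(j) * m / j, capped at 1.
bruteBH <- function(p) {
    m <- length(p)
    ord <- order(p)
    adj <- numeric(m)
    sorted <- p[ord] * m / seq_len(m)
    running <- rev(cummin(rev(sorted)))
    adj[ord] <- pmin(running, 1)
    adj
}

# Peak clustering by literal rule evaluation with plain loops.
brutePeakCluster <- function(records, peakDistance = 50,
                             extensionDistance = 25, localThreshold = 0.01) {
    out <- list()
    for (ch in unique(records$chrom)) for (st in c("+", "-")) {
        g <- records[records$chrom == ch & records$strand == st, ]
        if (nrow(g) == 0) next
        g <- g[order(g$pos), ]
        status <- rep("open", nrow(g))
        while (any(status == "open")) {
            best <- NA; bestTpm <- -Inf
            for (i in seq_len(nrow(g))) {
                if (status[i] != "open") next
                if (g$tpm[i] > bestTpm) { bestTpm <- g$tpm[i]; best <- i }
            }
            members <- c()
            for (i in seq_len(nrow(g))) {
                if (status[i] == "open" &&
                    abs(g$pos[i] - g$pos[best]) <= peakDistance)
                    members <- c(members, i)
            }
            retained <- c()
            for (i in members) {
                lowSignal <- g$tpm[i] < localThreshold * g$tpm[best]
                near <- abs(g$pos[i] - g$pos[best]) <= extensionDistance
                if (lowSignal && !near) status[i] <- "dropped"
                else { status[i] <- "assigned"; retained <- c(retained, i) }
            }
            out[[length(out) + 1]] <- data.frame(
                chrom = ch, strand = st,
                start = min(g$pos[retained]), end = max(g$pos[retained]),
                dominant_pos = g$pos[best],
                tpm_sum = sum(g$tpm[retained]),
                member_count = length(retained))
        }
    }
    out <- do.call(rbind, out)
    out <- out[order(out$chrom, out$strand, out$start), ]
    rownames(out) <- NULL
    out
}

# Complete-linkage agglomeration by direct pairwise search; returns merge
# heights in order.
bruteCompleteLinkageHeights <- function(mat) {
    clusters <- as.list(seq_len(nrow(mat)))
    d <- as.matrix(dist(mat))
    heights <- numeric(0)
    while (length(clusters) > 1) {
        best <- c(NA, NA); bestD <- Inf
        for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
            if (i >= j) next
            link <- max(d[clusters[[i]], clusters[[j]]])
            if (link < bestD) { bestD <- link; best <- c(i, j) }
        }
        heights <- c(heights, bestD)
        clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
        clusters[[best[2]]] <- NULL
    }
    heights
}

# random CTSS instance generator for the clustering property test
randomCTSS <- function(n, maxPos = 400) {
    pos <- sort(sample.int(maxPos, n, replace = FALSE))
    df <- data.frame(chrom = "chrI", pos = pos, strand = "+",
                     count = sample.int(50, n, replace = TRUE))
    ctssTpm(df)
}
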