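# TSS filtering, peak clustering, consensus building, gene assignment.

mkCtss <- function(pos, count, chrom = "chrI", strand = "+")
    data.frame(chrom = chrom, pos = pos, strand = strand, count = count)

test_that("TSS filter applies the inclusive TPM threshold", {
    r <- mkCtss(c(10, 20, 30), c(1, 2, 997))   # tpm: 1000, 2000, 997000
    r <- ctssTpm(r)
    r$tpm <- c(0.05, 0.1, 5)                   # exercise the rule directly
    kept <- filterTSS(r)
    expect_equal(kept$pos, c(20, 30))          # 0.05 removed, 0.1 retained
    empty <- filterTSS(r[0, , drop = FALSE])
    expect_equal(nrow(empty), 0)
})

test_that("peak clustering handles the canonical small cases", {
    one <- peakCluster(ctssTpm(mkCtss(100, 10)))
    expect_equal(one[, c("start", "end", "dominant_pos")],
                 data.frame(start = 100, end = 100, dominant_pos = 100))
    near <- peakCluster(ctssTpm(mkCtss(c(100, 130), c(10, 5))))
    expect_equal(nrow(near), 1)
    expect_equal(near$start, 100); expect_equal(near$end, 130)
    expect_equal(near$dominant_pos, 100)
    far <- peakCluster(ctssTpm(mkCtss(c(100, 180), c(10, 5))))
    expect_equal(nrow(far), 2)
})

test_that("weak distant members are dropped, near ones are exempt", {
    r <- mkCtss(c(100, 140), c(100, 0.5))
    r$tpm <- c(100, 0.5)   # 0.5 < 0.01 * 100 and 40 bp > extension 25
    cl <- peakCluster(r)
    expect_equal(cl$member_count, 1)
    expect_equal(cl$end, 100)
    r2 <- mkCtss(c(100, 120), c(100, 0.5))
    r2$tpm <- c(100, 0.5)  # same ratio but 20 bp <= 25: kept
    cl2 <- peakCluster(r2)
    expect_equal(cl2$member_count, 2)
    # with the exemption off, the near member is dropped too
    cl3 <- peakCluster(r2, extensionExempt = FALSE)
    expect_equal(cl3$member_count, 1)
})

test_that("unsorted CTSS input is rejected", {
    r <- ctssTpm(mkCtss(c(200, 100), c(1, 2)))
    expect_error(peakCluster(r), "sorted")
})

test_that("peak clustering equals the brute-force oracle", {
    set.seed(7)
    for (i in 1:30) {
        r <- randomCTSS(sample(1:50, 1))
        got <- peakCluster(r)
        want <- brutePeakCluster(r)
        expect_equal(got, want)
        # invariants: retained TSSs never outnumber the input (no TSS in
        # two clusters) and members sit within peakDistance of the peak
        expect_lte(sum(got$member_count), nrow(r))
        for (k in seq_len(nrow(got))) {
            expect_lte(got$end[k] - got$dominant_pos[k], 50)
            expect_lte(got$dominant_pos[k] - got$start[k], 50)
        }
        # clusters on one strand do not overlap
        if (nrow(got) > 1) {
            o <- order(got$start)
            expect_true(all(got$start[o][-1] > got$end[o][-nrow(got)]))
        }
    }
})

test_that("consensus clustering merges by gap and quantifies per sample", {
    a <- peakCluster(ctssTpm(mkCtss(c(100, 120), c(5, 5))))
    b <- peakCluster(ctssTpm(mkCtss(c(100, 120), c(4, 6))))
    cons <- consensusClusters(list(s1 = a, s2 = b))
    expect_equal(nrow(cons), 1)                       # identical spans merge
    gap89 <- consensusClusters(list(
        peakCluster(ctssTpm(mkCtss(c(100, 120), c(5, 5)))),
        peakCluster(ctssTpm(mkCtss(c(210, 230), c(5, 5))))))
    expect_equal(nrow(gap89), 1)                      # gap 89 <= 100
    expect_equal(c(gap89$start, gap89$end), c(100, 230))
    gap150 <- consensusClusters(list(
        peakCluster(ctssTpm(mkCtss(c(100, 120), c(5, 5)))),
        peakCluster(ctssTpm(mkCtss(c(271, 290), c(5, 5))))))
    expect_equal(nrow(gap150), 2)                     # gap 150 > 100
    # per-sample TPM is the sum of member TSS TPMs in range
    ct1 <- ctssTpm(mkCtss(c(100, 120), c(5, 5)))
    ct2 <- ctssTpm(mkCtss(c(110), c(4)))
    cons2 <- consensusClusters(list(peakCluster(ct1), peakCluster(ct2)),
                               ctssList = list(x = ct1, y = ct2))
    expect_equal(cons2$tpm.x, 1e6)
    expect_equal(cons2$tpm.y, 1e6)
})

test_that("strands are kept separate in consensus clustering", {
    plus <- peakCluster(ctssTpm(mkCtss(100, 5)))
    minus <- peakCluster(ctssTpm(mkCtss(120, 5, strand = "-")))
    cons <- consensusClusters(list(plus, minus))
    expect_equal(nrow(cons), 2)
})

test_that("clusters are assigned to genes by the start-codon window", {
    gm <- GenomicRanges::GRanges("chrI", IRanges::IRanges(4990, 6500),
                                 strand = "+")
    S4Vectors::mcols(gm) <- S4Vectors::DataFrame(
        gene_id = "gA", tx_length = 1500, cds_length = 1200,
        tss = 4990, start_codon = 5000)
    mk <- function(dom) data.frame(chrom = "chrI", strand = "+",
                                   start = dom, end = dom,
                                   dominant_pos = dom, tpm_sum = 3)
    inWin <- assignClustersToGenes(mk(4500), gm)
    expect_equal(inWin$assignments$gene_id, "gA")
    outWin <- assignClustersToGenes(mk(3900), gm)     # 1100 bp upstream
    expect_equal(nrow(outWin$assignments), 0)
    edge <- assignClustersToGenes(mk(5050), gm)       # +50 inclusive
    expect_equal(edge$assignments$gene_id, "gA")
    # two clusters assigned to one gene sum their TPMs
    two <- rbind(mk(4500), mk(4600)); two$tpm_sum <- c(3, 2)
    expect_equal(unname(assignClustersToGenes(two, gm)$geneTpm["gA", ]), 5)
})

test_that("ambiguous clusters go to the nearest (then upstream) gene", {
    gm <- GenomicRanges::GRanges("chrI",
                                 IRanges::IRanges(c(5000, 5900), c(5800, 7000)),
                                 strand = "+")
    S4Vectors::mcols(gm) <- S4Vectors::DataFrame(
        gene_id = c("gA", "gB"), tx_length = c(800, 1100),
        cds_length = c(600, 900), tss = c(5000, 5900),
        start_codon = c(5050, 5950))
    mk <- function(dom) data.frame(chrom = "chrI", strand = "+",
                                   start = dom, end = dom,
                                   dominant_pos = dom, tpm_sum = 1)
    near <- assignClustersToGenes(mk(5900), gm)   # 850 from gA, 50 from gB
    expect_equal(near$assignments$gene_id, "gB")
    tie <- assignClustersToGenes(mk(5500), gm)    # 450 from both: upstream
    expect_equal(tie$assignments$gene_id, "gB")   # cluster upstream of gB
})

test_that("the promoter pipeline recovers planted gene assignments", {
    b <- generateDataset(simConfig(nGenes = 150), seed = 10)
    tr <- simTruth(b)
    pooled <- ctssTables(b)[["cage_WT_r1"]]
    geneTpm <- cageGeneTpm(list(WT = pooled), geneModels(b))
    expressed <- assayCounts(b, "cage")[, "cage_WT_r1"] > 20
    recovered <- geneTpm[expressed, "WT"] > 0
    expect_gte(mean(recovered), 0.99)
})
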