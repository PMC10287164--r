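# Group calls, dependence, mechanism, deciles, summaries, clustering.

mkDiff <- function(gene_id, log2fc, padj, low = FALSE)
    data.frame(gene_id = gene_id, base_mean = 100, log2fc = log2fc,
               se = 0.1, wald_stat = log2fc / 0.1, pvalue = padj,
               padj = padj, low_count_flag = low, dispersion = 0.05,
               fit = "nb", stringsAsFactors = FALSE)

test_that("group calls follow the fold-change and FDR thresholds", {
    d <- mkDiff(c("a", "b", "c", "d"),
                log2fc = c(1.0, 0.4, -1.2, 0.6),
                padj = c(0.01, 0.001, 0.05, 0.5))
    g <- callGroups(d)
    expect_equal(g$group, c("UP", "NONE", "DN", "NONE"))
    # 0.4 < log2(1.4) ~ 0.485 despite tiny padj
    flagged <- mkDiff("e", NA, NA, low = TRUE)
    gf <- callGroups(flagged)
    expect_equal(gf$group, "NONE")
    expect_equal(gf$reason, "low_count")
})

test_that("dependence calls distinguish activator-dependent genes", {
    up <- c("a", "b", "c")
    dcp2 <- mkDiff(up, log2fc = c(1.0, 0.85, 0.9), padj = c(0.01, 0.01, 0.01))
    dhh1 <- mkDiff(c("a", "b"), log2fc = c(0.93, -0.15),
                   padj = c(0.02, 0.6))          # c missing entirely
    dble <- mkDiff(up, log2fc = c(1.0, 0.85, 0.9), padj = c(0.01, 0.01, 0.01))
    dep <- callDependence(up, dcp2, dhh1, dble)
    expect_equal(dep$dependence, c("DHH1_DEP", "DHH1_INDEP", NA))
    expect_true(all(dep$epistasis_consistent[1:2]))
    # an inconsistent double mutant is flagged
    dble2 <- mkDiff(up, log2fc = c(2.6, 0.85, 0.9), padj = rep(0.01, 3))
    dep2 <- callDependence(up, dcp2, dhh1, dble2)
    expect_false(dep2$epistasis_consistent[1])
})

test_that("mechanism diagnosis combines C/T and Pol II occupancy", {
    genes <- paste0("g", 1:6)
    dCt <- setNames(c(0.6, 0.0, 0.05, 0.7, -0.1, 0.02), genes)
    dRpb1 <- setNames(c(-0.3, 0.8, -0.1, 0.6, -0.2, NA), genes)
    m <- diagnoseMechanism(genes[c(1, 2, 4, 6)], dCt, dRpb1)
    expect_equal(m$mechanism[1], "DECAY")      # high dCT, Rpb1 down
    expect_equal(m$mechanism[2], "TXN")        # Rpb1 up > log2(1.4)
    expect_equal(m$mechanism[3], "TXN")        # TXN overrides high dCT
    expect_true(is.na(m$mechanism[4]))         # missing modality
    dCage <- setNames(rep(1, 6), genes); dRna <- setNames(rep(0.5, 6), genes)
    m2 <- diagnoseMechanism(genes[1], dCt, dRpb1, dCage, dRna)
    expect_true(m2$cage_exceeds_rna)
})

test_that("TE deciles partition genes and handle edge cases", {
    te <- setNames(20:1, paste0("g", 1:20))
    dte <- setNames(rep(0, 20), paste0("g", 1:20))
    dec <- teDeciles(te, dte)
    expect_equal(dec$n, rep(2, 10))            # 20 genes: bins of 2
    expect_equal(dec$median_delta_te, rep(0, 10))
    expect_error(teDeciles(te[1:9], dte[1:9]), "at least 10")
    # deciles partition all eligible genes exactly once
    expect_equal(sum(dec$n), 20)
})

test_that("decile medians fall with decreasing wild-type TE when the
           change is TE-correlated", {
    set.seed(13)
    te <- setNames(rlnorm(200, 0, 1), paste0("g", 1:200))
    dte <- log2(te) * 0.2 + rnorm(200, 0, 0.01)
    dec <- teDeciles(te, dte)
    expect_true(all(diff(dec$median_delta_te) <= 0))
})

test_that("group summaries report medians, notches and Mann-Whitney p", {
    set.seed(14)
    x <- rnorm(500); y <- rnorm(500)
    s <- groupSummary(c(x, y), rep(c("all", "same"), each = 500),
                      reference = "all")
    expect_gt(s$p_vs_reference[2], 0.01)
    # overlapping notches for identical distributions
    expect_lt(abs(s$median[1] - s$median[2]), s$notch[1] + s$notch[2])
    shifted <- groupSummary(c(x, y + 1), rep(c("all", "up"), each = 500),
                            reference = "all")
    expect_lt(shifted$p_vs_reference[2], 1e-10)
    expect_equal(groupSummary(c(-1, 0, 2, rnorm(5)),
                              c(rep("m", 3), rep("z", 5)),
                              reference = "z")$median[1], 0)
    tiny <- groupSummary(c(1, 2, rnorm(10)), c("t", "t", rep("z", 10)),
                         reference = "z")
    expect_true(is.na(tiny$notch[1]))          # notch suppressed, n < 3
    expect_equal(tiny$notch[1], NA_real_)
    expect_error(groupSummary(1:5, rep("one", 5)), "two groups")
    # notch formula: 1.58 IQR / sqrt(n)
    expect_equal(s$notch[1], 1.58 * (s$q3[1] - s$q1[1]) / sqrt(500))
})

test_that("hierarchical clustering matches brute-force complete linkage", {
    set.seed(15)
    for (i in 1:10) {
        m <- matrix(rnorm(4 * 3), 4)
        hc <- hclusterFoldChanges(m, exclude = Inf)
        expect_equal(sort(hc$hclust$height),
                     sort(bruteCompleteLinkageHeights(m)), tolerance = 1e-9)
    }
    dup <- rbind(a = c(1, 2), b = c(1, 2), c = c(5, 9))
    hc <- hclusterFoldChanges(dup, exclude = Inf)
    expect_equal(hc$hclust$height[1], 0)       # identical rows merge first
})

test_that("outlier rows beyond the fold-change bound are excluded", {
    m <- rbind(a = c(0.2, 0.4), b = c(4.5, 0.1), c = c(1, 1), d = c(2, 2))
    hc <- hclusterFoldChanges(m)               # default |log2| > 4
    expect_equal(hc$excluded, "b")
    expect_setequal(hc$order, c("a", "c", "d"))
    mNA <- rbind(a = c(NA, 1), b = c(1, 1), c = c(0, 0))
    expect_error(hclusterFoldChanges(mNA, exclude = Inf), "non-finite")
    # with exclusion on, the NA row is dropped instead
    expect_equal(hclusterFoldChanges(mNA)$excluded, "a")
})

test_that("classification labels are invariant to gene order", {
    set.seed(16)
    d <- mkDiff(paste0("g", 1:50), rnorm(50, 0, 1),
                runif(50)^2)
    g1 <- callGroups(d)
    perm <- sample(50)
    g2 <- callGroups(d[perm, ])
    expect_equal(g2$group[order(perm)], g1$group)
})
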