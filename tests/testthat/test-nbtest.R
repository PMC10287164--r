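# NB Wald test, dispersion moderation, BH, TE interaction test.

twoByTwo <- factor(c("a", "a", "b", "b"))

test_that("identical groups give zero fold change and high p", {
    y <- matrix(rep(c(30, 100, 7, 500), 4), ncol = 4)
    rownames(y) <- paste0("g", 1:4)
    d <- nbDiff(y, twoByTwo)
    expect_equal(d$log2fc, rep(0, 4), tolerance = 1e-6)
    expect_true(all(d$pvalue > 0.9))
})

test_that("the low-count filter excludes genes below the read total", {
    y <- rbind(low = c(2, 3, 2, 2),      # 9 total reads: excluded
               edge = c(2, 3, 3, 2),     # 10: tested
               high = c(50, 60, 55, 45))
    d <- nbDiff(y, twoByTwo)
    expect_true(d$low_count_flag[1])
    expect_true(is.na(d$pvalue[1]))
    expect_false(d$low_count_flag[2])
    expect_false(is.na(d$pvalue[2]))
})

test_that("design errors are rejected", {
    y <- matrix(rpois(40, 50), ncol = 4)
    expect_error(nbDiff(y, factor(c("a", "a", "a", "b"))), "replicates")
    expect_error(nbDiff(y[, 1:3], factor(c("a", "a", "a"))), "two groups")
})

test_that("a planted 4-fold gene is detected in nearly all seeds", {
    hits <- vapply(1:20, function(s) {
        set.seed(s)
        n <- 400
        mu <- rlnorm(n, log(100), 1); mu[1] <- 200
        fc <- rep(1, n); fc[1] <- 4
        y <- cbind(rnbinom(n, mu = mu, size = 20),
                   rnbinom(n, mu = mu, size = 20),
                   rnbinom(n, mu = mu * fc, size = 20),
                   rnbinom(n, mu = mu * fc, size = 20))
        d <- nbDiff(y, twoByTwo)
        isTRUE(d$padj[1] < 0.1)
    }, logical(1))
    expect_gte(mean(hits), 0.95)
})

test_that("type-I error under the null is near nominal", {
    set.seed(42)
    n <- 2000
    mu <- rlnorm(n, log(100), 1)
    y <- sapply(1:4, function(i) rnbinom(n, mu = mu, size = 20))
    d <- nbDiff(y, twoByTwo)
    rate <- mean(d$pvalue < 0.05, na.rm = TRUE)
    tested <- sum(!is.na(d$pvalue))
    ci <- 0.05 + c(-1, 1) * qnorm(0.995) * sqrt(0.05 * 0.95 / tested)
    expect_gte(rate, ci[1])
    expect_lte(rate, ci[2])
})

test_that("BH adjustment matches the brute-force definition", {
    set.seed(8)
    for (i in 1:20) {
        p <- runif(sample(5:200, 1))^sample(1:3, 1)
        expect_equal(p.adjust(p, "BH"), bruteBH(p), tolerance = 1e-12)
    }
    # monotone: ordering of padj follows ordering of p
    p <- runif(100)
    adj <- bruteBH(p)
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    # and padj >= p always
    expect_true(all(adj >= p - 1e-12))
})

test_that("padj is never below pvalue in reported results", {
    set.seed(9)
    y <- matrix(rnbinom(400 * 4, mu = 80, size = 10), ncol = 4)
    d <- nbDiff(y, twoByTwo)
    ok <- !is.na(d$padj)
    expect_true(all(d$padj[ok] >= d$pvalue[ok] - 1e-12))
})

test_that("fold-change estimates agree with an established NB pipeline", {
    set.seed(10)
    n <- 300
    mu <- rlnorm(n, log(120), 1)
    fc <- rep(1, n); fc[1:30] <- 3; fc[31:60] <- 1 / 3
    y <- cbind(s1 = rnbinom(n, mu = mu, size = 20),
               s2 = rnbinom(n, mu = mu, size = 20),
               s3 = rnbinom(n, mu = mu * fc, size = 20),
               s4 = rnbinom(n, mu = mu * fc, size = 20))
    rownames(y) <- paste0("g", 1:n)
    mine <- nbDiff(y, twoByTwo)
    suppressMessages({
        dds <- DESeq2::DESeqDataSetFromMatrix(y,
            S4Vectors::DataFrame(condition = twoByTwo), ~condition)
        dds <- DESeq2::DESeq(dds, quiet = TRUE)
        ref <- DESeq2::results(dds)
    })
    ok <- !is.na(mine$log2fc) & !is.na(ref$log2FoldChange) &
        mine$base_mean > 20
    expect_gt(cor(mine$log2fc[ok], ref$log2FoldChange[ok]), 0.98)
    # the two routes call essentially the same strong genes
    mineUp <- which(mine$padj < 0.1 & mine$log2fc > 1)
    refUp <- which(ref$padj < 0.1 & ref$log2FoldChange > 1)
    expect_gt(length(intersect(mineUp, refUp)) /
              max(length(union(mineUp, refUp)), 1), 0.8)
})

test_that("TE interaction is zero when RPF tracks mRNA", {
    set.seed(11)
    n <- 150
    mu <- rlnorm(n, log(100), 0.8)
    rna <- cbind(rpois(n, mu), rpois(n, mu),
                 rpois(n, mu * 2), rpois(n, mu * 2))   # mRNA doubles
    rpf <- cbind(rpois(n, mu), rpois(n, mu),
                 rpois(n, mu * 2), rpois(n, mu * 2))   # RPF doubles too
    rownames(rna) <- rownames(rpf) <- paste0("g", 1:n)
    d <- deltaTETest(rna, rpf, twoByTwo, twoByTwo)
    expect_lt(abs(median(d$log2fc, na.rm = TRUE)), 0.1)
    expect_equal(sum(d$padj < 0.1, na.rm = TRUE), 0)
})

test_that("a planted TE gain is recovered by the interaction term", {
    set.seed(12)
    n <- 200
    mu <- rlnorm(n, log(150), 0.5)
    teGain <- rep(1, n); teGain[1:10] <- 2
    rna <- cbind(rpois(n, mu), rpois(n, mu), rpois(n, mu), rpois(n, mu))
    rpf <- cbind(rpois(n, mu), rpois(n, mu),
                 rpois(n, mu * teGain), rpois(n, mu * teGain))
    rownames(rna) <- rownames(rpf) <- paste0("g", 1:n)
    d <- deltaTETest(rna, rpf, twoByTwo, twoByTwo)
    expect_equal(mean(d$log2fc[1:10]), 1, tolerance = 0.15)
    # the planted genes dominate the ranking
    top <- order(d$pvalue)[1:10]
    expect_gte(length(intersect(top, 1:10)), 8)
})

test_that("the TE test controls false discoveries under a global null", {
    fdp <- vapply(1:20, function(s) {
        set.seed(100 + s)
        n <- 300
        mu <- rlnorm(n, log(100), 0.8)
        rna <- sapply(1:4, function(i) rnbinom(n, mu = mu, size = 20))
        rpf <- sapply(1:4, function(i) rnbinom(n, mu = mu, size = 20))
        rownames(rna) <- rownames(rpf) <- paste0("g", 1:n)
        d <- deltaTETest(rna, rpf, twoByTwo, twoByTwo)
        disc <- sum(d$padj < 0.1, na.rm = TRUE)
        if (disc > 0) 1 else 0   # all discoveries are false under the null
    }, numeric(1))
    expect_lte(mean(fdp), 0.1)
})
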