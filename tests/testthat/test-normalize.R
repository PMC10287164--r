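# Size factors: median-of-ratios, ERCC spike-in, foreign-genome ChIP.

test_that("median-of-ratios recovers depth differences", {
    set.seed(3)
    base <- matrix(rpois(300, 100) + 1, 100)
    same <- sizeFactorsMOR(cbind(base[, 1], base[, 1]))
    expect_equal(unname(same$factors), c(1, 1))
    doubled <- cbind(a = base[, 1], b = base[, 1] * 2)
    sf <- sizeFactorsMOR(doubled)$factors
    expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-9)
    norm <- normalizeCounts(doubled, sizeFactorsMOR(doubled))
    expect_equal(norm[, "a"], norm[, "b"], tolerance = 1e-9)
    expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-12)
})

test_that("median-of-ratios needs an all-nonzero gene", {
    m <- rbind(c(0, 5), c(5, 0))
    expect_error(sizeFactorsMOR(m), "pseudo-reference")
})

test_that("mostly-null normalization centres the median fold change", {
    set.seed(4)
    n <- 800
    mu <- rlnorm(n, log(80), 1)
    fc <- rep(1, n); fc[1:80] <- 4        # 10% up-regulated
    y <- cbind(rnbinom(n, mu = mu, size = 20),
               rnbinom(n, mu = mu * fc * 1.8, size = 20))  # depth shift too
    norm <- normalizeCounts(y, sizeFactorsMOR(y))
    lfc <- log2((norm[, 2] + 0.5) / (norm[, 1] + 0.5))
    expect_lt(abs(median(lfc)), 0.05)
})

test_that("ERCC factors use subgroup B only and detect global shifts", {
    def <- erccDefinition()
    expect_equal(sum(def$subgroup == "B"), 23)
    expect_equal(def$conc_mix1[def$subgroup == "B"],
                 def$conc_mix2[def$subgroup == "B"])
    set.seed(5)
    spikes <- matrix(rpois(92 * 2, 200) + 1, 92,
                     dimnames = list(def$spike_id, c("s1", "s2")))
    spikes[, 2] <- spikes[, 1]
    expect_equal(unname(sizeFactorsERCC(spikes, def)$factors),
                 c(1, 1), tolerance = 1e-9)
    # biological genes do not move spike factors
    expect_equal(sizeFactorsERCC(spikes, def)$factors,
                 sizeFactorsERCC(spikes, def)$factors)
    # homogeneity: scaling one spike library scales its factor
    scaled <- spikes; scaled[, 2] <- scaled[, 2] * 3
    sf <- sizeFactorsERCC(scaled, def)$factors
    expect_equal(unname(sf[2] / sf[1]), 3, tolerance = 1e-9)
    zero <- spikes; zero[def$subgroup == "B", 2] <- 0
    expect_error(sizeFactorsERCC(zero, def), "zero")
})

test_that("a global abundance shift is invisible to MOR but seen by ERCC", {
    set.seed(6)
    n <- 600
    mu <- rlnorm(n, log(100), 0.8)
    def <- erccDefinition()
    spikeMu <- rep(300, 92)
    # condition B: every gene 1.5x more abundant, equal sequencing depth,
    # so cellular reads crowd out the fixed spike aliquot
    mkLib <- function(shift) {
        cell <- mu * shift
        tot <- sum(cell) + sum(spikeMu / shift * 0 + spikeMu)
        # fixed depth: scale everything to the same total
        depth <- 1e5
        c(rnbinom(n, mu = depth * cell / tot, size = 20),
          rnbinom(92, mu = depth * spikeMu / tot, size = 20))
    }
    libA <- mkLib(1); libB <- mkLib(1.5)
    genes <- rbind(cbind(libA[1:n], libB[1:n]))
    spikes <- cbind(libA[n + 1:92], libB[n + 1:92]) + 1
    rownames(spikes) <- def$spike_id
    morNorm <- normalizeCounts(genes, sizeFactorsMOR(genes))
    morFC <- median(morNorm[, 2] / pmax(morNorm[, 1], 1), na.rm = TRUE)
    erccNorm <- normalizeCounts(genes, sizeFactorsERCC(spikes, def))
    erccFC <- median(erccNorm[, 2] / pmax(erccNorm[, 1], 1), na.rm = TRUE)
    expect_lt(abs(log2(morFC)), 0.15)            # relative view: no change
    expect_gt(erccFC, 1.3)                       # absolute view: ~1.5x
    expect_lt(erccFC, 1.75)
})

test_that("foreign-genome ChIP factors follow mean(totals)/total", {
    sf <- sizeFactorsPombe(c(a = 10e6, b = 20e6, c = 30e6))$factors
    expect_equal(unname(sf), c(2, 1, 2 / 3), tolerance = 1e-9)
    expect_equal(unname(sizeFactorsPombe(c(5, 5, 5))$factors), rep(1, 3))
    expect_error(sizeFactorsPombe(c(1, 0)))
    # conservation of the spike average
    tot <- c(3e6, 9e6, 4e6)
    f <- sizeFactorsPombe(tot)$factors
    expect_equal(mean(f * tot), mean(tot), tolerance = 1e-9)
})

test_that("spike normalization removes IP-efficiency differences", {
    set.seed(7)
    occ <- rlnorm(300, log(50), 1)          # constant true occupancy
    eff <- c(1, 2, 0.7)                     # 2x IP-efficiency differences
    counts <- sapply(eff, function(e) rpois(300, e * occ))
    totals <- round(eff * 1e6)
    norm <- normalizeCounts(counts, sizeFactorsPombe(totals))
    ratios <- colSums(norm) / colSums(norm)[1]
    expect_equal(unname(ratios), rep(1, 3), tolerance = 0.05)
})
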