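## Synthetic multi-omic data generator.
##
## The generator plants a complete ground truth: per-gene kinetic rates and
## labels, genotype effects, a limiting-PIC translation layer, and then
## emits negative-binomial counts for RNA-Seq, CAGE, ribosome profiling and
## Rpb1 ChIP-Seq, together with ERCC-like and foreign-genome spike-ins and
## per-base CTSS tables for the CAGE samples.

#' Default simulation configuration
#'
#' Returns the fully-resolved configuration list that defines the study
#' conditions of the generator.  Any element can be overridden by passing a
#' (possibly nested) named list; unknown keys are rejected.
#'
#' The defaults encode the simulated design: ~5000 genes on four
#' chromosomes; two biological replicates per genotype; decapping
#' dependence classes at 14% activator-dependent (`DHH1_DEP`), 11%
#' NMD-dependent (`NMD_DEP`), remainder basal; 5% of basal genes carry a
#' stress-like transcriptional induction (3-fold) in decapping-null cells;
#' activator-targeted genes are decapped 4-fold faster than basal in wild
#' type; global transcriptional buffering of 1/1.3 and a 0.7x PIC pool in
#' decapping-null genotypes; per-assay negative-binomial dispersion 0.05.
#'
#' @param ... named overrides, e.g. `nGenes = 300`,
#'   `noise = list(enabled = FALSE)`
#' @return a configuration list
#' @examples
#' cfg <- simConfig(nGenes = 100, noise = list(enabled = FALSE))
#' cfg$nGenes
#' @export
simConfig <- function(...) {
    cfg <- list(
        nGenes = 5000,
        genotypes = c("WT", "dcp2", "dhh1", "dcp2dhh1", "xrn1", "upf1"),
        replicates = 2,
        genome = list(nChrom = 4, spacing = 3000, txMeanLog = log(1300),
                      txSdLog = 0.35, minTx = 300, maxTx = 2500,
                      cdsFrac = 0.75, utr5 = 50),
        kinetics = list(alphaMeanLog = log(5), alphaSdLog = 0.8,
                        deltaMeanLog = log(0.03), deltaSdLog = 0.5,
                        gammaMeanLog = log(0.5), gammaSdLog = 0.3,
                        mu = 0.02, sMeanLog = 0, sSdLog = 1),
        classes = list(pDhh1Dep = 0.14, pNmdDep = 0.11, pTxnDriven = 0.05),
        effects = list(activatorBoost = 4, txnBuffering = 1 / 1.3,
                       txnInduction = 3, picFactor = 0.7, txnFeedback = 0.25),
        pic = list(fraction = 0.3),
        assays = list(rna = c("WT", "dcp2", "dhh1", "dcp2dhh1", "xrn1", "upf1"),
                      cage = c("WT", "dcp2", "xrn1"),
                      rpf = c("WT", "dcp2", "dhh1", "dcp2dhh1"),
                      chip = c("WT", "dcp2"),
                      rna_ercc = c("WT", "dcp2")),
        depth = list(rna = 2e6, cage = 1e6, rpf = 1e6, chip = 1e6,
                     rna_ercc = 2e6),
        noise = list(enabled = TRUE,
                     dispersion = list(rna = 0.05, cage = 0.05, rpf = 0.05,
                                       chip = 0.05, rna_ercc = 0.05),
                     depthJitterSd = 0.05, chipEffSd = 0.2),
        cage = list(spread = 0.25, maxOffset = 60, multiTSSFrac = 0,
                    secondaryOffset = -120, secondaryFrac = 0.3),
        rpf = list(uncappedRPF = 0),
        ercc = list(aliquotFrac = 0.03, mixes = list(WT = "Mix1", dcp2 = "Mix2",
                    dhh1 = "Mix2", dcp2dhh1 = "Mix2", xrn1 = "Mix2",
                    upf1 = "Mix2")),
        pombe = list(aliquotFrac = 0.1),
        seed = NULL
    )
    over <- list(...)
    if (length(over)) {
        if (is.null(names(over)) || any(names(over) == ""))
            stop("configuration overrides must be named")
        bad <- setdiff(names(over), names(cfg))
        if (length(bad))
            stop("unknown configuration keys: ", paste(bad, collapse = ", "))
        cfg <- utils::modifyList(cfg, over)
    }
    cfg
}

## deterministic gene layout: genes placed on alternating strands with
## fixed spacing; same-strand neighbours are two slots apart so promoter
## windows never collide.
.simGeneModels <- function(cfg) {
    n <- cfg$nGenes
    g <- cfg$genome
    txlen <- pmin(g$maxTx, pmax(g$minTx,
                  round(stats::rlnorm(n, g$txMeanLog, g$txSdLog))))
    cdslen <- pmax(150, pmin(txlen - 2 * g$utr5, round(g$cdsFrac * txlen)))
    chrom <- paste0("chr", rep_len(seq_len(g$nChrom), n))
    slot <- (seq_len(n) - 1) %/% g$nChrom   # position index within chromosome
    strand <- ifelse(seq_len(n) %% 2 == 1, "+", "-")
    txStart <- slot * g$spacing + 1001
    txEnd <- txStart + txlen - 1
    tss <- ifelse(strand == "+", txStart, txEnd)
    startCodon <- ifelse(strand == "+", tss + g$utr5, tss - g$utr5)
    gene_id <- sprintf("gene%05d", seq_len(n))
    gr <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(txStart, txEnd),
                                 strand = strand)
    names(gr) <- gene_id
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        gene_id = gene_id, tx_length = txlen, cds_length = cdslen,
        tss = tss, start_codon = startCodon)
    gr
}

.simTruth <- function(cfg, gm) {
    n <- cfg$nGenes
    k <- cfg$kinetics
    cl <- cfg$classes
    gmc <- S4Vectors::mcols(gm)
    dep <- sample(c("DHH1_DEP", "NMD_DEP", "BASAL"), n, replace = TRUE,
                  prob = c(cl$pDhh1Dep, cl$pNmdDep,
                           1 - cl$pDhh1Dep - cl$pNmdDep))
    targeted <- dep != "BASAL"
    induced <- !targeted & (stats::runif(n) < cl$pTxnDriven /
                                max(1e-12, 1 - cl$pDhh1Dep - cl$pNmdDep))
    mech <- ifelse(targeted, "DECAY_DRIVEN",
                   ifelse(induced, "TXN_DRIVEN", "NEUTRAL"))
    alpha <- stats::rlnorm(n, k$alphaMeanLog, k$alphaSdLog)
    delta0 <- stats::rlnorm(n, k$deltaMeanLog, k$deltaSdLog)
    delta0[targeted] <- delta0[targeted] * cfg$effects$activatorBoost
    gamma <- stats::rlnorm(n, k$gammaMeanLog, k$gammaSdLog)
    s <- stats::rlnorm(n, k$sMeanLog, k$sSdLog)
    multi <- stats::runif(n) < cfg$cage$multiTSSFrac
    S4Vectors::DataFrame(
        gene_id = gmc$gene_id,
        chrom = as.character(GenomicRanges::seqnames(gm)),
        strand = as.character(GenomicRanges::strand(gm)),
        tss = gmc$tss, start_codon = gmc$start_codon,
        tx_length = gmc$tx_length, cds_length = gmc$cds_length,
        alpha = alpha, delta0 = delta0, gamma = gamma,
        mu = rep(k$mu, n), s = s,
        dep_class = dep, mech_class = mech, iesr_flag = induced,
        multi_tss = multi,
        row.names = gmc$gene_id)
}

.nbDraw <- function(mu, disp, noise) {
    if (!noise) return(round(mu))
    if (disp <= 0) return(stats::rpois(length(mu), mu))
    stats::rnbinom(length(mu), mu = mu, size = 1 / disp)
}

## per-base CTSS table for one CAGE sample: tags spread around each gene's
## TSS with a two-sided geometric kernel (all mass at the TSS when noise is
## off); optional secondary TSS for multi-TSS genes.
.simCTSS <- function(counts, truth, cfg, noise) {
    maxOff <- cfg$cage$maxOffset
    p <- cfg$cage$spread
    offs <- seq(-maxOff, maxOff)
    pmf <- p * (1 - p)^abs(offs)
    pmf <- pmf / sum(pmf)
    dir <- ifelse(truth$strand == "+", 1L, -1L)
    rows <- vector("list", length(counts))
    for (i in seq_along(counts)) {
        cnt <- counts[i]
        if (cnt == 0) next
        if (isTRUE(truth$multi_tss[i])) {
            c2 <- round(cnt * cfg$cage$secondaryFrac)
            c1 <- cnt - c2
            anchors <- c(truth$tss[i], truth$tss[i] +
                             dir[i] * cfg$cage$secondaryOffset)
            parts <- c(c1, c2)
        } else {
            anchors <- truth$tss[i]; parts <- cnt
        }
        loc <- integer(0); tag <- integer(0)
        for (a in seq_along(anchors)) {
            if (parts[a] == 0) next
            if (noise) {
                draw <- stats::rmultinom(1, parts[a], pmf)[, 1]
                keep <- draw > 0
                loc <- c(loc, anchors[a] + dir[i] * offs[keep])
                tag <- c(tag, draw[keep])
            } else {
                loc <- c(loc, anchors[a]); tag <- c(tag, parts[a])
            }
        }
        rows[[i]] <- data.frame(chrom = truth$chrom[i], pos = loc,
                                strand = truth$strand[i], count = tag)
    }
    out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(out))
        return(data.frame(chrom = character(), pos = integer(),
                          strand = character(), count = integer()))
    out <- stats::aggregate(count ~ chrom + pos + strand, out, sum)
    out <- out[order(out$chrom, out$strand, out$pos), c("chrom", "pos",
                                                        "strand", "count")]
    rownames(out) <- NULL
    out
}

## synthetic ERCC-like spike definition bundled with the package
#' Synthetic ERCC-like spike-in definition table
#'
#' Loads the bundled synthetic spike-in definition: 92 transcripts in four
#' subgroups (A-D) whose Mix1:Mix2 concentration ratios are 4, 1, 2/3 and
#' 1/2; subgroup B (23 transcripts, equal concentration in both mixes) is
#' the set used for size-factor calculation.  The table is a synthetic
#' stand-in modelled on the layout of the commercial ERCC ExFold mixes, not
#' the vendor's concentrations.
#'
#' @return data.frame with columns `spike_id`, `subgroup`, `length`,
#'   `conc_mix1`, `conc_mix2`
#' @export
erccDefinition <- function() {
    path <- system.file("extdata", "ercc_synthetic_def.tsv",
                        package = "decapDiag", mustWork = TRUE)
    utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Generate a complete synthetic multi-assay dataset
#'
#' Draws per-gene kinetic parameters and planted labels, evaluates the
#' two-pool steady state under every configured genotype (with global
#' buffering and per-gene homeostatic transcription feedback), solves the
#' limiting-PIC competition for per-mRNA initiation occupancies, and emits
#' count matrices for each assay, CTSS tables for CAGE samples, and
#' spike-in tables.  Identical `(config, seed)` give byte-identical output.
#'
#' Expected count construction per sample (before library-depth scaling):
#' RNA-Seq is proportional to total abundance times transcript length; CAGE
#' to capped abundance only (one tag per transcript 5' end, no length
#' factor); ribosome footprints to PIC occupancy times capped abundance
#' times CDS length (uncapped molecules are translationally silent by
#' default); Rpb1 ChIP to the realized transcription rate times gene
#' length.  ERCC-like spikes enter RNA libraries as a fixed aliquot against
#' the cellular mRNA mass, and a fixed foreign-genome chromatin aliquot is
#' carried through each ChIP sample's IP efficiency.
#'
#' @param config configuration from [simConfig()]
#' @param seed integer seed; all randomness derives from it
#' @return a [SimBundle-class] object
#' @examples
#' bundle <- generateDataset(simConfig(nGenes = 50), seed = 1)
#' bundle
#' @export
generateDataset <- function(config = simConfig(), seed = 1) {
    if (is.null(config$nGenes) || config$nGenes < 1)
        stop("config must name a positive gene count")
    if (any(unlist(config$depth) <= 0)) stop("library depth must be > 0")
    if (config$replicates < 2)
        warning("fewer than 2 replicates per genotype: ",
                "differential testing will not be possible")
    set.seed(seed)
    config$seed <- seed
    noise <- isTRUE(config$noise$enabled)

    gm <- .simGeneModels(config)
    truth <- .simTruth(config, gm)
    pdf0 <- as.data.frame(truth)

    ## steady states per genotype; WT is the feedback reference
    effWT <- genotypeEffect("WT", config)
    ssWT <- steadyState(pdf0, effWT)
    kappa <- config$effects$txnFeedback
    ss <- list(WT = ssWT)
    for (g in setdiff(config$genotypes, "WT")) {
        eff <- genotypeEffect(g, config)
        p <- pdf0
        p$induced <- truth$iesr_flag
        ss[[g]] <- steadyState(p, eff, kappa = kappa, refTotal = ssWT$T)
    }

    ## limiting-PIC occupancies; the pool is set in WT and scaled per genotype
    picTotalWT <- config$pic$fraction * sum(ssWT$C)
    theta <- list(); freeF <- numeric(0)
    for (g in config$genotypes) {
        eff <- genotypeEffect(g, config)
        sol <- solveFreePICs(ss[[g]]$C, truth$s, picTotalWT * eff$picFactor)
        theta[[g]] <- sol$theta
        freeF[g] <- sol$F
    }

    ercc <- erccDefinition()
    cellMass <- vapply(ss, function(x) sum(x$T * truth$tx_length), 0)
    erccAliquot <- config$ercc$aliquotFrac * cellMass["WT"] /
        sum(ercc$conc_mix1 * ercc$length)

    assays <- list(); expectations <- list()
    ctss <- list(); spikes <- list()
    for (assayName in names(config$assays)) {
        genos <- config$assays[[assayName]]
        depth0 <- config$depth[[assayName]]
        disp <- config$noise$dispersion[[assayName]]
        samples <- expand.grid(rep = seq_len(config$replicates),
                               genotype = genos, stringsAsFactors = FALSE)
        sampleID <- sprintf("%s_%s_r%d", assayName, samples$genotype,
                            samples$rep)
        mu <- matrix(0, config$nGenes, nrow(samples),
                     dimnames = list(truth$gene_id, sampleID))
        cnt <- mu
        spikeMu <- NULL; spikeCnt <- NULL
        chipEff <- rep(1, nrow(samples)); pombeTotal <- NULL
        for (j in seq_len(nrow(samples))) {
            g <- samples$genotype[j]
            depth <- depth0 * (if (noise)
                exp(stats::rnorm(1, 0, config$noise$depthJitterSd)) else 1)
            w <- switch(assayName,
                rna = ss[[g]]$T * truth$tx_length,
                rna_ercc = ss[[g]]$T * truth$tx_length,
                cage = ss[[g]]$C,
                rpf = (ss[[g]]$C + config$rpf$uncappedRPF * ss[[g]]$U) *
                      theta[[g]] * truth$cds_length,
                chip = ss[[g]]$alphaEff * truth$tx_length,
                stop("unknown assay: ", assayName))
            if (assayName == "rna_ercc") {
                mixName <- config$ercc$mixes[[g]]
                conc <- if (identical(mixName, "Mix1")) ercc$conc_mix1
                        else ercc$conc_mix2
                spikeW <- erccAliquot * conc * ercc$length
                denom <- sum(w) + sum(spikeW)
                muS <- depth * spikeW / denom
                if (is.null(spikeMu))
                    spikeMu <- spikeCnt <- matrix(0, nrow(ercc), nrow(samples),
                        dimnames = list(ercc$spike_id, sampleID))
                spikeMu[, j] <- muS
                spikeCnt[, j] <- .nbDraw(muS, disp, noise)
                mu[, j] <- depth * w / denom
            } else if (assayName == "chip") {
                eff <- if (noise) exp(stats::rnorm(1, 0, config$noise$chipEffSd)) else 1
                chipEff[j] <- eff
                refW <- ss$WT$alphaEff * truth$tx_length
                mu[, j] <- eff * depth * w / sum(refW)
                if (is.null(pombeTotal))
                    pombeTotal <- stats::setNames(numeric(nrow(samples)), sampleID)
                ## the spike total aggregates reads over a whole genome, so
                ## per-locus overdispersion averages out: Poisson scale
                pombeMu <- eff * depth * config$pombe$aliquotFrac
                pombeTotal[j] <- if (noise) stats::rpois(1, pombeMu)
                    else round(pombeMu)
            } else {
                mu[, j] <- depth * w / sum(w)
            }
            cnt[, j] <- .nbDraw(mu[, j], disp, noise)
            if (assayName == "cage")
                ctss[[sampleID[j]]] <- .simCTSS(cnt[, j], pdf0, config, noise)
        }
        cd <- S4Vectors::DataFrame(sample = sampleID, assay = assayName,
                                   genotype = samples$genotype,
                                   replicate = samples$rep,
                                   row.names = sampleID)
        if (assayName == "chip") cd$ip_efficiency <- chipEff
        se <- SummarizedExperiment::SummarizedExperiment(
            assays = list(counts = cnt), rowRanges = gm, colData = cd)
        assays[[assayName]] <- se
        expectations[[assayName]] <- mu
        if (!is.null(spikeCnt)) {
            attr(spikeCnt, "expectation") <- spikeMu
            spikes$ercc <- spikeCnt
        }
        if (!is.null(pombeTotal)) spikes$pombe <- pombeTotal
    }

    S4Vectors::metadata(truth)$steadyState <- ss
    S4Vectors::metadata(truth)$theta <- theta
    S4Vectors::metadata(truth)$freePIC <- freeF
    S4Vectors::metadata(truth)$picTotalWT <- picTotalWT

    methods::new("SimBundle", assays = assays, expectations = expectations,
                 ctss = ctss, spikes = spikes, truth = truth,
                 geneModels = gm, config = config)
}
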