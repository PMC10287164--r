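## End-to-end pipeline: simulate -> quantify -> cluster TSSs -> normalize ->
## differential testing -> classification, with a machine-readable summary.

.mergeByGenotype <- function(counts, colData)
    mergeReplicates(counts, colData$genotype)

.mergedCtss <- function(bundle, genotype) {
    sheets <- sampleSheet(bundle)
    ids <- sheets$sample[sheets$assay == "cage" & sheets$genotype == genotype]
    pooled <- do.call(rbind, ctssTables(bundle)[ids])
    pooled <- stats::aggregate(count ~ chrom + pos + strand, pooled, sum)
    pooled[order(pooled$chrom, pooled$strand, pooled$pos), ]
}

#' Run the full analysis pipeline on a simulated dataset
#'
#' Executes simulate -> quantify -> cluster-tss -> normalize -> diff ->
#' classify and writes all intermediate tables plus a machine-readable
#' JSON summary (group sizes, medians, recovery metrics, seed, config
#' hash) into `outDir`.  Identical `(config, seed)` produce identical
#' summaries.
#'
#' @param config configuration from [simConfig()]
#' @param seed integer seed controlling every random draw
#' @param outDir output directory, or `NULL` to skip writing
#' @param fcThreshold,fdr,fdrAbsolute thresholds for relative and
#'   spike-in (absolute) group calls
#' @return list with the bundle, per-contrast differential tables, CAGE
#'   gene TPMs, C/T tables, TE tables, Rpb1 changes, classification
#'   tables, and the `summary` list
#' @export
runPipeline <- function(config = simConfig(), seed = 1, outDir = NULL,
                        fcThreshold = 1.4, fdr = 0.1, fdrAbsolute = 0.01) {
    t0 <- Sys.time()
    bundle <- generateDataset(config, seed)
    truth <- simTruth(bundle)
    gm <- geneModels(bundle)
    res <- list(bundle = bundle)

    ## ---- differential mRNA abundance (relative, MOR-normalized) ----
    rna <- assayCounts(bundle, "rna")
    rnaCD <- as.data.frame(SummarizedExperiment::colData(bundle@assays$rna))
    contrasts <- intersect(c("dcp2", "dhh1", "dcp2dhh1", "xrn1", "upf1"),
                           unique(rnaCD$genotype))
    diffs <- list()
    for (g in contrasts) {
        sel <- rnaCD$genotype %in% c("WT", g)
        diffs[[g]] <- nbDiff(rna[, sel, drop = FALSE],
                             factor(rnaCD$genotype[sel], levels = c("WT", g)))
    }
    res$diff <- diffs

    ## ---- CAGE promoter pipeline and C/T ratios ----
    cageGenos <- unique(sampleSheet(bundle)$genotype[
        sampleSheet(bundle)$assay == "cage"])
    ctssMerged <- lapply(stats::setNames(cageGenos, cageGenos),
                         function(g) .mergedCtss(bundle, g))
    cageTpmMat <- cageGeneTpm(ctssMerged, gm)
    rnaMerged <- .mergeByGenotype(rna, rnaCD)
    rnaTpmMat <- tpm(rnaMerged, gm$tx_length)
    cageCountsMerged <- .mergeByGenotype(assayCounts(bundle, "cage"),
        as.data.frame(SummarizedExperiment::colData(bundle@assays$cage)))
    res$cageTpm <- cageTpmMat
    res$ct <- list()
    for (g in setdiff(cageGenos, "WT")) {
        res$ct[[g]] <- ctRatio(cageTpmMat[, c("WT", g)],
                               rnaTpmMat[, c("WT", g)],
                               cageCountsMerged[, c("WT", g)])
    }

    ## ---- TE and delta-TE ----
    haveRpf <- "rpf" %in% names(bundle@assays)
    if (haveRpf) {
        rpf <- assayCounts(bundle, "rpf")
        rpfCD <- as.data.frame(SummarizedExperiment::colData(bundle@assays$rpf))
        rpfMerged <- .mergeByGenotype(rpf, rpfCD)
        te <- list()
        for (g in unique(rpfCD$genotype)) {
            te[[g]] <- teTable(rpkm(rpfMerged[, g], gm$cds_length),
                               rpkm(rnaMerged[, g], gm$tx_length))
        }
        res$te <- te
        teContrasts <- intersect(c("dcp2", "dhh1", "dcp2dhh1"),
                                 unique(rpfCD$genotype))
        res$teDiff <- list()
        for (g in teContrasts) {
            selR <- rnaCD$genotype %in% c("WT", g)
            selP <- rpfCD$genotype %in% c("WT", g)
            res$teDiff[[g]] <- deltaTETest(
                rna[, selR, drop = FALSE], rpf[, selP, drop = FALSE],
                factor(rnaCD$genotype[selR], levels = c("WT", g)),
                factor(rpfCD$genotype[selP], levels = c("WT", g)))
        }
        if ("dcp2" %in% teContrasts) {
            dte <- stats::setNames(res$teDiff$dcp2$log2fc,
                                   res$teDiff$dcp2$gene_id)
            res$teDecile <- teDeciles(te$WT, dte[names(te$WT)])
        }
    }

    ## ---- ERCC absolute normalization ----
    sp <- spikeTables(bundle)
    if (!is.null(sp$ercc)) {
        sfE <- sizeFactorsERCC(sp$ercc)
        erccCounts <- assayCounts(bundle, "rna_ercc")
        erccCD <- as.data.frame(
            SummarizedExperiment::colData(bundle@assays$rna_ercc))
        normAbs <- normalizeCounts(erccCounts, sfE)
        res$diffAbsolute <- nbDiff(round(normAbs),
            factor(erccCD$genotype, levels = c("WT", "dcp2")),
            sizeFactors = rep(1, ncol(normAbs)))
        res$erccFactors <- sfE$factors
        merged <- .mergeByGenotype(normAbs, erccCD)
        res$bulkChange <- stats::median(
            log2(merged[, "dcp2"] / merged[, "WT"]), na.rm = TRUE)
    }

    ## ---- spike-normalized Rpb1 occupancy ----
    if ("chip" %in% names(bundle@assays) && !is.null(sp$pombe)) {
        chip <- assayCounts(bundle, "chip")
        chipCD <- as.data.frame(
            SummarizedExperiment::colData(bundle@assays$chip))
        sfP <- sizeFactorsPombe(sp$pombe)
        chipNorm <- normalizeCounts(chip, sfP)
        chipMerged <- .mergeByGenotype(chipNorm, chipCD)
        res$deltaRpb1 <- stats::setNames(
            log2(chipMerged[, "dcp2"] / chipMerged[, "WT"]),
            rownames(chipMerged))
        res$rpb1MedianFC <- 2^stats::median(res$deltaRpb1[
            is.finite(res$deltaRpb1)])
    }

    ## ---- classification ----
    groups <- callGroups(diffs$dcp2, fcThreshold, fdr)
    upGenes <- groups$gene_id[groups$group == "UP"]
    res$groups <- groups
    if (all(c("dhh1", "dcp2dhh1") %in% names(diffs))) {
        res$dependence <- callDependence(upGenes, diffs$dcp2, diffs$dhh1,
                                         diffs$dcp2dhh1, fcThreshold, fdr)
    }
    if (!is.null(res$ct$dcp2) && !is.null(res$deltaRpb1)) {
        deltaCt <- stats::setNames(res$ct$dcp2$log2_delta_ct,
                                   rownames(res$ct$dcp2))
        dCage <- log2(cageTpmMat[, "dcp2"] / cageTpmMat[, "WT"])
        dRna <- log2(rnaTpmMat[, "dcp2"] / rnaTpmMat[, "WT"])
        res$mechanism <- diagnoseMechanism(upGenes, deltaCt, res$deltaRpb1,
                                           dCage, dRna)
    }
    if (length(upGenes) >= 2 &&
        all(c("dcp2", "dhh1", "dcp2dhh1") %in% names(diffs))) {
        fcMat <- vapply(diffs[c("dhh1", "dcp2", "dcp2dhh1")],
                        function(d) d$log2fc[match(upGenes, d$gene_id)],
                        numeric(length(upGenes)))
        rownames(fcMat) <- upGenes
        ok <- apply(is.finite(fcMat), 1, all)
        if (sum(ok) >= 2)
            res$cluster <- hclusterFoldChanges(fcMat[ok, , drop = FALSE])
    }

    ## ---- recovery metrics against the planted truth ----
    summary <- list(seed = seed, config_md5 = configHash(config),
                    package_version = as.character(
                        utils::packageVersion("decapDiag")),
                    n_genes = nrow(truth),
                    elapsed_sec = as.numeric(Sys.time() - t0, units = "secs"))
    summary$groups <- as.list(table(groups$group))
    upSel <- match(upGenes, truth$gene_id)
    summary$median_fc_up <- if (length(upGenes))
        2^stats::median(diffs$dcp2$log2fc[match(upGenes, diffs$dcp2$gene_id)])
        else NA
    dnGenes <- groups$gene_id[groups$group == "DN"]
    summary$median_fc_dn <- if (length(dnGenes))
        2^stats::median(diffs$dcp2$log2fc[match(dnGenes, diffs$dcp2$gene_id)])
        else NA
    if (!is.null(res$dependence)) {
        planted <- ifelse(truth$dep_class[upSel] == "DHH1_DEP",
                          "DHH1_DEP", "DHH1_INDEP")
        called <- res$dependence$dependence
        ok <- !is.na(called)
        summary$dependence_recovery <- if (any(ok))
            mean(called[ok] == planted[ok]) else NA
        summary$dependence_split <- as.list(table(called[ok]))
    }
    if (!is.null(res$mechanism)) {
        plantedM <- truth$mech_class[upSel]
        relevant <- plantedM %in% c("DECAY_DRIVEN", "TXN_DRIVEN") &
            !is.na(res$mechanism$mechanism)
        want <- ifelse(plantedM == "DECAY_DRIVEN", "DECAY", "TXN")
        summary$mechanism_recovery <- if (any(relevant))
            mean(res$mechanism$mechanism[relevant] == want[relevant]) else NA
    }
    if (!is.null(res$bulkChange)) summary$bulk_log2_change <- res$bulkChange
    if (!is.null(res$rpb1MedianFC)) summary$rpb1_median_fc <- res$rpb1MedianFC
    res$summary <- summary

    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        writeDataset(bundle, file.path(outDir, "dataset"))
        for (g in names(diffs))
            writeDiffTSV(diffs[[g]],
                         file.path(outDir, sprintf("diff_rna_%s_vs_WT.tsv", g)))
        for (g in names(res$teDiff))
            writeDiffTSV(res$teDiff[[g]],
                         file.path(outDir, sprintf("diff_te_%s_vs_WT.tsv", g)))
        utils::write.table(groups, file.path(outDir, "groups.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        if (!is.null(res$dependence))
            utils::write.table(res$dependence,
                               file.path(outDir, "dependence.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
        if (!is.null(res$mechanism))
            utils::write.table(res$mechanism,
                               file.path(outDir, "mechanism.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
        if (!is.null(res$teDecile))
            utils::write.table(res$teDecile,
                               file.path(outDir, "te_deciles.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
        if (!is.null(res$cluster))
            writeNewick(res$cluster$hclust,
                        file.path(outDir, "cluster_up_genes.nwk"))
        jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    res
}
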