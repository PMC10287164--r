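## Plain-text file formats.  Every writer/reader pair round-trips exactly;
## all intermediate tables are TSV with typed headers.  Coordinates are
## 1-based inclusive internally; BED output is 0-based half-open.

.stopLine <- function(file, line, what)
    stop(sprintf("%s: malformed line %d (%s)", file, line, what))

#' Read/write a gene x sample count matrix as TSV
#'
#' The first column (`gene_id`) holds row names; remaining columns are
#' samples.  Values must be non-negative numbers.
#'
#' @param counts genes x samples matrix
#' @param file path
#' @return `readCountsTSV` returns the matrix with gene ids as rownames
#' @export
writeCountsTSV <- function(counts, file) {
    df <- data.frame(gene_id = rownames(counts), counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' @rdname writeCountsTSV
#' @export
readCountsTSV <- function(file) {
    df <- utils::read.delim(file, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (names(df)[1] != "gene_id")
        stop(file, ": first column must be gene_id")
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m) || any(is.na(m)) || any(m < 0))
        stop(file, ": counts must be non-negative numbers")
    rownames(m) <- df$gene_id
    m
}

#' Read/write a sample sheet as TSV
#'
#' @param sheet data.frame with at least `sample`, `assay`, `genotype`,
#'   `replicate`
#' @param file path
#' @export
writeSampleSheet <- function(sheet, file) {
    utils::write.table(sheet, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' @rdname writeSampleSheet
#' @export
readSampleSheet <- function(file) {
    df <- utils::read.delim(file, stringsAsFactors = FALSE)
    need <- c("sample", "assay", "genotype", "replicate")
    if (!all(need %in% names(df)))
        stop(file, ": sample sheet needs columns ",
             paste(need, collapse = ", "))
    df
}

#' Read/write CTSS tables
#'
#' CTSS is strictly 4 columns, no header: chromosome, 1-based position,
#' strand, tag count.
#'
#' @param records CTSS data.frame (`chrom`, `pos`, `strand`, `count`)
#' @param file path
#' @export
writeCTSS <- function(records, file) {
    .checkCTSS(records)
    utils::write.table(records[c("chrom", "pos", "strand", "count")], file,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    invisible(file)
}

#' @rdname writeCTSS
#' @export
readCTSS <- function(file) {
    raw <- readLines(file)
    parts <- strsplit(raw, "\t", fixed = TRUE)
    nc <- lengths(parts)
    if (length(raw) && any(nc != 4))
        .stopLine(file, which(nc != 4)[1], "CTSS requires exactly 4 columns")
    df <- data.frame(
        chrom = vapply(parts, `[`, "", 1),
        pos = suppressWarnings(as.integer(vapply(parts, `[`, "", 2))),
        strand = vapply(parts, `[`, "", 3),
        count = suppressWarnings(as.numeric(vapply(parts, `[`, "", 4))),
        stringsAsFactors = FALSE)
    if (anyNA(df$pos) || anyNA(df$count))
        .stopLine(file, which(is.na(df$pos) | is.na(df$count))[1],
                  "non-numeric position or count")
    .checkCTSS(df)
    df
}

#' Write TSS clusters as BED6
#'
#' Converts the 1-based inclusive cluster spans to BED's 0-based half-open
#' convention (a 1-based `[100, 130]` cluster becomes BED `99 130`); the
#' score column carries `tpm_sum` capped at 1000 per BED convention.
#' Reading back restores 1-based coordinates.
#'
#' @param clusters cluster table from [peakCluster()] or
#'   [consensusClusters()]
#' @param file path
#' @export
writeClustersBED <- function(clusters, file) {
    gr <- GenomicRanges::GRanges(clusters$chrom,
                                 IRanges::IRanges(clusters$start,
                                                  clusters$end),
                                 strand = clusters$strand)
    S4Vectors::mcols(gr)$name <- sprintf("TC%05d", seq_len(nrow(clusters)))
    S4Vectors::mcols(gr)$score <- pmin(round(clusters$tpm_sum), 1000)
    rtracklayer::export(gr, file, format = "BED")
    invisible(file)
}

#' @rdname writeClustersBED
#' @export
readClustersBED <- function(file) {
    gr <- rtracklayer::import(file, format = "BED")
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               strand = as.character(GenomicRanges::strand(gr)),
               start = GenomicRanges::start(gr),
               end = GenomicRanges::end(gr),
               name = gr$name, score = gr$score,
               stringsAsFactors = FALSE)
}

#' Write a per-base signal track as bedGraph
#'
#' @param records CTSS-like data.frame (`chrom`, `pos`, `count`); one
#'   bedGraph interval is written per base
#' @param file path
#' @export
writeBedGraph <- function(records, file) {
    gr <- GenomicRanges::GRanges(records$chrom,
                                 IRanges::IRanges(records$pos, records$pos))
    S4Vectors::mcols(gr)$score <- records$count
    rtracklayer::export(gr, file, format = "bedGraph")
    invisible(file)
}

#' Read/write gene models as TSV (and BED6)
#'
#' The TSV carries 1-based inclusive transcript spans plus `tss`,
#' `start_codon`, `tx_length` and `cds_length`.
#'
#' @param gm `GRanges` from [geneModels()]
#' @param file path
#' @export
writeGeneModelsTSV <- function(gm, file) {
    df <- data.frame(gene_id = gm$gene_id,
                     chrom = as.character(GenomicRanges::seqnames(gm)),
                     start = GenomicRanges::start(gm),
                     end = GenomicRanges::end(gm),
                     strand = as.character(GenomicRanges::strand(gm)),
                     tss = gm$tss, start_codon = gm$start_codon,
                     tx_length = gm$tx_length, cds_length = gm$cds_length,
                     stringsAsFactors = FALSE)
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' @rdname writeGeneModelsTSV
#' @export
readGeneModelsTSV <- function(file) {
    df <- utils::read.delim(file, stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "start", "end", "strand", "tss",
              "start_codon", "tx_length", "cds_length")
    if (!all(need %in% names(df)))
        stop(file, ": gene models need columns ", paste(need, collapse = ", "))
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start, df$end),
                                 strand = df$strand)
    names(gr) <- df$gene_id
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        gene_id = df$gene_id, tx_length = df$tx_length,
        cds_length = df$cds_length, tss = df$tss,
        start_codon = df$start_codon)
    gr
}

#' @rdname writeGeneModelsTSV
#' @export
writeGeneModelsBED <- function(gm, file) {
    gr <- GenomicRanges::granges(gm)
    S4Vectors::mcols(gr)$name <- gm$gene_id
    S4Vectors::mcols(gr)$score <- 0L
    rtracklayer::export(gr, file, format = "BED")
    invisible(file)
}

#' Write a dendrogram in Newick format
#'
#' @param hc an `hclust` object (e.g. from [hclusterFoldChanges()])
#' @param file path
#' @export
writeNewick <- function(hc, file) {
    ape::write.tree(ape::as.phylo(hc), file = file)
    invisible(file)
}

#' Write a differential-test result as TSV (NA kept explicit)
#'
#' @param diff result from [nbDiff()] / [deltaTETest()]
#' @param file path
#' @export
writeDiffTSV <- function(diff, file) {
    utils::write.table(diff, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(file)
}

#' @rdname writeDiffTSV
#' @export
readDiffTSV <- function(file) {
    utils::read.delim(file, stringsAsFactors = FALSE, na.strings = "NA")
}

#' Read/write the pipeline configuration as YAML
#'
#' Unknown keys are rejected on read via [simConfig()]'s validation.
#'
#' @param config configuration list
#' @param file path
#' @export
writeConfigYAML <- function(config, file) {
    yaml::write_yaml(config, file, precision = 15)
    invisible(file)
}

#' @rdname writeConfigYAML
#' @export
readConfigYAML <- function(file) {
    raw <- yaml::read_yaml(file)
    raw$seed <- NULL
    do.call(simConfig, raw)
}

#' Hash of a configuration (for provenance logging)
#'
#' @param config configuration list
#' @return md5 hex string of the YAML serialization
#' @export
configHash <- function(config) {
    tf <- tempfile(fileext = ".yaml")
    on.exit(unlink(tf))
    yaml::write_yaml(config, tf)
    unname(tools::md5sum(tf))
}

#' Write a SimBundle to a directory of plain-text files
#'
#' Emits count TSVs per assay, the combined sample sheet, per-sample CTSS
#' files, spike tables, gene models (TSV and BED6), the truth table and
#' the configuration; paths and seed are logged to `MANIFEST.tsv`.
#'
#' @param bundle a [SimBundle-class]
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
writeDataset <- function(bundle, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c()
    for (nm in names(bundle@assays)) {
        f <- file.path(dir, paste0("counts_", nm, ".tsv"))
        writeCountsTSV(assayCounts(bundle, nm), f)
        paths[paste0("counts_", nm)] <- f
    }
    f <- file.path(dir, "samples.tsv")
    writeSampleSheet(sampleSheet(bundle), f); paths["samples"] <- f
    for (nm in names(bundle@ctss)) {
        f <- file.path(dir, paste0("ctss_", nm, ".ctss"))
        writeCTSS(bundle@ctss[[nm]], f)
        paths[paste0("ctss_", nm)] <- f
    }
    sp <- spikeTables(bundle)
    if (!is.null(sp$ercc)) {
        f <- file.path(dir, "spikes_ercc.tsv")
        writeCountsTSV(sp$ercc, f); paths["spikes_ercc"] <- f
    }
    if (!is.null(sp$pombe)) {
        f <- file.path(dir, "spikes_pombe.tsv")
        utils::write.table(data.frame(sample = names(sp$pombe),
                                      total = as.numeric(sp$pombe)),
                           f, sep = "\t", quote = FALSE, row.names = FALSE)
        paths["spikes_pombe"] <- f
    }
    f <- file.path(dir, "gene_models.tsv")
    writeGeneModelsTSV(geneModels(bundle), f); paths["gene_models"] <- f
    writeGeneModelsBED(geneModels(bundle), file.path(dir, "gene_models.bed"))
    f <- file.path(dir, "truth.tsv")
    utils::write.table(as.data.frame(simTruth(bundle)), f, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths["truth"] <- f
    f <- file.path(dir, "config.yaml")
    writeConfigYAML(simConfigOf(bundle), f); paths["config"] <- f
    manifest <- data.frame(key = names(paths), path = unname(paths),
                           seed = simConfigOf(bundle)$seed,
                           config_md5 = configHash(simConfigOf(bundle)))
    utils::write.table(manifest, file.path(dir, "MANIFEST.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(dir)
}
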