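#' SimBundle: a complete simulated multi-assay experiment
#'
#' A `SimBundle` holds everything one simulation run produces: one
#' [SummarizedExperiment::SummarizedExperiment] of raw counts per assay
#' (`rna`, `cage`, `rpf`, `chip`, plus `rna_ercc` when ERCC spike-ins are
#' simulated), per-sample CTSS tables for the CAGE samples, spike-in count
#' tables, the planted per-gene ground truth, the gene models, and the
#' configuration that generated it all.
#'
#' @slot assays named list of `SummarizedExperiment` objects, one per assay;
#'   rows are genes (with the gene models as `rowRanges`), columns are
#'   samples described by their `colData`.
#' @slot expectations named list of matrices of noise-free expected counts,
#'   parallel to `assays`.
#' @slot ctss named list (one element per CAGE sample) of 4-column CTSS
#'   data frames: `chrom`, `pos` (1-based), `strand`, `count`.
#' @slot spikes list with elements `ercc` (spike x sample count matrix, with
#'   the expected counts in `attr(,"expectation")`) and `pombe` (named
#'   per-sample totals of foreign-genome reads for the ChIP samples).
#' @slot truth `DataFrame` of planted per-gene simulator parameters and
#'   labels (kinetic rates, dependence class, mechanism class, initiation
#'   strength, TSS position).
#' @slot geneModels `GRanges` of the simulated genes, carrying transcript
#'   length, CDS length, start-codon coordinate and TSS position.
#' @slot config the fully-resolved configuration list (see [simConfig()]).
#'
#' @seealso [generateDataset()], [simConfig()]
#' @export
setClass("SimBundle", slots = c(
    assays = "list",
    expectations = "list",
    ctss = "list",
    spikes = "list",
    truth = "DataFrame",
    geneModels = "GRanges",
    config = "list"
))

setValidity("SimBundle", function(object) {
    msg <- character()
    ng <- length(object@geneModels)
    for (nm in names(object@assays)) {
        se <- object@assays[[nm]]
        if (!is(se, "SummarizedExperiment"))
            msg <- c(msg, sprintf("assay '%s' is not a SummarizedExperiment", nm))
        else {
            cnt <- SummarizedExperiment::assay(se)
            if (nrow(cnt) != ng)
                msg <- c(msg, sprintf("assay '%s' has %d rows for %d genes",
                                      nm, nrow(cnt), ng))
            if (any(cnt < 0) || any(cnt != floor(cnt)))
                msg <- c(msg, sprintf("assay '%s' has negative or non-integer counts", nm))
        }
    }
    if (nrow(object@truth) != ng)
        msg <- c(msg, "truth table and gene models disagree on gene number")
    if (length(msg)) msg else TRUE
})

#' @describeIn SimBundle raw count matrix for one assay
#' @param object,x a `SimBundle`
#' @param assay assay name, e.g. `"rna"`, `"cage"`, `"rpf"`, `"chip"`
#' @export
setGeneric("assayCounts", function(object, assay) standardGeneric("assayCounts"))

#' @rdname SimBundle-class
#' @export
setMethod("assayCounts", "SimBundle", function(object, assay) {
    se <- object@assays[[assay]]
    if (is.null(se)) stop("no assay '", assay, "' in this bundle")
    SummarizedExperiment::assay(se)
})

#' @describeIn SimBundle noise-free expected count matrix for one assay
#' @export
setGeneric("assayExpectation", function(object, assay) standardGeneric("assayExpectation"))

#' @rdname SimBundle-class
#' @export
setMethod("assayExpectation", "SimBundle", function(object, assay) {
    m <- object@expectations[[assay]]
    if (is.null(m)) stop("no assay '", assay, "' in this bundle")
    m
})

#' @describeIn SimBundle combined sample sheet across all assays
#' @export
setGeneric("sampleSheet", function(object) standardGeneric("sampleSheet"))

#' @rdname SimBundle-class
#' @export
setMethod("sampleSheet", "SimBundle", function(object) {
    keep <- c("sample", "assay", "genotype", "replicate")
    sheets <- lapply(object@assays, function(se)
        as.data.frame(SummarizedExperiment::colData(se))[, keep])
    out <- do.call(rbind, sheets)
    rownames(out) <- NULL
    out
})

#' @describeIn SimBundle planted per-gene ground truth
#' @export
setGeneric("simTruth", function(object) standardGeneric("simTruth"))

#' @rdname SimBundle-class
#' @export
setMethod("simTruth", "SimBundle", function(object) object@truth)

#' @describeIn SimBundle gene models as a `GRanges`
#' @export
setGeneric("geneModels", function(object) standardGeneric("geneModels"))

#' @rdname SimBundle-class
#' @export
setMethod("geneModels", "SimBundle", function(object) object@geneModels)

#' @describeIn SimBundle CTSS tables (list, one per CAGE sample)
#' @export
setGeneric("ctssTables", function(object) standardGeneric("ctssTables"))

#' @rdname SimBundle-class
#' @export
setMethod("ctssTables", "SimBundle", function(object) object@ctss)

#' @describeIn SimBundle spike-in tables (`ercc` matrix, `pombe` totals)
#' @export
setGeneric("spikeTables", function(object) standardGeneric("spikeTables"))

#' @rdname SimBundle-class
#' @export
setMethod("spikeTables", "SimBundle", function(object) object@spikes)

#' @describeIn SimBundle resolved configuration list
#' @export
setGeneric("simConfigOf", function(object) standardGeneric("simConfigOf"))

#' @rdname SimBundle-class
#' @export
setMethod("simConfigOf", "SimBundle", function(object) object@config)

setMethod("show", "SimBundle", function(object) {
    cat("SimBundle with", length(object@geneModels), "genes\n")
    for (nm in names(object@assays)) {
        se <- object@assays[[nm]]
        cd <- SummarizedExperiment::colData(se)
        cat(sprintf("  %-8s %2d samples (%s)\n", nm, ncol(se),
                    paste(unique(cd$genotype), collapse = ", ")))
    }
    cat("  CTSS tables:", length(object@ctss), "\n")
    if (!is.null(object@spikes$ercc))
        cat("  ERCC spikes:", nrow(object@spikes$ercc), "x",
            ncol(object@spikes$ercc), "\n")
    dep <- table(object@truth$dep_class)
    cat("  dependence classes:",
        paste(names(dep), dep, sep = "=", collapse = ", "), "\n")
    cat("  noise:", if (isTRUE(object@config$noise$enabled)) "on" else "off",
        " seed:", object@config$seed, "\n")
})
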