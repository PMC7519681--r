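.DRIVER_CLASSES <- c("TSG", "ONCOGENE", "TSG_AND_ONCOGENE", "PREDICTED",
                     "OTHER")

#' Classify genes against tumor-suppressor / oncogene lists
#'
#' Three-group driver classification: genes in the curated
#' tumor-suppressor (TSG) or oncogene lists, genes only in the predicted
#' list, and all others. Membership in both curated lists yields
#' `TSG_AND_ONCOGENE`; curated lists take precedence over the predicted
#' list.
#'
#' @param genes character vector of gene symbols.
#' @param tsgList,oncoList,predictedList character vectors of symbols
#'   (see [readGeneList()]).
#' @return data.frame with `gene` and `class` (factor over TSG,
#'   ONCOGENE, TSG_AND_ONCOGENE, PREDICTED, OTHER).
#' @examples
#' classifyDriverGenes(c("Nras", "Plekha5", "Xyz"),
#'                     tsgList = "Trp53", oncoList = "Nras",
#'                     predictedList = "Plekha5")
#' @export
classifyDriverGenes <- function(genes, tsgList = character(),
                                oncoList = character(),
                                predictedList = character()) {
    cls <- ifelse(genes %in% tsgList & genes %in% oncoList,
                  "TSG_AND_ONCOGENE",
           ifelse(genes %in% tsgList, "TSG",
           ifelse(genes %in% oncoList, "ONCOGENE",
           ifelse(genes %in% predictedList, "PREDICTED", "OTHER"))))
    data.frame(gene = genes,
               class = factor(cls, levels = .DRIVER_CLASSES),
               stringsAsFactors = FALSE)
}

#' Read a one-symbol-per-line gene list
#'
#' @param path text file, one gene symbol per line; blank lines and
#'   lines starting with `#` are skipped.
#' @return character vector.
#' @export
readGeneList <- function(path) {
    if (!file.exists(path)) stop("gene list file not found: ", path)
    x <- trimws(readLines(path))
    x[nzchar(x) & !startsWith(x, "#")]
}

#' Gene-by-cell oncoplot matrix
#'
#' Collapses the site-level ternary matrix to gene level: a cell is "M"
#' for a gene when any of the gene's sites is mutant, otherwise "W" when
#' any site is covered wild type, otherwise ".". Rows are ordered by
#' mutant frequency (descending), ties broken alphabetically.
#'
#' @param mm a [MutationMatrix-class] with `gene` row metadata.
#' @param annotations optional data.frame from [classifyDriverGenes()];
#'   its `class` column is carried into the output attribute
#'   `"driverClass"`.
#' @return character matrix, genes x cells, ordered by frequency.
#' @export
oncoplotMatrix <- function(mm, annotations = NULL) {
    st <- statusMatrix(mm)
    if (!nrow(st))
        return(matrix(character(), 0L, ncol(st),
                      dimnames = list(NULL, colnames(st))))
    genes <- rowData(mm)$gene
    if (is.null(genes)) stop("mutation matrix has no gene annotation")
    ug <- unique(genes)
    out <- matrix(.STATUS_NOCOV, length(ug), ncol(st),
                  dimnames = list(ug, colnames(st)))
    for (g in ug) {
        sub <- st[genes == g, , drop = FALSE]
        anyM <- apply(sub == .STATUS_MUTANT, 2L, any)
        anyW <- apply(sub == .STATUS_WILDTYPE, 2L, any)
        out[g, anyM] <- .STATUS_MUTANT
        out[g, !anyM & anyW] <- .STATUS_WILDTYPE
    }
    freq <- rowMeans(out == .STATUS_MUTANT)
    ord <- order(-freq, rownames(out))
    out <- out[ord, , drop = FALSE]
    if (!is.null(annotations))
        attr(out, "driverClass") <- setNames(
            as.character(annotations$class), annotations$gene)[rownames(out)]
    out
}

#' Run the full simulate-to-report pipeline
#'
#' Orchestrates one deterministic end-to-end run: simulate a
#' clone-structured scWES experiment, call somatic SNVs through the
#' filter cascade, infer CNVs, build the clonal tree and saturation
#' curve, fit signature exposures, classify drivers, and write all
#' tabular outputs plus a JSON run manifest to `outdir`.
#'
#' @param config named list with optional elements `seed`, `nClones`,
#'   `snvsPerEdge`, `cnvSpec`, `fractions`, `genesPerChrom`,
#'   `simulation` (arguments to [simConfig()]), `thresholds` (arguments
#'   to [filterThresholds()]), `cnv` (arguments to [cnvParams()]),
#'   `catalog` (path to a signature catalog TSV; default: a synthetic
#'   catalog), `exposureWeights`, `tsgList`, `oncoList`,
#'   `predictedList` (paths), `nPerm`.
#' @param outdir output directory (created if missing).
#' @return invisibly, a list with the main in-memory results
#'   (`snv`, `cnv`, `tree`, `subclones`, `saturation`, `fit`,
#'   `oncoplot`, `manifest`).
#' @export
runAll <- function(config = list(), outdir) {
    if (missing(outdir)) stop("outdir is required")
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    seed <- config$seed %||% 1L
    simArgs <- config$simulation %||% list()
    simArgs$seed <- seed
    cfg <- do.call(simConfig, simArgs)
    gm <- simGeneModel(genesPerChrom = config$genesPerChrom %||% 100L)
    tree <- buildCloneTree(config$nClones %||% 4L,
                           config$snvsPerEdge %||% 20L,
                           cnvSpec = config$cnvSpec,
                           fractions = config$fractions,
                           geneModel = gm, seed = seed)
    sim <- simulateExperiment(tree, cfg, gm)

    ## matched normal: pure normal of the first sample's bulk mix
    normal <- sim$bulk[[1L]]$normalSites
    thr <- do.call(filterThresholds, config$thresholds %||% list())
    snv <- runSnvPipeline(sim$siteCounts, normal,
                          bulk = sim$bulk[[1L]]$bulkSites, thresholds = thr)

    params <- do.call(cnvParams, config$cnv %||% list())
    cnv <- runCnvPipeline(sim$geneCounts, gm,
                          control = sim$bulk[[1L]]$normalGenes,
                          params = params)

    mm <- snv$matrix
    bin <- asBinaryMatrix(mm)
    clonal <- NULL
    subclones <- data.frame()
    if (nrow(mm) >= 1L && ncol(mm) >= 4L) {
        clonal <- ratchetSearch(bin, nIters = config$nIters %||% 5L,
                                seed = seed)
        subclones <- findSubclones(clonal$tree)
        ape::write.tree(clonal$tree, file.path(outdir, "tree.nwk"))
    }
    snvSets <- lapply(seq_len(ncol(mm)), function(j)
        rownames(mm)[statusMatrix(mm)[, j] == .STATUS_MUTANT])
    names(snvSets) <- colnames(mm)
    sat <- saturationCurve(snvSets, nPerm = config$nPerm %||% 100L,
                           seed = seed)

    catalog <- if (!is.null(config$catalog))
        readSignatureCatalog(config$catalog)
    else simSignatureCatalog(4L, seed = seed)
    truthKeys <- paste(sim$truth$chrom, sim$truth$pos, sep = ":")
    called <- sim$truth[truthKeys %in% rownames(mm), , drop = FALSE]
    spectrum <- buildSpectrum(called)
    fit <- if (sum(spectrum@counts) > 0) fitExposures(spectrum, catalog)

    readList <- function(p) if (is.null(p)) character() else readGeneList(p)
    ann <- classifyDriverGenes(unique(rowData(mm)$gene),
                               readList(config$tsgList),
                               readList(config$oncoList),
                               readList(config$predictedList))
    oncop <- if (nrow(mm)) oncoplotMatrix(mm, ann) else
        matrix(character(), 0, 0)

    wt <- function(x, f) {
        write.table(x, file.path(outdir, f), sep = "\t", quote = FALSE,
                    row.names = FALSE)
        f
    }
    files <- c(
        wt(sim$truth, "truth_snvs.tsv"),
        wt(sim$assignments, "truth_cells.tsv"),
        wt(as.data.frame(statusMatrix(mm)), "mutation_matrix.tsv"),
        wt(snv$log, "rejection_log.tsv"),
        wt(as.data.frame(assay(cnv, "scaled")), "cnv_scaled.tsv"),
        wt(subclones, "subclones.tsv"),
        wt(sat, "saturation.tsv"),
        wt(ann, "driver_classes.tsv"),
        wt(as.data.frame(oncop), "oncoplot.tsv"))
    writeCloneNewick(tree, file.path(outdir, "clone_tree.nwk"))
    writeSiteVcf(sim$siteCounts, file.path(outdir, "cells.vcf"))

    manifest <- list(
        tool = "scExome",
        version = as.character(utils::packageVersion("scExome")),
        seed = seed,
        stageCounts = as.list(snv$stageCounts),
        records = list(
            cells = ncol(mm), sites = nrow(mm),
            genes = nrow(cnv), subclones = nrow(subclones)),
        thresholds = list(bulkMinCov = thr@bulkMinCov,
                          cellMinCov = thr@cellMinCov,
                          minCells = thr@minCells, pMax = thr@pMax),
        files = files)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(list(snv = snv, cnv = cnv,
                   tree = if (!is.null(clonal)) clonal$tree,
                   score = if (!is.null(clonal)) clonal$score,
                   subclones = subclones, saturation = sat, fit = fit,
                   oncoplot = oncop, manifest = manifest))
}
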