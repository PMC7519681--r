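#' @import methods
#' @importFrom stats rpois rbinom rnorm rmultinom phyper sd setNames
#' @importFrom utils read.table write.table head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
#' @importFrom S4Vectors DataFrame metadata "metadata<-"
NULL

## ternary status codes used throughout the mutation matrix
.STATUS_MUTANT <- "M"
.STATUS_WILDTYPE <- "W"
.STATUS_NOCOV <- "."

#' Simulation configuration for the clone-structured scWES simulator
#'
#' Holds the per-cell noise model parameters: mean sequencing depth at a
#' site, the lognormal SD of the per-cell-per-locus whole-genome
#' amplification (WGA) factor, the per-allele allelic dropout (ADO)
#' probability, the per-read miscall probability, bulk tumor purity, the
#' expected total exome reads per cell, and the RNG seed.
#'
#' @slot nCellsPerSample integer, cells drawn per sample.
#' @slot meanDepth numeric, expected reads covering a site before WGA bias.
#' @slot wgaSigma numeric, SD (log scale) of the lognormal amplification
#'   factor applied independently per cell and locus.
#' @slot adoRate numeric in [0,1], probability each chromosomal copy of a
#'   locus drops out of the amplified library.
#' @slot seqErrorRate numeric in [0,1], probability a read reports the
#'   listed alternate base at a site where the template is reference.
#' @slot bulkPurity numeric in [0,1], tumor fraction of the bulk mixture.
#' @slot librarySize numeric, expected neutral-genome total reads per cell.
#' @slot seed integer RNG seed; a fixed seed makes all outputs reproducible.
#' @exportClass SimConfig
setClass("SimConfig", representation(
    nCellsPerSample = "integer",
    meanDepth = "numeric",
    wgaSigma = "numeric",
    adoRate = "numeric",
    seqErrorRate = "numeric",
    bulkPurity = "numeric",
    librarySize = "numeric",
    seed = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    rate01 <- function(x, nm) {
        if (length(x) != 1L || is.na(x) || x < 0 || x > 1)
            sprintf("%s must be a single value in [0, 1]", nm)
        else character()
    }
    msg <- c(msg, rate01(object@adoRate, "adoRate"),
             rate01(object@seqErrorRate, "seqErrorRate"),
             rate01(object@bulkPurity, "bulkPurity"))
    if (object@meanDepth < 0) msg <- c(msg, "meanDepth must be >= 0")
    if (object@wgaSigma < 0) msg <- c(msg, "wgaSigma must be >= 0")
    if (object@librarySize < 0) msg <- c(msg, "librarySize must be >= 0")
    if (object@nCellsPerSample < 0L) msg <- c(msg, "nCellsPerSample must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Construct a [SimConfig-class]
#'
#' Defaults describe a C1/WGA-style single-cell WES experiment: 20 cells per
#' sample, 200x site depth, lognormal WGA sigma 0.5, 10% allelic dropout,
#' 1e-3 sequencing error, bulk purity 0.6.
#'
#' @param nCellsPerSample cells per sample.
#' @param meanDepth expected per-site read depth.
#' @param wgaSigma lognormal SD of the WGA amplification factor.
#' @param adoRate per-allele, per-locus dropout probability.
#' @param seqErrorRate per-read miscall probability (to the listed alt).
#' @param bulkPurity tumor purity of simulated bulk samples.
#' @param librarySize expected neutral-genome total reads per cell.
#' @param seed integer RNG seed.
#' @return A `SimConfig` object.
#' @examples
#' cfg <- simConfig(seed = 7)
#' cfg
#' @export
simConfig <- function(nCellsPerSample = 20L, meanDepth = 200, wgaSigma = 0.5,
                      adoRate = 0.1, seqErrorRate = 1e-3, bulkPurity = 0.6,
                      librarySize = 2e6, seed = 1L) {
    new("SimConfig", nCellsPerSample = as.integer(nCellsPerSample),
        meanDepth = meanDepth, wgaSigma = wgaSigma, adoRate = adoRate,
        seqErrorRate = seqErrorRate, bulkPurity = bulkPurity,
        librarySize = librarySize, seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig\n",
        sprintf("  cells/sample: %d  meanDepth: %g  librarySize: %g\n",
                object@nCellsPerSample, object@meanDepth, object@librarySize),
        sprintf("  wgaSigma: %g  adoRate: %g  seqErrorRate: %g  bulkPurity: %g\n",
                object@wgaSigma, object@adoRate, object@seqErrorRate,
                object@bulkPurity),
        sprintf("  seed: %d\n", object@seed), sep = "")
})

#' Clone tree ground truth for the simulator
#'
#' A rooted clone genealogy. Each clone acquires a private set of somatic
#' SNVs on the edge leading into it, so a clone's full genotype is the
#' union of the edge sets along its root path. Copy-number events are
#' attached per clone and inherited by descendants unless overridden.
#'
#' @slot clones data.frame with columns `clone_id`, `parent_id`
#'   (`NA` for the root).
#' @slot snvAssignments named list (by clone_id) of site data.frames with
#'   columns `chrom`, `pos`, `ref`, `alt`, `context`, `gene`.
#' @slot cnvEvents named list (by clone_id) of data.frames with columns
#'   `chrom`, `start`, `end`, `cn` (total integer copy number).
#' @slot fractions named list (by sample_id) of named numeric clone
#'   fractions summing to 1.
#' @exportClass CloneTree
setClass("CloneTree", representation(
    clones = "data.frame",
    snvAssignments = "list",
    cnvEvents = "list",
    fractions = "list"
))

setValidity("CloneTree", function(object) {
    msg <- character()
    cl <- object@clones
    if (!all(c("clone_id", "parent_id") %in% names(cl)))
        return("clones must have clone_id and parent_id columns")
    roots <- sum(is.na(cl$parent_id))
    if (roots != 1L) msg <- c(msg, "clone tree must have exactly one root")
    if (anyDuplicated(cl$clone_id)) msg <- c(msg, "duplicate clone_id")
    bad <- setdiff(cl$parent_id[!is.na(cl$parent_id)], cl$clone_id)
    if (length(bad)) msg <- c(msg, "parent_id refers to unknown clone")
    keys <- unlist(lapply(object@snvAssignments, function(s)
        if (nrow(s)) paste(s$chrom, s$pos, s$ref, s$alt) else character()))
    if (anyDuplicated(keys))
        msg <- c(msg, "SNV sets on distinct edges must be disjoint")
    for (sm in names(object@fractions)) {
        fr <- object@fractions[[sm]]
        if (abs(sum(fr) - 1) > 1e-9)
            msg <- c(msg, sprintf("fractions for sample '%s' do not sum to 1", sm))
        if (any(fr < 0 | fr > 1))
            msg <- c(msg, sprintf("fractions for sample '%s' outside [0,1]", sm))
        if (!all(names(fr) %in% cl$clone_id))
            msg <- c(msg, sprintf("fractions for sample '%s' name unknown clones", sm))
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "CloneTree", function(object) {
    n <- nrow(object@clones)
    nsnv <- sum(vapply(object@snvAssignments, nrow, 0L))
    cat(sprintf("CloneTree with %d clone%s, %d somatic SNVs, %d sample%s\n",
                n, if (n == 1) "" else "s", nsnv, length(object@fractions),
                if (length(object@fractions) == 1) "" else "s"))
})

#' Somatic-filtering thresholds
#'
#' The filter cascade's knobs: minimum coverage/variant reads for bulk (20/5)
#' and single cells (10/3), the three-cell recurrence rule, the 10% maximum
#' normal VAF and 10% minimum tumor VAF, the one-sided Fisher p cutoff
#' 5e-3, the 2-read rescue threshold, and the minimum depth (5) at which a
#' rescue-stage site with < 2 alt reads is asserted wild type rather than
#' no-coverage.
#'
#' @slot bulkMinCov,bulkMinVar,cellMinCov,cellMinVar,minCells,rescueMinVar,wtAssertMinDepth integer thresholds.
#' @slot maxNormalVaf,minTumorVaf,pMax numeric thresholds.
#' @exportClass FilterThresholds
setClass("FilterThresholds", representation(
    bulkMinCov = "integer", bulkMinVar = "integer",
    cellMinCov = "integer", cellMinVar = "integer",
    minCells = "integer", maxNormalVaf = "numeric",
    minTumorVaf = "numeric", pMax = "numeric",
    rescueMinVar = "integer", wtAssertMinDepth = "integer"
))

setValidity("FilterThresholds", function(object) {
    msg <- character()
    cnt <- c(bulkMinCov = object@bulkMinCov, bulkMinVar = object@bulkMinVar,
             cellMinCov = object@cellMinCov, cellMinVar = object@cellMinVar,
             minCells = object@minCells, rescueMinVar = object@rescueMinVar,
             wtAssertMinDepth = object@wtAssertMinDepth)
    if (any(cnt < 0L)) msg <- c(msg, "count thresholds must be >= 0")
    if (object@maxNormalVaf < 0 || object@maxNormalVaf > 1 ||
        object@minTumorVaf < 0 || object@minTumorVaf > 1)
        msg <- c(msg, "VAF thresholds must be in [0, 1]")
    if (object@pMax <= 0 || object@pMax >= 1)
        msg <- c(msg, "pMax must be in (0, 1)")
    if (length(msg)) msg else TRUE
})

#' Construct [FilterThresholds-class] with the published defaults
#'
#' @param bulkMinCov,bulkMinVar bulk minimum depth and alt-read counts.
#' @param cellMinCov,cellMinVar single-cell minimum depth and alt reads.
#' @param minCells minimum number of cells a site must pass the per-cell
#'   filter in (recurrence rule).
#' @param maxNormalVaf maximum VAF tolerated in the matched normal.
#' @param minTumorVaf minimum tumor VAF.
#' @param pMax one-sided Fisher somatic p-value cutoff.
#' @param rescueMinVar alt reads that re-assert a known site as mutant in
#'   any cell at the rescue stage.
#' @param wtAssertMinDepth depth below which a non-mutant rescue entry is
#'   reported as no-coverage rather than wild type.
#' @return A `FilterThresholds` object.
#' @examples
#' filterThresholds()
#' @export
filterThresholds <- function(bulkMinCov = 20L, bulkMinVar = 5L,
                             cellMinCov = 10L, cellMinVar = 3L,
                             minCells = 3L, maxNormalVaf = 0.10,
                             minTumorVaf = 0.10, pMax = 5e-3,
                             rescueMinVar = 2L, wtAssertMinDepth = 5L) {
    new("FilterThresholds",
        bulkMinCov = as.integer(bulkMinCov), bulkMinVar = as.integer(bulkMinVar),
        cellMinCov = as.integer(cellMinCov), cellMinVar = as.integer(cellMinVar),
        minCells = as.integer(minCells), maxNormalVaf = maxNormalVaf,
        minTumorVaf = minTumorVaf, pMax = pMax,
        rescueMinVar = as.integer(rescueMinVar),
        wtAssertMinDepth = as.integer(wtAssertMinDepth))
}

setMethod("show", "FilterThresholds", function(object) {
    cat("FilterThresholds\n",
        sprintf("  bulk: depth >= %d, alt >= %d\n", object@bulkMinCov,
                object@bulkMinVar),
        sprintf("  cell: depth >= %d, alt >= %d, recurrence >= %d cells\n",
                object@cellMinCov, object@cellMinVar, object@minCells),
        sprintf("  normal VAF <= %.2f, tumor VAF >= %.2f, Fisher p < %g\n",
                object@maxNormalVaf, object@minTumorVaf, object@pMax),
        sprintf("  rescue: alt >= %d mutant, depth >= %d wild type\n",
                object@rescueMinVar, object@wtAssertMinDepth), sep = "")
})

#' Ternary per-cell mutation matrix
#'
#' A [SummarizedExperiment-class] with one character assay `"status"`
#' holding sites (rows) by cells (columns) entries in \{"M", "W", "."\}
#' (mutant, wild type, no coverage). Row metadata carries `chrom`, `pos`,
#' `ref`, `alt` and the annotated `gene`; column metadata carries
#' `cell_id`, `sample_id` and optionally `individual`.
#'
#' @exportClass MutationMatrix
setClass("MutationMatrix", contains = "SummarizedExperiment")

setValidity("MutationMatrix", function(object) {
    if (!"status" %in% names(assays(object)))
        return("MutationMatrix requires a 'status' assay")
    st <- assay(object, "status")
    ok <- st %in% c(.STATUS_MUTANT, .STATUS_WILDTYPE, .STATUS_NOCOV)
    if (!all(ok)) return("status entries must be 'M', 'W' or '.'")
    need <- c("chrom", "pos", "ref", "alt")
    if (nrow(object) && !all(need %in% names(rowData(object))))
        return("rowData must contain chrom, pos, ref, alt")
    TRUE
})

#' Build a [MutationMatrix-class] from a status matrix
#'
#' @param status character matrix (sites x cells) of "M"/"W"/"." codes.
#' @param siteInfo data.frame with one row per site: `chrom`, `pos`,
#'   `ref`, `alt` and optionally `gene`.
#' @param cellInfo optional data.frame of per-cell metadata.
#' @return A `MutationMatrix`.
#' @examples
#' st <- matrix(c("M", "W", ".", "M"), nrow = 2,
#'              dimnames = list(NULL, c("c1", "c2")))
#' si <- data.frame(chrom = "chr1", pos = c(100L, 200L), ref = "A",
#'                  alt = "T", gene = c("G1", "G2"))
#' MutationMatrix(st, si)
#' @export
MutationMatrix <- function(status, siteInfo, cellInfo = NULL) {
    status <- as.matrix(status)
    rownames(status) <- paste(siteInfo$chrom, siteInfo$pos, sep = ":")
    cd <- if (is.null(cellInfo)) {
        DataFrame(cell_id = colnames(status))
    } else DataFrame(cellInfo)
    new("MutationMatrix", SummarizedExperiment(
        assays = list(status = status), rowData = DataFrame(siteInfo),
        colData = cd))
}

#' Extract the sites-by-cells ternary status matrix
#'
#' @param x a [MutationMatrix-class].
#' @return character matrix of "M"/"W"/"." codes.
#' @export
statusMatrix <- function(x) assay(x, "status")

setMethod("show", "MutationMatrix", function(object) {
    st <- statusMatrix(object)
    cat(sprintf("MutationMatrix: %d site%s x %d cell%s (M: %d, W: %d, .: %d)\n",
                nrow(object), if (nrow(object) == 1) "" else "s",
                ncol(object), if (ncol(object) == 1) "" else "s",
                sum(st == .STATUS_MUTANT), sum(st == .STATUS_WILDTYPE),
                sum(st == .STATUS_NOCOV)))
})

#' Smoothed and scaled copy-number profile
#'
#' A [SummarizedExperiment-class] with genes (rows, genomic order) by cells
#' (columns) assays: `"scaled"` (moving-averaged, centrally scaled
#' coverage) and `"mask"` (logical; TRUE where the entry is suppressed by
#' the low-amplitude band or the wild-type-control mask). Row metadata
#' carries the gene model plus a per-gene `control_masked` flag; pipeline
#' parameters live in `metadata(x)$params`.
#'
#' @exportClass CnvProfile
setClass("CnvProfile", contains = "SummarizedExperiment")

setValidity("CnvProfile", function(object) {
    nm <- names(assays(object))
    if (!all(c("scaled", "mask") %in% nm))
        return("CnvProfile requires 'scaled' and 'mask' assays")
    if (!is.logical(assay(object, "mask")))
        return("'mask' assay must be logical")
    TRUE
})

setMethod("show", "CnvProfile", function(object) {
    m <- assay(object, "mask")
    cat(sprintf("CnvProfile: %d gene%s x %d cell%s (%.1f%% masked)\n",
                nrow(object), if (nrow(object) == 1) "" else "s",
                ncol(object), if (ncol(object) == 1) "" else "s",
                if (length(m)) 100 * mean(m) else 0))
})

#' 96-channel mutation spectrum
#'
#' Counts of single-base substitutions in the pyrimidine-strand convention:
#' 6 substitution classes (C>A, C>G, C>T, T>A, T>C, T>G) by 4 possible 5'
#' and 4 possible 3' neighbours. The 6-class marginal is available via
#' [sixClassSpectrum()].
#'
#' @slot counts named numeric vector of length 96 (names like `"A[C>A]A"`).
#' @exportClass MutationSpectrum
setClass("MutationSpectrum", representation(counts = "numeric"))

setValidity("MutationSpectrum", function(object) {
    if (length(object@counts) != 96L)
        return("spectrum must have 96 channels")
    if (!identical(names(object@counts), spectrumChannels()))
        return("channel names must follow the canonical 96-channel order")
    if (any(object@counts < 0)) return("counts must be non-negative")
    TRUE
})

setMethod("show", "MutationSpectrum", function(object) {
    six <- sixClassSpectrum(object)
    cat(sprintf("MutationSpectrum: %g SNVs\n", sum(object@counts)))
    print(six)
})

#' Reference signature catalog
#'
#' Signatures (rows) by 96 substitution channels (columns); each row is a
#' probability distribution over channels (sums to 1).
#'
#' @slot probs numeric matrix, signatures x 96, rows summing to 1.
#' @exportClass SignatureCatalog
setClass("SignatureCatalog", representation(probs = "matrix"))

setValidity("SignatureCatalog", function(object) {
    p <- object@probs
    if (ncol(p) != 96L) return("catalog must have 96 channels")
    if (!identical(colnames(p), spectrumChannels()))
        return("catalog columns must follow the canonical 96-channel order")
    if (any(p < 0)) return("catalog entries must be non-negative")
    if (any(abs(rowSums(p) - 1) > 1e-9))
        return("catalog rows must sum to 1 (+- 1e-9)")
    TRUE
})

#' Construct a [SignatureCatalog-class]
#' @param probs signatures x 96 matrix; rows are normalized to sum 1 when
#'   within 1e-6 of doing so, otherwise validity fails.
#' @return A `SignatureCatalog`.
#' @export
SignatureCatalog <- function(probs) {
    probs <- as.matrix(probs)
    if (is.null(rownames(probs)))
        rownames(probs) <- paste0("Signature.", seq_len(nrow(probs)))
    new("SignatureCatalog", probs = probs)
}

setMethod("show", "SignatureCatalog", function(object) {
    cat(sprintf("SignatureCatalog: %d signatures x 96 channels\n",
                nrow(object@probs)))
    cat(" ", paste(rownames(object@probs), collapse = ", "), "\n")
})

#' Fitted signature exposures
#'
#' @slot weights named numeric exposures in [0,1]; after the reporting
#'   cutoff, surviving weights sum to 1.
#' @slot rawWeights exposures before the cutoff was applied.
#' @slot rss residual sum of squares of the reported (post-cutoff) fit
#'   against the normalized spectrum.
#' @slot dropped logical flag per signature: TRUE where a nonzero raw
#'   weight fell below the cutoff.
#' @slot cutoff the reporting cutoff used.
#' @exportClass ExposureFit
setClass("ExposureFit", representation(
    weights = "numeric", rawWeights = "numeric", rss = "numeric",
    dropped = "logical", cutoff = "numeric"))

setValidity("ExposureFit", function(object) {
    if (any(object@weights < 0)) return("weights must be non-negative")
    s <- sum(object@weights)
    if (s > 0 && abs(s - 1) > 1e-9)
        return("nonzero post-cutoff weights must sum to 1")
    TRUE
})

setMethod("show", "ExposureFit", function(object) {
    cat("ExposureFit (cutoff", object@cutoff, ")\n")
    w <- object@weights[object@weights > 0]
    if (length(w)) print(round(sort(w, decreasing = TRUE), 4))
    else cat("  all exposures below cutoff\n")
    cat(sprintf("  residual sum of squares: %.3g\n", object@rss))
})

#' Exposure weights after cutoff and renormalization
#'
#' @param x an [ExposureFit-class].
#' @return named numeric exposure vector.
#' @export
exposures <- function(x) x@weights
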