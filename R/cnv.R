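#' CNV pipeline parameters
#'
#' @param window moving-average window in genes (default 100).
#' @param lowBand closed low-amplitude band removed before plotting
#'   (default `c(-1, 1)`).
#' @param controlRoundCut absolute rounded control value at or above
#'   which a gene is masked by the wild-type control (default 1).
#' @param highBandCut retention cut for the high-amplitude comparison
#'   mode (default 1.5).
#' @param scaling `"gene"` (per-gene z-score across cells, default) or
#'   `"cell"` (per-cell centering).
#' @param boundary `"genome"` (one ordered list; windows may span
#'   chromosome junctions, default) or `"chromosome"` (windows restart
#'   at each chromosome).
#' @param logTransform apply log2(x + 1) to RPKM before smoothing.
#' @return a named list of validated parameters.
#' @export
cnvParams <- function(window = 100L, lowBand = c(-1, 1),
                      controlRoundCut = 1, highBandCut = 1.5,
                      scaling = c("gene", "cell"),
                      boundary = c("genome", "chromosome"),
                      logTransform = FALSE) {
    stopifnot(window >= 1L, length(lowBand) == 2L,
              isTRUE(all.equal(lowBand[1], -lowBand[2])))
    list(window = as.integer(window), lowBand = lowBand,
         controlRoundCut = controlRoundCut, highBandCut = highBandCut,
         scaling = match.arg(scaling), boundary = match.arg(boundary),
         logTransform = isTRUE(logTransform))
}

#' Reads per kilobase of exon per million mapped reads
#'
#' RPKM(g, i) = reads(g, i) / ((exonic_length_g / 1e3) x
#' (librarySize_i / 1e6)).
#'
#' @param geneCounts genes x cells count matrix (rownames = gene ids).
#' @param geneModel gene model with `gene_id` and `exonic_length`.
#' @param librarySizes per-cell totals; defaults to column sums.
#' @return numeric matrix of RPKM values, genes x cells.
#' @export
computeRpkm <- function(geneCounts, geneModel,
                        librarySizes = colSums(geneCounts)) {
    len <- geneModel$exonic_length[match(rownames(geneCounts),
                                         geneModel$gene_id)]
    if (anyNA(len)) stop("gene model is missing genes present in counts")
    if (any(len <= 0)) stop("exonic lengths must be > 0")
    if (any(librarySizes <= 0)) stop("library sizes must be > 0")
    sweep(geneCounts / (len / 1e3), 2L, librarySizes / 1e6, "/")
}

.chromRank <- function(chrom) {
    lab <- sub("^chr", "", chrom)
    rank <- suppressWarnings(as.numeric(lab))
    rank[lab %in% c("X", "x")] <- 1e6
    rank[lab %in% c("Y", "y")] <- 1e6 + 1
    if (anyNA(rank))
        stop("unknown chromosome label(s): ",
             paste(unique(chrom[is.na(rank)]), collapse = ", "))
    rank
}

#' Genomic gene ordering
#'
#' Stable sort by (chromosome rank, gene start): autosomes in numeric
#' order, then X (and Y if present).
#'
#' @param geneModel gene model data.frame.
#' @return integer permutation such that `geneModel[orderGenes(gm), ]`
#'   is in genomic order.
#' @export
orderGenes <- function(geneModel) {
    order(.chromRank(geneModel$chrom), geneModel$start)
}

#' Centered moving average over genome-ordered genes
#'
#' Window mean over `window` genes centered at each position; at the
#' sequence ends the window truncates to the available genes. For an
#' even window the extra gene sits on the 3' side.
#'
#' @param x numeric vector or genes x cells matrix, rows in genomic
#'   order.
#' @param window window size in genes.
#' @param chrom optional chromosome label per row; when given, windows
#'   are computed within each chromosome separately.
#' @return smoothed object of the same shape as `x`.
#' @export
movingAverage <- function(x, window = 100L, chrom = NULL) {
    if (is.matrix(x)) {
        out <- x
        if (is.null(chrom)) {
            for (j in seq_len(ncol(x)))
                out[, j] <- movingAverage(x[, j], window)
        } else {
            for (ch in unique(chrom)) {
                i <- chrom == ch
                for (j in seq_len(ncol(x)))
                    out[i, j] <- movingAverage(x[i, j], window)
            }
        }
        return(out)
    }
    n <- length(x)
    if (!is.null(chrom)) {
        out <- numeric(n)
        for (ch in unique(chrom)) {
            i <- chrom == ch
            out[i] <- movingAverage(x[i], window)
        }
        return(out)
    }
    if (window > n)
        stop("window (", window, ") larger than the number of genes (", n, ")")
    left <- ceiling(window / 2) - 1L
    right <- window - 1L - left
    cs <- cumsum(c(0, x))
    i <- seq_len(n)
    lo <- pmax(i - left, 1L)
    hi <- pmin(i + right, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Central scaling of smoothed coverage
#'
#' Default mode z-scores each gene across cells (mean 0, SD 1; genes
#' constant across cells map to 0). The alternative centers each cell at
#' its own mean without rescaling.
#'
#' @param m genes x cells matrix of smoothed values.
#' @param mode `"gene"` or `"cell"`.
#' @return scaled matrix of the same shape.
#' @export
centerScale <- function(m, mode = c("gene", "cell")) {
    mode <- match.arg(mode)
    if (mode == "gene") {
        if (ncol(m) < 2L)
            stop("per-gene scaling needs at least 2 cells")
        mu <- rowMeans(m)
        s <- apply(m, 1L, sd)
        out <- (m - mu) / ifelse(s > 0, s, 1)
        out[s == 0, ] <- 0
        out
    } else {
        sweep(m, 2L, colMeans(m), "-")
    }
}

#' Low-amplitude mask
#'
#' Flags entries inside the closed band (default [-1, 1]) for removal,
#' de-emphasizing low-amplitude CNVs.
#'
#' @param scaled scaled matrix.
#' @param band closed interval `c(lo, hi)`.
#' @return logical matrix, TRUE where masked.
#' @export
maskLowAmplitude <- function(scaled, band = c(-1, 1)) {
    scaled >= band[1] & scaled <= band[2]
}

## half-away-from-zero rounding (base round() rounds half to even)
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Wild-type-control mask
#'
#' Masks (in every cell) the genes whose value in a wild-type control
#' profile, processed through the same smoothing and scaling, rounds
#' half-away-from-zero to an absolute value of `cut` or more.
#'
#' @param scaled genes x cells scaled matrix.
#' @param controlProfile numeric vector of the control's scaled values,
#'   one per gene.
#' @param cut rounded-value cutoff (default 1).
#' @return list with `mask` (logical matrix) and `genesMasked` (logical
#'   per gene).
#' @export
controlMask <- function(scaled, controlProfile, cut = 1) {
    stopifnot(length(controlProfile) == nrow(scaled))
    genes <- abs(.roundHalfAway(controlProfile)) >= cut
    list(mask = matrix(genes, nrow(scaled), ncol(scaled)),
         genesMasked = genes)
}

#' High-amplitude retention mask
#'
#' Complement of [maskLowAmplitude()] with the wider band: only entries
#' strictly below -cut or strictly above +cut are retained (the
#' patient-derived-xenograft comparison mode).
#'
#' @param scaled scaled matrix.
#' @param cut band half-width (default 1.5).
#' @return logical matrix, TRUE where masked (dropped).
#' @export
retainHighAmplitude <- function(scaled, cut = 1.5) {
    abs(scaled) <= cut
}

#' Per-cell chromosome amplification call
#'
#' mean(a) is the mean scaled value of the chromosome's genes in a cell
#' (control-masked genes excluded); mean(t) is the mean of mean(a) over
#' the tumor cells. A cell is called amplified when strictly
#' mean(a) > mean(t).
#'
#' @param scaled genes x cells scaled matrix.
#' @param geneChrom chromosome label per gene (row).
#' @param chrom chromosome to call.
#' @param tumorCells columns (names or indices) defining the tumor
#'   cohort; defaults to all cells.
#' @param excludeGenes optional logical per gene; TRUE drops the gene
#'   from mean(a) (e.g. the wild-type-control mask).
#' @return data.frame with `cell_id`, `mean_a`, `mean_t`, `call`.
#' @export
callAmplification <- function(scaled, geneChrom, chrom,
                              tumorCells = colnames(scaled),
                              excludeGenes = NULL) {
    use <- geneChrom == chrom
    if (!is.null(excludeGenes)) use <- use & !excludeGenes
    if (!any(use))
        stop("no usable genes on ", chrom, ": amplification call undefined")
    meanA <- colMeans(scaled[use, , drop = FALSE])
    meanT <- mean(meanA[tumorCells])
    data.frame(cell_id = colnames(scaled), mean_a = unname(meanA),
               mean_t = meanT, call = unname(meanA > meanT),
               stringsAsFactors = FALSE)
}

#' Run the CNV inference pipeline
#'
#' Fixed stage order: RPKM, genomic ordering, 100-gene moving average,
#' central scaling, wild-type-control masking, low-amplitude masking.
#' The returned [CnvProfile-class] carries the scaled matrix, the
#' combined mask, gene metadata, and the parameters used; amplification
#' calls are made on it with [callAmplification()] /
#' [callChromosomeAmplification()].
#'
#' @param geneCounts genes x cells integer matrix.
#' @param geneModel gene model data.frame.
#' @param control optional named numeric vector of wild-type bulk gene
#'   counts (the control is smoothed and scaled alongside the cells).
#' @param params from [cnvParams()].
#' @param librarySizes per-cell totals; defaults to column sums.
#' @return A [CnvProfile-class].
#' @export
runCnvPipeline <- function(geneCounts, geneModel, control = NULL,
                           params = cnvParams(),
                           librarySizes = colSums(geneCounts)) {
    ord <- orderGenes(geneModel)
    gm <- geneModel[ord, , drop = FALSE]
    counts <- geneCounts[match(gm$gene_id, rownames(geneCounts)), ,
                         drop = FALSE]
    hasCtrl <- !is.null(control)
    if (hasCtrl) {
        ctrl <- control[match(gm$gene_id, names(control))]
        counts <- cbind(counts, `.control` = ctrl)
        librarySizes <- c(librarySizes, sum(ctrl))
    }
    rpkm <- computeRpkm(counts, gm, librarySizes)
    if (params$logTransform) rpkm <- log2(rpkm + 1)
    smoothChrom <- if (params$boundary == "chromosome") gm$chrom else NULL
    smooth <- movingAverage(rpkm, params$window, chrom = smoothChrom)
    scaled <- centerScale(smooth, params$scaling)
    if (hasCtrl) {
        ctrlProfile <- scaled[, ".control"]
        scaled <- scaled[, colnames(scaled) != ".control", drop = FALSE]
        cm <- controlMask(scaled, ctrlProfile, params$controlRoundCut)
        gm$control_masked <- cm$genesMasked
    } else {
        cm <- list(mask = matrix(FALSE, nrow(scaled), ncol(scaled)),
                   genesMasked = rep(FALSE, nrow(scaled)))
        gm$control_masked <- FALSE
    }
    mask <- cm$mask | maskLowAmplitude(scaled, params$lowBand)
    se <- SummarizedExperiment(
        assays = list(scaled = scaled, mask = mask),
        rowData = DataFrame(gm),
        colData = DataFrame(cell_id = colnames(scaled)))
    metadata(se)$params <- params
    new("CnvProfile", se)
}

#' @describeIn runCnvPipeline amplification call on a [CnvProfile-class];
#'   control-masked genes are excluded from mean(a), low-amplitude
#'   masking is not (the call operates on scaled values).
#' @param profile a `CnvProfile`.
#' @param chrom chromosome to call.
#' @param tumorCells tumor cohort columns; defaults to all cells.
#' @export
callChromosomeAmplification <- function(profile, chrom,
                                        tumorCells = colnames(profile)) {
    rd <- rowData(profile)
    callAmplification(assay(profile, "scaled"), rd$chrom, chrom,
                      tumorCells = tumorCells,
                      excludeGenes = rd$control_masked)
}
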