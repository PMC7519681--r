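#' @importFrom stats runif
NULL

.BASES <- c("A", "C", "G", "T")
.MOUSE_CHROMS <- c(paste0("chr", 1:19), "chrX")

#' Synthetic exome gene model
#'
#' A deterministic BED-like gene model used by the simulator: equally
#' spaced genes of equal exonic length on the mouse chromosome set
#' (chr1..chr19, chrX). Coordinates are 0-based half-open.
#'
#' @param genesPerChrom genes per chromosome.
#' @param chroms chromosome labels.
#' @param geneLength exonic length (bp) per gene.
#' @param spacing distance between gene starts (bp).
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`,
#'   `exonic_length`.
#' @examples
#' gm <- simGeneModel(genesPerChrom = 5)
#' head(gm)
#' @export
simGeneModel <- function(genesPerChrom = 100L, chroms = .MOUSE_CHROMS,
                         geneLength = 1500L, spacing = 50000L) {
    stopifnot(genesPerChrom >= 1L, geneLength > 0L)
    idx <- seq_len(genesPerChrom)
    do.call(rbind, lapply(chroms, function(ch) {
        start <- (idx - 1L) * spacing
        data.frame(
            gene_id = sprintf("%s_g%03d", ch, idx), chrom = ch,
            start = start, end = start + geneLength,
            exonic_length = geneLength, stringsAsFactors = FALSE)
    }))
}

#' Build a random clone tree with known somatic truth
#'
#' Generates a rooted clone genealogy with a random topology (each clone's
#' parent drawn uniformly among earlier clones), assigns a disjoint set of
#' somatic SNVs to the edge into each clone (each SNV placed in a distinct
#' gene of the gene model, with a random trinucleotide context centered on
#' the reference base), and attaches copy-number events and per-sample
#' clone fractions.
#'
#' @param nClones number of clones (>= 1; the first clone is the root).
#' @param snvsPerEdge SNVs acquired on the edge into each clone; scalar or
#'   vector of length `nClones`.
#' @param cnvSpec optional data.frame of copy-number events with columns
#'   `clone` (clone index or id), `chrom`, `cn` and optional `start`,
#'   `end` (default: whole chromosome). Events are inherited by
#'   descendant clones.
#' @param fractions optional named list (sample id) of named numeric clone
#'   fractions summing to 1. Default: one sample `"S1"` with equal
#'   fractions.
#' @param geneModel gene model from [simGeneModel()]; SNVs are placed
#'   inside its genes.
#' @param seed integer RNG seed.
#' @return A [CloneTree-class].
#' @examples
#' tree <- buildCloneTree(3, snvsPerEdge = 5, seed = 1)
#' tree
#' @export
buildCloneTree <- function(nClones, snvsPerEdge = 20L, cnvSpec = NULL,
                           fractions = NULL, geneModel = simGeneModel(),
                           seed = 1L) {
    if (nClones < 1L)
        stop("invalid configuration: nClones must be >= 1")
    set.seed(seed)
    ids <- paste0("C", seq_len(nClones))
    ## each clone k >= 2 picks a parent uniformly among clones 1..k-1
    parent <- rep(NA_character_, nClones)
    if (nClones > 1L)
        for (k in 2:nClones) parent[k] <- ids[sample.int(k - 1L, 1L)]
    clones <- data.frame(clone_id = ids, parent_id = parent,
                         stringsAsFactors = FALSE)

    nPer <- rep_len(as.integer(snvsPerEdge), nClones)
    total <- sum(nPer)
    if (total > nrow(geneModel))
        stop("gene model too small for the requested number of SNVs")
    pick <- sample.int(nrow(geneModel), total)
    edges <- rep(ids, nPer)
    pos <- geneModel$start[pick] +
        floor(runif(total) * (geneModel$end[pick] - geneModel$start[pick])) + 1L
    ref <- sample(.BASES, total, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(.BASES, r), 1L), "")
    ctx <- paste0(sample(.BASES, total, replace = TRUE), ref,
                  sample(.BASES, total, replace = TRUE))
    sites <- data.frame(chrom = geneModel$chrom[pick], pos = as.integer(pos),
                        ref = ref, alt = unname(alt), context = ctx,
                        gene = geneModel$gene_id[pick],
                        stringsAsFactors = FALSE)
    snvAssignments <- split(sites, factor(edges, levels = ids))

    cnvEvents <- setNames(vector("list", nClones), ids)
    for (i in seq_len(nClones)) cnvEvents[[i]] <-
        data.frame(chrom = character(), start = integer(), end = integer(),
                   cn = integer(), stringsAsFactors = FALSE)
    if (!is.null(cnvSpec) && nrow(cnvSpec)) {
        for (i in seq_len(nrow(cnvSpec))) {
            cid <- cnvSpec$clone[i]
            if (is.numeric(cid)) cid <- ids[cid]
            if (!cid %in% ids) stop("cnvSpec names unknown clone: ", cid)
            chromMax <- max(geneModel$end[geneModel$chrom == cnvSpec$chrom[i]],
                            0L)
            ev <- data.frame(
                chrom = cnvSpec$chrom[i],
                start = if ("start" %in% names(cnvSpec) &&
                            !is.na(cnvSpec$start[i])) cnvSpec$start[i] else 0L,
                end = if ("end" %in% names(cnvSpec) &&
                          !is.na(cnvSpec$end[i])) cnvSpec$end[i] else chromMax,
                cn = as.integer(cnvSpec$cn[i]), stringsAsFactors = FALSE)
            cnvEvents[[cid]] <- rbind(cnvEvents[[cid]], ev)
        }
    }
    if (is.null(fractions))
        fractions <- list(S1 = setNames(rep(1 / nClones, nClones), ids))
    new("CloneTree", clones = clones, snvAssignments = snvAssignments,
        cnvEvents = cnvEvents, fractions = fractions)
}

## clone ids on the path from the root down to (and including) cloneId
.rootPath <- function(tree, cloneId) {
    cl <- tree@clones
    path <- character()
    cur <- cloneId
    while (!is.na(cur)) {
        path <- c(cur, path)
        cur <- cl$parent_id[match(cur, cl$clone_id)]
    }
    path
}

#' Full somatic genotype of a clone
#'
#' Union of the SNV sets on the edges along the clone's root path.
#'
#' @param tree a [CloneTree-class].
#' @param cloneId clone identifier.
#' @return data.frame of sites (`chrom`, `pos`, `ref`, `alt`, `context`,
#'   `gene`).
#' @export
cloneGenotype <- function(tree, cloneId) {
    if (!cloneId %in% tree@clones$clone_id)
        stop("unknown clone: ", cloneId)
    do.call(rbind, c(tree@snvAssignments[.rootPath(tree, cloneId)],
                     list(make.row.names = FALSE)))
}

## total copy number at (chrom, pos) for a clone: events along the root
## path, later (more derived) events overriding earlier ones
.copyNumberAt <- function(tree, cloneId, chrom, pos) {
    cn <- rep(2L, length(pos))
    for (cid in .rootPath(tree, cloneId)) {
        ev <- tree@cnvEvents[[cid]]
        if (is.null(ev) || !nrow(ev)) next
        for (j in seq_len(nrow(ev))) {
            hit <- chrom == ev$chrom[j] & pos > ev$start[j] & pos <= ev$end[j]
            cn[hit] <- ev$cn[j]
        }
    }
    cn
}

## per-gene total copy number vector for a clone
.copyNumberPerGene <- function(tree, cloneId, geneModel) {
    mid <- floor((geneModel$start + geneModel$end) / 2) + 1L
    .copyNumberAt(tree, cloneId, geneModel$chrom, mid)
}

#' Assign cells of a sample to clones
#'
#' Multinomial draw from the sample's clone fractions.
#'
#' @param tree a [CloneTree-class] with fractions defined for `sampleId`.
#' @param sampleId sample identifier.
#' @param nCells number of cells to draw.
#' @param seed integer RNG seed.
#' @return data.frame with `cell_id`, `sample_id`, `clone_id`.
#' @export
sampleCells <- function(tree, sampleId, nCells, seed = 1L) {
    if (!sampleId %in% names(tree@fractions))
        stop("no clone fractions defined for sample '", sampleId, "'")
    if (nCells == 0L)
        return(data.frame(cell_id = character(), sample_id = character(),
                          clone_id = character(), stringsAsFactors = FALSE))
    set.seed(seed)
    fr <- tree@fractions[[sampleId]]
    counts <- rmultinom(1L, nCells, fr)[, 1L]
    data.frame(
        cell_id = sprintf("%s_c%02d", sampleId, seq_len(nCells)),
        sample_id = sampleId,
        clone_id = rep(names(fr), counts), stringsAsFactors = FALSE)
}

#' Simulate per-cell read counts at every somatic site
#'
#' For each cell and each somatic site in the clone tree, depth is drawn
#' as Poisson(meanDepth x lognormal(0, wgaSigma)). A carrier cell is
#' heterozygous with the alternate allele on one chromosomal copy; each
#' copy independently drops out with probability `adoRate`, and surviving
#' allele fractions are weighted by copy dosage. Reads miscall to the
#' listed alternate base with probability `seqErrorRate`, so wild-type
#' sites emit alternate reads only through error. Loci with total copy
#' number 0, or with all copies dropped out, yield depth 0.
#'
#' @param assignments cell-to-clone table from [sampleCells()].
#' @param tree a [CloneTree-class].
#' @param config a [SimConfig-class]; its `seed` drives the draw.
#' @return data.frame with one row per cell x site: `cell_id`,
#'   `sample_id`, `chrom`, `pos`, `ref`, `alt`, `ref_reads`, `alt_reads`,
#'   `gene`, `context`.
#' @export
simulateSiteCounts <- function(assignments, tree, config) {
    truth <- truthSites(tree)
    if (!nrow(assignments) || !nrow(truth))
        return(data.frame(cell_id = character(), sample_id = character(),
                          chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          ref_reads = integer(), alt_reads = integer(),
                          gene = character(), context = character(),
                          stringsAsFactors = FALSE))
    set.seed(config@seed)
    ns <- nrow(truth)
    e <- config@seqErrorRate
    out <- vector("list", nrow(assignments))
    for (i in seq_len(nrow(assignments))) {
        clone <- assignments$clone_id[i]
        g <- cloneGenotype(tree, clone)
        carrier <- paste(truth$chrom, truth$pos) %in% paste(g$chrom, g$pos)
        cn <- .copyNumberAt(tree, clone, truth$chrom, truth$pos)
        depth <- rpois(ns, config@meanDepth *
                           exp(rnorm(ns, 0, config@wgaSigma)))
        depth[cn == 0L] <- 0L
        altCopies <- ifelse(carrier & cn >= 1L, 1L, 0L)
        refCopies <- pmax(cn - altCopies, 0L)
        survAlt <- rbinom(ns, altCopies, 1 - config@adoRate)
        survRef <- rbinom(ns, refCopies, 1 - config@adoRate)
        depth[survAlt + survRef == 0L] <- 0L
        f <- ifelse(survAlt + survRef > 0, survAlt / (survAlt + survRef), 0)
        pAlt <- f * (1 - e) + (1 - f) * e
        altReads <- rbinom(ns, depth, pAlt)
        out[[i]] <- data.frame(
            cell_id = assignments$cell_id[i],
            sample_id = assignments$sample_id[i],
            chrom = truth$chrom, pos = truth$pos,
            ref = truth$ref, alt = truth$alt,
            ref_reads = as.integer(depth - altReads),
            alt_reads = as.integer(altReads),
            gene = truth$gene, context = truth$context,
            stringsAsFactors = FALSE)
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' All simulated somatic sites with their clone of origin
#'
#' @param tree a [CloneTree-class].
#' @return data.frame of sites with a `clone_id` column naming the edge
#'   each SNV was acquired on; each site appears exactly once.
#' @export
truthSites <- function(tree) {
    ids <- names(tree@snvAssignments)
    out <- do.call(rbind, c(lapply(ids, function(cid) {
        s <- tree@snvAssignments[[cid]]
        if (!nrow(s)) return(NULL)
        cbind(s, clone_id = cid, stringsAsFactors = FALSE)
    }), list(make.row.names = FALSE)))
    if (is.null(out))
        out <- data.frame(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          context = character(), gene = character(),
                          clone_id = character(), stringsAsFactors = FALSE)
    out
}

#' Ground-truth carrier matrix
#'
#' @param tree a [CloneTree-class].
#' @param assignments cell-to-clone table from [sampleCells()].
#' @return logical matrix, sites x cells: TRUE where the cell's clone
#'   carries the site.
#' @export
truthGenotypeMatrix <- function(tree, assignments) {
    truth <- truthSites(tree)
    key <- paste(truth$chrom, truth$pos)
    m <- vapply(seq_len(nrow(assignments)), function(i) {
        g <- cloneGenotype(tree, assignments$clone_id[i])
        key %in% paste(g$chrom, g$pos)
    }, logical(nrow(truth)))
    m <- matrix(m, nrow = nrow(truth),
                dimnames = list(paste(truth$chrom, truth$pos, sep = ":"),
                                assignments$cell_id))
    m
}

#' Simulate per-cell gene-level exome read counts
#'
#' Expected reads for gene g in cell i are
#' `librarySize x (cn_g / 2) x exonic_length_g x lognormal(0, wgaSigma) / L`
#' with `L` the neutral-genome total exonic length, then Poisson-sampled.
#' A copy-number-4 chromosome therefore doubles its genes' expected
#' counts relative to neutral genes.
#'
#' @param assignments cell-to-clone table from [sampleCells()].
#' @param tree a [CloneTree-class].
#' @param geneModel gene model data.frame (see [simGeneModel()]).
#' @param config a [SimConfig-class].
#' @return integer matrix, genes x cells, with `geneModel$gene_id` rownames.
#' @export
simulateGeneCounts <- function(assignments, tree, geneModel, config) {
    if (!nrow(geneModel)) stop("gene model is empty")
    set.seed(config@seed + 1L)
    L <- sum(geneModel$exonic_length)
    ng <- nrow(geneModel)
    counts <- matrix(0L, ng, nrow(assignments),
                     dimnames = list(geneModel$gene_id, assignments$cell_id))
    for (i in seq_len(nrow(assignments))) {
        cn <- .copyNumberPerGene(tree, assignments$clone_id[i], geneModel)
        lam <- config@librarySize * (cn / 2) * geneModel$exonic_length *
            exp(rnorm(ng, 0, config@wgaSigma)) / L
        counts[, i] <- rpois(ng, lam)
    }
    counts
}

#' Mix single-cell counts into bulk samples with normal contamination
#'
#' The bulk tumor component is the sum of the constituent cells' counts;
#' a simulated matched-normal contaminant of equal total depth (all
#' reference apart from sequencing error, copy-neutral genome) is blended
#' at weight `1 - purity`. A pure matched-normal sample (the kidney-style
#' control) is emitted alongside. In deterministic mode the expected
#' counts are returned without Poisson resampling, so the bulk depth
#' equals the weighted component sum exactly.
#'
#' @param siteCounts per-cell site counts from [simulateSiteCounts()].
#' @param geneCounts per-cell gene counts from [simulateGeneCounts()]
#'   (or NULL to skip gene-level mixing).
#' @param geneModel gene model (required when `geneCounts` is given).
#' @param purity tumor fraction in [0, 1].
#' @param config a [SimConfig-class].
#' @param deterministic logical; TRUE returns expected (real-valued)
#'   counts with no resampling.
#' @param sampleId label for the emitted bulk rows.
#' @return list with `bulkSites`, `normalSites` (site-count data.frames
#'   with empty `cell_id`), and, when gene counts were supplied,
#'   `bulkGenes`, `normalGenes` (named numeric vectors).
#' @export
mixBulk <- function(siteCounts, geneCounts = NULL, geneModel = NULL,
                    purity, config, deterministic = FALSE,
                    sampleId = "bulk") {
    stopifnot(purity >= 0, purity <= 1)
    set.seed(config@seed + 2L)
    e <- config@seqErrorRate
    key <- paste(siteCounts$chrom, siteCounts$pos)
    first <- !duplicated(key)
    tumorRef <- tapply(siteCounts$ref_reads, key, sum)
    tumorAlt <- tapply(siteCounts$alt_reads, key, sum)
    ord <- key[first]
    tumorRef <- as.numeric(tumorRef[ord]); tumorAlt <- as.numeric(tumorAlt[ord])
    depthT <- tumorRef + tumorAlt
    normRefE <- depthT * (1 - e)
    normAltE <- depthT * e
    bulkRefE <- purity * tumorRef + (1 - purity) * normRefE
    bulkAltE <- purity * tumorAlt + (1 - purity) * normAltE
    draw <- function(x) if (deterministic) x else rpois(length(x), x)
    mkSites <- function(refv, altv, sid) data.frame(
        cell_id = "", sample_id = sid,
        chrom = siteCounts$chrom[first], pos = siteCounts$pos[first],
        ref = siteCounts$ref[first], alt = siteCounts$alt[first],
        ref_reads = draw(refv), alt_reads = draw(altv),
        gene = siteCounts$gene[first], context = siteCounts$context[first],
        stringsAsFactors = FALSE)
    out <- list(bulkSites = mkSites(bulkRefE, bulkAltE, sampleId),
                normalSites = mkSites(normRefE, normAltE,
                                      paste0(sampleId, "_normal")))
    if (!is.null(geneCounts)) {
        stopifnot(!is.null(geneModel))
        tumorG <- rowSums(geneCounts)
        normGE <- ncol(geneCounts) * config@librarySize *
            geneModel$exonic_length / sum(geneModel$exonic_length)
        out$bulkGenes <- setNames(draw(purity * tumorG +
                                           (1 - purity) * normGE),
                                  rownames(geneCounts))
        out$normalGenes <- setNames(draw(normGE), rownames(geneCounts))
    }
    out
}

#' Simulate a complete clone-structured scWES experiment
#'
#' Convenience wrapper: draws cells for every sample in the tree's
#' fraction table, simulates site and gene counts per cell, and mixes a
#' purity-weighted bulk plus a matched normal per sample.
#'
#' @param tree a [CloneTree-class].
#' @param config a [SimConfig-class].
#' @param geneModel gene model (see [simGeneModel()]).
#' @param deterministicBulk passed to [mixBulk()].
#' @return list with `assignments`, `siteCounts`, `geneCounts`, `bulk`
#'   (list per sample of [mixBulk()] results), and `truth` (site table
#'   with clone of origin).
#' @export
simulateExperiment <- function(tree, config, geneModel = simGeneModel(),
                               deterministicBulk = FALSE) {
    samples <- names(tree@fractions)
    assignments <- do.call(rbind, lapply(seq_along(samples), function(i)
        sampleCells(tree, samples[i], config@nCellsPerSample,
                    seed = config@seed + 10L + i)))
    siteCounts <- simulateSiteCounts(assignments, tree, config)
    geneCounts <- simulateGeneCounts(assignments, tree, geneModel, config)
    bulk <- lapply(samples, function(sm) {
        cells <- assignments$cell_id[assignments$sample_id == sm]
        mixBulk(siteCounts[siteCounts$cell_id %in% cells, , drop = FALSE],
                geneCounts[, cells, drop = FALSE], geneModel,
                purity = config@bulkPurity, config = config,
                deterministic = deterministicBulk,
                sampleId = paste0(sm, "_bulk"))
    })
    names(bulk) <- samples
    list(assignments = assignments, siteCounts = siteCounts,
         geneCounts = geneCounts, bulk = bulk, truth = truthSites(tree))
}
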