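#' Variant allele fraction
#'
#' VAF = alt reads / (ref reads + alt reads). Defined only at covered
#' sites.
#'
#' @param refReads,altReads non-negative read counts (vectorized).
#' @return numeric VAF in [0, 1].
#' @examples
#' computeVaf(12, 13)  # 0.52
#' @export
computeVaf <- function(refReads, altReads) {
    depth <- refReads + altReads
    if (any(depth == 0))
        stop("VAF undefined at zero-depth site")
    altReads / depth
}

#' One-sided Fisher exact somatic test
#'
#' Exact hypergeometric tail probability that the tumor sample is at
#' least as alt-enriched as observed, given the margins of the 2x2
#' (normal/tumor x ref/alt) read-count table. This is the somatic test
#' used by VarScan-style callers: small p means the alternate allele is
#' enriched in the tumor relative to the matched normal.
#'
#' @param normalRef,normalAlt,tumorRef,tumorAlt read counts (vectorized).
#' @return p-value(s) in (0, 1].
#' @examples
#' somaticFisherP(20, 0, 10, 10)
#' @export
somaticFisherP <- function(normalRef, normalAlt, tumorRef, tumorAlt) {
    depthN <- normalRef + normalAlt
    depthT <- tumorRef + tumorAlt
    if (any(depthN == 0 | depthT == 0))
        stop("Fisher somatic test undefined at zero-depth input")
    totalAlt <- normalAlt + tumorAlt
    totalRef <- normalRef + tumorRef
    ## P(X >= tumorAlt), X ~ Hypergeometric(alt successes, ref failures,
    ## tumor depth draws)
    phyper(tumorAlt - 1, totalAlt, totalRef, depthT, lower.tail = FALSE)
}

## shared site-level filter used for bulk and cells; returns a keep flag
## and the first failing reason per site
.siteFilter <- function(sites, normal, minCov, minVar, maxNormalVaf,
                        minTumorVaf, pMax) {
    nkey <- paste(normal$chrom, normal$pos)
    idx <- match(paste(sites$chrom, sites$pos), nkey)
    if (anyNA(idx))
        stop("matched normal is missing ",
             sum(is.na(idx)), " site(s) present in the tumor input")
    nref <- normal$ref_reads[idx]
    nalt <- normal$alt_reads[idx]
    depth <- sites$ref_reads + sites$alt_reads
    ndepth <- nref + nalt
    reason <- rep(NA_character_, nrow(sites))
    fail <- function(cond, why) {
        hit <- cond & is.na(reason)
        reason[hit] <<- why
    }
    fail(depth < minCov, "coverage")
    fail(sites$alt_reads < minVar, "var_reads")
    fail(ndepth == 0, "normal_uncovered")
    covered <- ndepth > 0
    nvaf <- ifelse(covered, nalt / pmax(ndepth, 1L), NA_real_)
    tvaf <- ifelse(depth > 0, sites$alt_reads / pmax(depth, 1L), 0)
    fail(covered & nvaf > maxNormalVaf, "normal_vaf")
    fail(tvaf < minTumorVaf, "tumor_vaf")
    testable <- is.na(reason)
    p <- rep(NA_real_, nrow(sites))
    if (any(testable))
        p[testable] <- somaticFisherP(nref[testable], nalt[testable],
                                      sites$ref_reads[testable],
                                      sites$alt_reads[testable])
    fail(testable & p >= pMax, "fisher_p")
    list(keep = is.na(reason), reason = reason, p = p)
}

#' Filter bulk somatic SNVs
#'
#' Retains sites with depth >= 20, alt reads >= 5, normal VAF <= 0.10,
#' tumor VAF >= 0.10, and one-sided Fisher p < 5e-3 (defaults from
#' [filterThresholds()]).
#'
#' @param sites bulk site-count data.frame (`chrom`, `pos`, `ref`, `alt`,
#'   `ref_reads`, `alt_reads`).
#' @param normal matched-normal site counts (same columns).
#' @param thresholds a [FilterThresholds-class].
#' @return list with `retained` (sites plus a `fisher_p` column) and
#'   `log` (one row per rejected site: `chrom`, `pos`, `reason`).
#' @export
filterBulk <- function(sites, normal, thresholds = filterThresholds()) {
    if (is.null(normal) || !nrow(normal))
        stop("matched normal sample is required")
    f <- .siteFilter(sites, normal, thresholds@bulkMinCov,
                     thresholds@bulkMinVar, thresholds@maxNormalVaf,
                     thresholds@minTumorVaf, thresholds@pMax)
    retained <- sites[f$keep, , drop = FALSE]
    retained$fisher_p <- f$p[f$keep]
    list(retained = retained,
         log = data.frame(chrom = sites$chrom[!f$keep],
                          pos = sites$pos[!f$keep],
                          reason = f$reason[!f$keep],
                          stringsAsFactors = FALSE))
}

#' Filter per-cell candidate somatic SNVs
#'
#' As [filterBulk()] but with the single-cell thresholds (depth >= 10,
#' alt >= 3); the VAF and Fisher rules are identical. Applied per cell.
#'
#' @param cellSites site counts for cells (must contain `cell_id`).
#' @param normal matched-normal site counts.
#' @param thresholds a [FilterThresholds-class].
#' @return list with `retained` (candidate rows with `cell_id` and
#'   `fisher_p`) and `log`.
#' @export
filterCell <- function(cellSites, normal, thresholds = filterThresholds()) {
    if (is.null(normal) || !nrow(normal))
        stop("matched normal sample is required")
    f <- .siteFilter(cellSites, normal, thresholds@cellMinCov,
                     thresholds@cellMinVar, thresholds@maxNormalVaf,
                     thresholds@minTumorVaf, thresholds@pMax)
    retained <- cellSites[f$keep, , drop = FALSE]
    retained$fisher_p <- f$p[f$keep]
    list(retained = retained,
         log = data.frame(cell_id = cellSites$cell_id[!f$keep],
                          chrom = cellSites$chrom[!f$keep],
                          pos = cellSites$pos[!f$keep],
                          reason = f$reason[!f$keep],
                          stringsAsFactors = FALSE))
}

#' Recurrence filter across single cells
#'
#' Keeps sites whose candidate status holds in at least `minCells`
#' distinct cells.
#'
#' @param candidates data.frame of per-cell candidates (`cell_id`,
#'   `chrom`, `pos`, ...).
#' @param minCells minimum number of supporting cells (default 3).
#' @return data.frame of surviving unique sites with an `n_cells` column.
#' @export
recurrenceFilter <- function(candidates, minCells = 3L) {
    if (!nrow(candidates)) {
        out <- candidates[0, setdiff(names(candidates), "cell_id"),
                          drop = FALSE]
        out$n_cells <- integer()
        return(out)
    }
    key <- paste(candidates$chrom, candidates$pos, candidates$ref,
                 candidates$alt)
    nc <- tapply(candidates$cell_id, key,
                 function(x) length(unique(x)))
    keep <- names(nc)[nc >= minCells]
    first <- candidates[!duplicated(key) & key %in% keep, , drop = FALSE]
    first$n_cells <- as.integer(nc[paste(first$chrom, first$pos,
                                         first$ref, first$alt)])
    first$cell_id <- NULL
    rownames(first) <- NULL
    first
}

#' One-individual uniqueness filter
#'
#' Removes any (site, allele) observed in more than one individual; a
#' proxy for residual germline variants and recurrent artifacts. With a
#' single individual the input passes through with a warning.
#'
#' @param siteSetsByIndividual named list (individual) of site
#'   data.frames (`chrom`, `pos`, `ref`, `alt`, ...).
#' @return named list of filtered site data.frames.
#' @export
uniquenessFilter <- function(siteSetsByIndividual) {
    if (length(siteSetsByIndividual) < 2L) {
        warning("uniqueness filter needs >= 2 individuals; passing through")
        return(siteSetsByIndividual)
    }
    keys <- lapply(siteSetsByIndividual, function(s)
        unique(paste(s$chrom, s$pos, s$ref, s$alt)))
    shared <- unlist(keys)
    shared <- unique(shared[duplicated(shared)])
    lapply(siteSetsByIndividual, function(s) {
        k <- paste(s$chrom, s$pos, s$ref, s$alt)
        s[!k %in% shared, , drop = FALSE]
    })
}

#' Rescue genotyping into the ternary mutation matrix
#'
#' Re-examines every cell at each cascade-surviving site: a cell is
#' MUTANT ("M") with >= 2 alternate reads, otherwise WILDTYPE ("W") when
#' its depth reaches `wtAssertMinDepth`, otherwise NO_COVERAGE (".").
#'
#' @param finalSites data.frame of retained sites (`chrom`, `pos`,
#'   `ref`, `alt`, optionally `gene`).
#' @param allCellSites per-cell site counts for all cells (`cell_id`,
#'   `sample_id`, `chrom`, `pos`, `ref_reads`, `alt_reads`). Cells with
#'   no row at a site are treated as depth 0.
#' @param thresholds a [FilterThresholds-class].
#' @param cellInfo optional per-cell metadata data.frame (must contain
#'   `cell_id`); defaults to the distinct cells of `allCellSites`.
#' @return A [MutationMatrix-class].
#' @export
rescueGenotype <- function(finalSites, allCellSites,
                           thresholds = filterThresholds(),
                           cellInfo = NULL) {
    if (is.null(cellInfo)) {
        cellInfo <- unique(allCellSites[, intersect(
            c("cell_id", "sample_id", "individual"),
            names(allCellSites)), drop = FALSE])
    }
    cells <- cellInfo$cell_id
    ns <- nrow(finalSites)
    st <- matrix(.STATUS_NOCOV, ns, length(cells),
                 dimnames = list(NULL, cells))
    if (ns && nrow(allCellSites)) {
        skey <- paste(finalSites$chrom, finalSites$pos, finalSites$ref,
                      finalSites$alt)
        akey <- paste(allCellSites$chrom, allCellSites$pos,
                      allCellSites$ref, allCellSites$alt)
        ri <- match(akey, skey)
        ci <- match(allCellSites$cell_id, cells)
        hit <- !is.na(ri) & !is.na(ci)
        depth <- allCellSites$ref_reads + allCellSites$alt_reads
        status <- ifelse(allCellSites$alt_reads >= thresholds@rescueMinVar,
                         .STATUS_MUTANT,
                  ifelse(depth >= thresholds@wtAssertMinDepth,
                         .STATUS_WILDTYPE, .STATUS_NOCOV))
        st[cbind(ri[hit], ci[hit])] <- status[hit]
    }
    siteCols <- intersect(c("chrom", "pos", "ref", "alt", "gene", "context",
                            "individual", "n_cells", "fisher_p"),
                          names(finalSites))
    MutationMatrix(st, finalSites[, siteCols, drop = FALSE], cellInfo)
}

#' Run the full somatic SNV cascade
#'
#' Per-cell filtering, recurrence across cells of each individual,
#' cross-individual uniqueness (when more than one individual is
#' present), and rescue genotyping into a ternary [MutationMatrix-class].
#' Optionally also filters a bulk sample with the bulk thresholds.
#'
#' @param cellSites per-cell site counts (`cell_id`, `sample_id`,
#'   optional `individual`, `chrom`, `pos`, `ref`, `alt`, `ref_reads`,
#'   `alt_reads`).
#' @param normal matched-normal site counts. Either a single data.frame
#'   or a named list per individual.
#' @param bulk optional bulk site counts (single data.frame, one
#'   individual assumed) put through [filterBulk()].
#' @param thresholds a [FilterThresholds-class].
#' @return list with `matrix` (a `MutationMatrix`), `bulkSnvs` (or NULL),
#'   `log` (rejection rows from all stages), and `stageCounts` (named
#'   integer site counts after each stage).
#' @export
runSnvPipeline <- function(cellSites, normal, bulk = NULL,
                           thresholds = filterThresholds()) {
    if (!nrow(cellSites)) {
        mm <- MutationMatrix(
            matrix(character(), 0, 0),
            data.frame(chrom = character(), pos = integer(),
                       ref = character(), alt = character()),
            data.frame(cell_id = character()))
        return(list(matrix = mm, bulkSnvs = NULL,
                    log = data.frame(), stageCounts = c(candidates = 0L)))
    }
    if (!"individual" %in% names(cellSites))
        cellSites$individual <- "I1"
    normalFor <- function(ind) {
        if (is.data.frame(normal)) normal
        else normal[[ind]] %||% stop("no normal for individual ", ind)
    }
    inds <- unique(cellSites$individual)
    perInd <- lapply(inds, function(ind) {
        cs <- cellSites[cellSites$individual == ind, , drop = FALSE]
        flt <- filterCell(cs, normalFor(ind), thresholds)
        rec <- recurrenceFilter(flt$retained, thresholds@minCells)
        list(candidates = flt$retained, recurrent = rec, log = flt$log)
    })
    names(perInd) <- inds
    recSets <- lapply(perInd, `[[`, "recurrent")
    finalSets <- if (length(inds) > 1L) uniquenessFilter(recSets) else recSets
    finalSites <- do.call(rbind, c(lapply(inds, function(ind) {
        s <- finalSets[[ind]]
        if (nrow(s)) cbind(s, individual = ind, stringsAsFactors = FALSE)
        else NULL
    }), list(make.row.names = FALSE)))
    if (is.null(finalSites))
        finalSites <- data.frame(chrom = character(), pos = integer(),
                                 ref = character(), alt = character(),
                                 individual = character())
    cellInfo <- unique(cellSites[, intersect(
        c("cell_id", "sample_id", "individual"), names(cellSites)),
        drop = FALSE])
    mm <- rescueGenotype(finalSites, cellSites, thresholds, cellInfo)
    bulkRes <- if (!is.null(bulk))
        filterBulk(bulk, if (is.data.frame(normal)) normal else normal[[1L]],
                   thresholds)
    stageCounts <- c(
        input = length(unique(paste(cellSites$chrom, cellSites$pos))),
        candidates = length(unique(unlist(lapply(perInd, function(p)
            paste(p$candidates$chrom, p$candidates$pos))))),
        recurrent = sum(vapply(recSets, nrow, 0L)),
        unique = nrow(finalSites))
    list(matrix = mm, bulkSnvs = bulkRes$retained,
         log = do.call(rbind, c(lapply(perInd, `[[`, "log"),
                                list(make.row.names = FALSE))),
         stageCounts = stageCounts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
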