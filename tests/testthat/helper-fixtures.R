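# Shared fixtures and independent oracles used across test files.

# Incidence fixture: mutation matrices encoding the published single-cell
# counts for mouse 153 (18 primary-tumor cells, 20 liver-metastasis cells).
# Sites: one per gene; cells are assigned M/W so that marginal and joint
# counts match the printed fractions exactly.
makeIncidenceFixture <- function() {
    build <- function(nCells, nA, nP, nBoth, prefix) {
        st <- matrix("W", 2L, nCells,
                     dimnames = list(NULL, sprintf("%s_c%02d", prefix,
                                                   seq_len(nCells))))
        aOnly <- nA - nBoth
        pOnly <- nP - nBoth
        stopifnot(nBoth + aOnly + pOnly <= nCells)
        idx <- seq_len(nCells)
        both <- idx[seq_len(nBoth)]
        aRest <- idx[nBoth + seq_len(aOnly)]
        pRest <- idx[nBoth + aOnly + seq_len(pOnly)]
        st[1L, c(both, aRest)] <- "M"
        st[2L, c(both, pRest)] <- "M"
        MutationMatrix(st, data.frame(
            chrom = c("chr1", "chr6"), pos = c(1000L, 2000L),
            ref = "C", alt = "T", gene = c("Arhgef11", "Plekha5"),
            stringsAsFactors = FALSE))
    }
    list(PT = build(18L, nA = 15L, nP = 10L, nBoth = 8L, "153PT"),
         LMT = build(20L, nA = 15L, nP = 17L, nBoth = 13L, "153LMT"))
}

# Brute-force one-sided Fisher somatic p: enumerate every table with the
# observed margins and sum the probabilities of tables at least as
# tumor-alt-enriched, using choose() directly.
fisherEnumOracle <- function(nr, na, tr, ta) {
    dn <- nr + na
    dt <- tr + ta
    alt <- na + ta
    tot <- dn + dt
    ks <- max(0L, alt - dn):min(alt, dt)   # feasible tumor alt counts
    probs <- choose(dt, ks) * choose(dn, alt - ks) / choose(tot, alt)
    sum(probs[ks >= ta])
}

# Brute-force centered truncating moving average.
movingAverageOracle <- function(x, window) {
    n <- length(x)
    left <- ceiling(window / 2) - 1L
    right <- window - 1L - left
    vapply(seq_len(n), function(i)
        mean(x[max(1L, i - left):min(n, i + right)]), 0)
}

# Exhaustive Fitch score: minimize changes over all internal-node state
# assignments (and over states of missing leaves).
fitchExhaustiveOracle <- function(tree, bin) {
    ntip <- length(tree$tip.label)
    bin <- bin[tree$tip.label, , drop = FALSE]
    nn <- ntip + tree$Nnode
    free <- (ntip + 1L):nn
    total <- 0
    for (s in seq_len(ncol(bin))) {
        leafStates <- bin[, s]
        freeLeaves <- which(is.na(leafStates))
        vars <- c(free, freeLeaves)
        best <- Inf
        for (mask in 0:(2^length(vars) - 1L)) {
            st <- integer(nn)
            st[seq_len(ntip)] <- leafStates
            bits <- as.integer(intToBits(mask))[seq_along(vars)]
            st[vars] <- bits
            cost <- sum(st[tree$edge[, 1L]] != st[tree$edge[, 2L]])
            best <- min(best, cost)
        }
        total <- total + best
    }
    total
}

# Random additive distance matrix from a random topology with positive
# branch lengths; returns the tree and its path-length matrix.
makeAdditiveCase <- function(n, seed) {
    set.seed(seed)
    tr <- ape::rtree(n, rooted = FALSE,
                     br = function(k) runif(k, 0.2, 1))
    list(tree = tr, D = cophenetic(tr))
}

# Simulate a clean two-clone experiment: nA + nB cells, clone-private
# SNV blocks, no noise.
makeTwoCloneSim <- function(nA = 10L, nB = 10L, snvsPerEdge = 8L,
                            seed = 42L, adoRate = 0, wgaSigma = 0,
                            seqErrorRate = 0, meanDepth = 60) {
    gm <- simGeneModel(genesPerChrom = 30L)
    frA <- nA / (nA + nB)
    tree <- buildCloneTree(2L, snvsPerEdge = snvsPerEdge, geneModel = gm,
                           seed = seed,
                           fractions = list(S1 = c(C1 = frA, C2 = 1 - frA)))
    cfg <- simConfig(nCellsPerSample = nA + nB, meanDepth = meanDepth,
                     wgaSigma = wgaSigma, adoRate = adoRate,
                     seqErrorRate = seqErrorRate, seed = seed)
    ## force exact clone counts for a deterministic split
    assignments <- data.frame(
        cell_id = sprintf("S1_c%02d", seq_len(nA + nB)),
        sample_id = "S1",
        clone_id = rep(c("C1", "C2"), c(nA, nB)),
        stringsAsFactors = FALSE)
    sites <- simulateSiteCounts(assignments, tree, cfg)
    list(tree = tree, cfg = cfg, gm = gm, assignments = assignments,
         sites = sites)
}

# Deep matched normal covering the given sites: ref-only reads.
cleanNormal <- function(sites, depth = 100L) {
    key <- paste(sites$chrom, sites$pos)
    first <- !duplicated(key)
    data.frame(chrom = sites$chrom[first], pos = sites$pos[first],
               ref = sites$ref[first], alt = sites$alt[first],
               ref_reads = depth, alt_reads = 0L,
               stringsAsFactors = FALSE)
}
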