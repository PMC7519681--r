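#' @importFrom ape write.tree
NULL

#' Binary presence/absence matrix from a mutation matrix
#'
#' MUTANT maps to 1, WILDTYPE to 0, NO_COVERAGE to NA (missing).
#'
#' @param mm a [MutationMatrix-class].
#' @return integer matrix, cells x sites, with NA for missing entries.
#' @export
asBinaryMatrix <- function(mm) {
    st <- t(statusMatrix(mm))
    out <- matrix(NA_integer_, nrow(st), ncol(st), dimnames = dimnames(st))
    out[st == .STATUS_MUTANT] <- 1L
    out[st == .STATUS_WILDTYPE] <- 0L
    rownames(out) <- colData(mm)$cell_id
    out
}

#' Pairwise-complete normalized Hamming distance
#'
#' Distance between two cells is the fraction of disagreeing sites among
#' the sites where both cells are non-missing.
#'
#' @param bin cells x sites matrix of 1/0/NA.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
pairwiseDistance <- function(bin) {
    n <- nrow(bin)
    if (n < 2L) stop("need at least 2 cells")
    D <- matrix(0, n, n, dimnames = list(rownames(bin), rownames(bin)))
    for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
            shared <- !is.na(bin[i, ]) & !is.na(bin[j, ])
            if (!any(shared))
                stop("cells '", rownames(bin)[i], "' and '",
                     rownames(bin)[j], "' share no informative sites")
            d <- mean(bin[i, shared] != bin[j, shared])
            D[i, j] <- D[j, i] <- d
        }
    }
    D
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration on a symmetric distance matrix. Ties in the
#' Q criterion break toward the lowest (row, column) index pair; negative
#' branch lengths are clamped to zero with the deficit shifted to the
#' sister branch.
#'
#' @param D symmetric non-negative distance matrix (n >= 3) with row
#'   names used as tip labels.
#' @return an unrooted `phylo` tree.
#' @export
neighborJoining <- function(D) {
    D <- as.matrix(D)
    if (!isSymmetric(unname(D), tol = 1e-12))
        stop("distance matrix must be symmetric")
    n <- nrow(D)
    if (n < 3L) stop("need at least 3 taxa")
    labels <- rownames(D)
    if (is.null(labels)) labels <- paste0("t", seq_len(n))

    nodeIds <- seq_len(n)          # ape ids; internals assigned later
    nextInternal <- n + 2L         # reserve n+1 for the final (root) node
    edges <- matrix(0L, 0L, 2L)
    lens <- numeric()
    active <- seq_len(n)
    Dw <- D

    while (length(active) > 3L) {
        m <- length(active)
        r <- rowSums(Dw)
        Q <- (m - 2) * Dw - outer(r, r, "+")
        diag(Q) <- Inf
        best <- which(Q == min(Q), arr.ind = TRUE)
        best <- best[best[, 1] < best[, 2], , drop = FALSE]
        best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1L, ]
        i <- best[1L]; j <- best[2L]
        li <- Dw[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
        lj <- Dw[i, j] - li
        if (li < 0) { lj <- lj + li; li <- 0 }
        if (lj < 0) { li <- li + lj; lj <- 0 }
        u <- nextInternal
        nextInternal <- nextInternal + 1L
        edges <- rbind(edges, c(u, nodeIds[active[i]]),
                       c(u, nodeIds[active[j]]))
        lens <- c(lens, li, lj)
        dNew <- (Dw[i, ] + Dw[j, ] - Dw[i, j]) / 2
        keep <- setdiff(seq_len(m), c(i, j))
        Dw <- rbind(cbind(Dw[keep, keep, drop = FALSE], dNew[keep]),
                    c(dNew[keep], 0))
        active <- c(active[keep], length(nodeIds) + 1L)
        nodeIds <- c(nodeIds, u)
    }
    ## final three-point join onto the root trifurcation
    a <- active[1L]; b <- active[2L]; c3 <- active[3L]
    la <- max((Dw[1, 2] + Dw[1, 3] - Dw[2, 3]) / 2, 0)
    lb <- max((Dw[1, 2] + Dw[2, 3] - Dw[1, 3]) / 2, 0)
    lc <- max((Dw[1, 3] + Dw[2, 3] - Dw[1, 2]) / 2, 0)
    root <- n + 1L
    edges <- rbind(edges, c(root, nodeIds[a]), c(root, nodeIds[b]),
                   c(root, nodeIds[c3]))
    lens <- c(lens, la, lb, lc)

    phy <- structure(list(edge = edges, edge.length = lens,
                          tip.label = labels,
                          Nnode = n - 2L), class = "phylo")
    phy <- ape::reorder.phylo(phy, "cladewise")
    phy
}

#' Fitch parsimony with acctran-style branch mutation counts
#'
#' Bottom-up Fitch counting of state changes for binary characters on an
#' unrooted tree (missing leaf states are uninformative), followed by a
#' top-down resolution that fixes each node to its parent's state when
#' possible, so forced changes land on the most root-proximal branch.
#' The root state prefers absence (0), the ancestral state for somatic
#' mutations. Branch lengths of the returned tree are the per-branch
#' mutation counts.
#'
#' @param tree an unrooted binary `phylo`; tip labels must match the
#'   rows of `bin`.
#' @param bin cells x sites matrix of 1/0/NA.
#' @param siteWeights optional per-site weights (default 1).
#' @return list with `score` (total weighted changes), `tree` (with
#'   branch lengths = mutation counts), and `edgeCounts` (count per
#'   edge, in `tree$edge` order).
#' @export
fitchParsimony <- function(tree, bin, siteWeights = NULL) {
    if (!setequal(tree$tip.label, rownames(bin)))
        stop("tree tip labels do not match the cells of the matrix")
    ntip <- length(tree$tip.label)
    nn <- ntip + tree$Nnode
    ns <- ncol(bin)
    if (is.null(siteWeights)) siteWeights <- rep(1, ns)
    bin <- bin[tree$tip.label, , drop = FALSE]

    ## state sets as bitmasks: 1 = {0}, 2 = {1}, 3 = {0,1}
    sets <- matrix(0L, nn, ns)
    sets[seq_len(ntip), ] <- ifelse(is.na(bin), 3L, ifelse(bin == 1L, 2L, 1L))

    ## bottom-up: postorder guarantees a child's set is final before the
    ## edge into its parent is processed; a parent's set accumulates by
    ## intersection, falling back to union (one counted change) when empty
    po <- ape::reorder.phylo(tree, "postorder")
    score <- 0
    for (k in seq_len(nrow(po$edge))) {
        u <- po$edge[k, 1L]; v <- po$edge[k, 2L]
        if (all(sets[u, ] == 0L)) {
            sets[u, ] <- sets[v, ]
        } else {
            inter <- bitwAnd(sets[u, ], sets[v, ])
            conflict <- inter == 0L
            score <- score + sum(siteWeights[conflict])
            sets[u, ] <- ifelse(conflict, bitwOr(sets[u, ], sets[v, ]), inter)
        }
    }

    ## top-down resolution; root prefers state 0 when ambiguous
    root <- ntip + 1L
    state <- matrix(NA_integer_, nn, ns)
    state[root, ] <- ifelse(bitwAnd(sets[root, ], 1L) > 0L, 1L, 2L)
    pre <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]
    edgeCounts <- numeric(nrow(tree$edge))
    edgeKey <- paste(tree$edge[, 1L], tree$edge[, 2L])
    for (k in seq_len(nrow(pre))) {
        p <- pre[k, 1L]; v <- pre[k, 2L]
        keepParent <- bitwAnd(sets[v, ], state[p, ]) > 0L
        ## a forced child takes the other state (bitmasks 1 <-> 2)
        state[v, ] <- ifelse(keepParent, state[p, ], 3L - state[p, ])
        changed <- state[v, ] != state[p, ]
        edgeCounts[match(paste(p, v), edgeKey)] <-
            sum(siteWeights[changed])
    }
    out <- tree
    out$edge.length <- edgeCounts
    list(score = score, tree = out, edgeCounts = edgeCounts)
}

## hill-climb over NNI neighbours until no improvement
.nniHillClimb <- function(tree, bin, siteWeights = NULL) {
    cur <- tree
    curScore <- fitchParsimony(cur, bin, siteWeights)$score
    repeat {
        nbrs <- phangorn::nni(cur)
        scores <- vapply(nbrs, function(t)
            fitchParsimony(t, bin, siteWeights)$score, 0)
        if (min(scores) < curScore) {
            cur <- nbrs[[which.min(scores)]]
            curScore <- min(scores)
        } else break
    }
    list(tree = cur, score = curScore)
}

#' Parsimony-ratchet tree search
#'
#' Starts from the neighbor-joining topology and alternates
#' nearest-neighbor-interchange hill climbing under perturbed character
#' weights (a random 10% of sites doubled) with hill climbing under the
#' original weights, keeping the best scoring tree. With `nIters = 0`
#' the neighbor-joining tree is returned unchanged.
#'
#' @param bin cells x sites matrix of 1/0/NA (>= 4 cells).
#' @param nIters number of perturbation rounds (default 25).
#' @param seed integer RNG seed (mandatory for reproducibility).
#' @param upweightFrac fraction of characters upweighted per round.
#' @return list with `tree` (branch lengths = acctran mutation counts)
#'   and `score` (parsimony score).
#' @export
ratchetSearch <- function(bin, nIters = 25L, seed, upweightFrac = 0.1) {
    if (nrow(bin) < 4L) stop("ratchet search needs at least 4 cells")
    if (missing(seed)) stop("seed is required")
    set.seed(seed)
    njTree <- neighborJoining(pairwiseDistance(bin))
    if (nIters == 0L) {
        f <- fitchParsimony(njTree, bin)
        return(list(tree = f$tree, score = f$score))
    }
    best <- .nniHillClimb(njTree, bin)
    for (it in seq_len(nIters)) {
        w <- 1 + as.numeric(runif(ncol(bin)) < upweightFrac)
        pert <- .nniHillClimb(best$tree, bin, w)
        cand <- .nniHillClimb(pert$tree, bin)
        if (cand$score < best$score) best <- cand
    }
    f <- fitchParsimony(best$tree, bin)
    list(tree = f$tree, score = f$score)
}

#' Identify subclones on a mutation-annotated tree
#'
#' Every internal edge of the unrooted tree induces a bipartition of the
#' cells; each side with at least `minCells` cells whose supporting
#' branch carries at least `minSupport` mutations is a candidate
#' subclone, and maximal candidates (not properly contained in another)
#' are reported.
#'
#' @param tree a `phylo` whose branch lengths are mutation counts (from
#'   [fitchParsimony()] or [ratchetSearch()]).
#' @param minCells minimum cells per subclone (default 5, i.e. "more
#'   than four cells").
#' @param minSupport minimum mutations on the supporting branch.
#' @return data.frame with `subclone`, `n_cells`, `support`, and a
#'   comma-separated `cells` column; zero rows when none qualify.
#' @export
findSubclones <- function(tree, minCells = 5L, minSupport = 1L) {
    ntip <- length(tree$tip.label)
    cands <- list()
    for (k in seq_len(nrow(tree$edge))) {
        child <- tree$edge[k, 2L]
        if (child <= ntip) next    # pendant edge
        if (tree$edge.length[k] < minSupport) next
        clade <- ape::extract.clade(tree, child)$tip.label
        other <- setdiff(tree$tip.label, clade)
        for (side in list(clade, other))
            if (length(side) >= minCells)
                cands <- c(cands, list(list(cells = sort(side),
                                            support = tree$edge.length[k])))
    }
    if (!length(cands))
        return(data.frame(subclone = integer(), n_cells = integer(),
                          support = numeric(), cells = character(),
                          stringsAsFactors = FALSE))
    keep <- vapply(seq_along(cands), function(i) {
        !any(vapply(seq_along(cands), function(j) {
            i != j && length(cands[[i]]$cells) < length(cands[[j]]$cells) &&
                all(cands[[i]]$cells %in% cands[[j]]$cells)
        }, TRUE))
    }, TRUE)
    cands <- cands[keep]
    ## de-duplicate identical cell sets
    keys <- vapply(cands, function(x) paste(x$cells, collapse = ","), "")
    cands <- cands[!duplicated(keys)]
    data.frame(subclone = seq_along(cands),
               n_cells = vapply(cands, function(x) length(x$cells), 0L),
               support = vapply(cands, function(x) x$support, 0),
               cells = vapply(cands, function(x)
                   paste(x$cells, collapse = ","), ""),
               stringsAsFactors = FALSE)
}

#' Mutation saturation (rarefaction) curve
#'
#' For each k, the mean over random cell orderings of the cumulative
#' number of unique SNVs in the first k cells, with its Monte-Carlo SD,
#' alongside the closed-form expectation
#' E[U_k] = sum_s (1 - C(n - c_s, k) / C(n, k)) where c_s is the number
#' of cells carrying SNV s.
#'
#' @param snvSets named list, one character vector of SNV keys per cell.
#' @param nPerm number of random orderings (default 100).
#' @param seed integer RNG seed.
#' @return data.frame with `k`, `mc_mean`, `mc_sd`, `expected`.
#' @export
saturationCurve <- function(snvSets, nPerm = 100L, seed = 1L) {
    set.seed(seed)
    n <- length(snvSets)
    allSnvs <- unique(unlist(snvSets))
    carriers <- vapply(allSnvs, function(s)
        sum(vapply(snvSets, function(x) s %in% x, TRUE)), 0L)
    cum <- matrix(0L, nPerm, n)
    for (p in seq_len(nPerm)) {
        ord <- sample.int(n)
        seen <- character(0)
        for (k in seq_len(n)) {
            seen <- union(seen, snvSets[[ord[k]]])
            cum[p, k] <- length(seen)
        }
    }
    expected <- vapply(seq_len(n), function(k)
        sum(1 - choose(n - carriers, k) / choose(n, k)), 0)
    data.frame(k = seq_len(n), mc_mean = colMeans(cum),
               mc_sd = apply(cum, 2L, sd), expected = expected)
}

## percent formatting: nearest integer, except keep one decimal when the
## truncated first decimal is exactly 5 (55.555... prints as 55.5)
.formatPercent <- function(fraction) {
    p <- 100 * fraction
    firstDec <- floor(p * 10 + 1e-9) %% 10
    if (abs(firstDec - 5) < 1e-9 && abs(p - round(p)) > 1e-9)
        floor(p * 10 + 1e-9) / 10
    else round(p)
}

#' Per-gene mutation frequency in a cell group
#'
#' A cell counts as mutated when any site annotated to the gene is
#' MUTANT; the denominator is every cell of the group, including cells
#' without coverage.
#'
#' @param mm a [MutationMatrix-class] with `gene` in its row metadata.
#' @param gene gene symbol.
#' @param cells cell ids defining the group.
#' @return list with `count`, `total`, `fraction`, and `percent`
#'   (reporting-rounded).
#' @examples
#' ## 15 of 18 cells -> 83%
#' @export
mutationFrequency <- function(mm, gene, cells) {
    if (!length(cells)) stop("empty cell group")
    sites <- which(rowData(mm)$gene == gene)
    st <- statusMatrix(mm)[sites, cells, drop = FALSE]
    count <- sum(apply(st == .STATUS_MUTANT, 2L, any))
    list(count = count, total = length(cells),
         fraction = count / length(cells),
         percent = .formatPercent(count / length(cells)))
}

#' Co-occurrence frequency of two mutated genes
#'
#' Cells MUTANT for at least one site of each gene, over the group size.
#'
#' @inheritParams mutationFrequency
#' @param geneA,geneB gene symbols.
#' @return list with `count`, `total`, `fraction`, `percent`.
#' @export
cooccurrenceFrequency <- function(mm, geneA, geneB, cells) {
    if (!length(cells)) stop("empty cell group")
    st <- statusMatrix(mm)
    hasMut <- function(g) {
        sites <- which(rowData(mm)$gene == g)
        apply(st[sites, cells, drop = FALSE] == .STATUS_MUTANT, 2L, any)
    }
    count <- sum(hasMut(geneA) & hasMut(geneB))
    list(count = count, total = length(cells),
         fraction = count / length(cells),
         percent = .formatPercent(count / length(cells)))
}
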