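test_that("binary conversion and pairwise distances honor missing data", {
    st <- matrix(c("M", "W", ".",
                   "M", "M", "W"), nrow = 3,
                 dimnames = list(NULL, c("c1", "c2")))
    mm <- MutationMatrix(st, data.frame(chrom = "chr1", pos = 1:3,
                                        ref = "A", alt = "T"))
    bin <- asBinaryMatrix(mm)
    expect_identical(unname(bin["c1", ]), c(1L, 0L, NA))
    expect_identical(unname(bin["c2", ]), c(1L, 1L, 0L))

    ident <- rbind(a = c(1, 0, 1), b = c(1, 0, 1))
    expect_equal(pairwiseDistance(ident)["a", "b"], 0)

    comp <- rbind(a = rep(1, 10), b = rep(0, 10))
    expect_equal(pairwiseDistance(comp)["a", "b"], 1)

    ## scattered missing entries vs a pairwise-complete loop oracle
    set.seed(12)
    m <- matrix(sample(c(0L, 1L, NA), 8 * 30, TRUE,
                       prob = c(.4, .4, .2)), 8, 30,
                dimnames = list(paste0("c", 1:8), NULL))
    D <- pairwiseDistance(m)
    for (i in 1:7) for (j in (i + 1):8) {
        sh <- !is.na(m[i, ]) & !is.na(m[j, ])
        expect_equal(D[i, j], mean(m[i, sh] != m[j, sh]))
    }
    expect_true(isSymmetric(D))

    none <- rbind(a = c(1, NA), b = c(NA, 0))
    expect_error(pairwiseDistance(none), "share no informative sites")
})

test_that("neighbor joining recovers additive trees", {
    ## n = 3: closed-form three-point branch lengths
    D3 <- matrix(c(0, 5, 9,
                   5, 0, 10,
                   9, 10, 0), 3, 3,
                 dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
    t3 <- neighborJoining(D3)
    expect_identical(sort(t3$tip.label), c("a", "b", "c"))
    got <- setNames(t3$edge.length,
                    t3$tip.label[t3$edge[, 2]])
    expect_equal(got[["a"]], (5 + 9 - 10) / 2)
    expect_equal(got[["b"]], (5 + 10 - 9) / 2)
    expect_equal(got[["c"]], (9 + 10 - 5) / 2)

    expect_error(neighborJoining(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")

    ## additive matrices from random trees: topology is recovered
    ## (reference implementation ape::nj as an independent cross-check)
    for (seed in 1:5) for (n in c(5, 8)) {
        cs <- makeAdditiveCase(n, seed)
        mine <- neighborJoining(cs$D)
        expect_equal(phangorn::RF.dist(mine, cs$tree), 0,
                     label = sprintf("n=%d seed=%d vs truth", n, seed))
        expect_equal(phangorn::RF.dist(mine, ape::nj(cs$D)), 0)
        ## branch lengths reproduce the additive distances
        expect_equal(cophenetic(mine)[rownames(cs$D), colnames(cs$D)],
                     cs$D, tolerance = 1e-9)
    }

    ## zero-noise two-clone matrix: the tree separates the clones
    sim <- makeTwoCloneSim(seed = 61)
    res <- runSnvPipeline(sim$sites, cleanNormal(sim$sites))
    bin <- asBinaryMatrix(res$matrix)
    tr <- neighborJoining(pairwiseDistance(bin))
    cloneB <- sim$assignments$cell_id[sim$assignments$clone_id == "C2"]
    parts <- ape::prop.part(tr)
    sides <- lapply(parts, function(p) tr$tip.label[p])
    split <- any(vapply(sides, function(s)
        setequal(s, cloneB) || setequal(s, setdiff(tr$tip.label, cloneB)),
        TRUE))
    expect_true(split)
})

test_that("Fitch counts match exhaustive parsimony and place changes", {
    set.seed(14)
    cs <- makeAdditiveCase(6, 3)
    tr <- cs$tree

    ## invariant character: no changes
    inv <- matrix(1L, 6, 1, dimnames = list(tr$tip.label, NULL))
    expect_equal(fitchParsimony(tr, inv)$score, 0)

    ## private character: one change on the pendant branch
    priv <- matrix(0L, 6, 1, dimnames = list(tr$tip.label, NULL))
    priv["t3", 1] <- 1L
    f <- fitchParsimony(tr, priv)
    expect_equal(f$score, 1)
    pend <- which(tr$edge[, 2] == which(tr$tip.label == "t3"))
    expect_equal(f$tree$edge.length[pend], 1)
    expect_equal(sum(f$tree$edge.length), 1)

    ## random instances vs the exhaustive assignment oracle
    for (seed in 1:4) {
        set.seed(seed)
        bin <- matrix(sample(c(0L, 1L, NA), 6 * 12, TRUE,
                             prob = c(.45, .45, .1)), 6, 12,
                      dimnames = list(tr$tip.label, NULL))
        mine <- fitchParsimony(tr, bin)
        expect_equal(mine$score, fitchExhaustiveOracle(tr, bin))
        ## branch counts always sum to the parsimony score
        expect_equal(sum(mine$edgeCounts), mine$score)
        ## cross-check with phangorn's Fitch implementation
        pd <- phangorn::phyDat(ifelse(is.na(bin), "?", bin),
                               type = "USER", levels = c("0", "1"))
        expect_equal(mine$score,
                     as.numeric(phangorn::parsimony(tr, pd)))
    }

    expect_error(fitchParsimony(tr, matrix(0L, 2, 1,
                                           dimnames = list(c("x", "y"),
                                                           NULL))),
                 "tip labels")
})

test_that("the parsimony ratchet attains the exhaustive optimum", {
    ## perfect phylogeny: every polymorphic mutation arises exactly once
    ## (mutations carried by every cell are invariant on the tree)
    sim <- makeTwoCloneSim(seed = 71)
    res <- runSnvPipeline(sim$sites, cleanNormal(sim$sites))
    bin <- asBinaryMatrix(res$matrix)
    carriers <- colSums(bin)
    nPoly <- sum(carriers > 0 & carriers < nrow(bin))
    rs <- ratchetSearch(bin, nIters = 3L, seed = 5)
    expect_equal(rs$score, nPoly)

    ## nIters = 0 returns the neighbor-joining start
    nj0 <- ratchetSearch(bin, nIters = 0L, seed = 5)
    njTree <- neighborJoining(pairwiseDistance(bin))
    expect_equal(nj0$score, fitchParsimony(njTree, bin)$score)

    ## 7-leaf random instance: score equals the optimum over all 945
    ## unrooted topologies, scored by an independent implementation
    set.seed(15)
    bin7 <- matrix(sample(c(0L, 1L), 7 * 14, TRUE), 7, 14,
                   dimnames = list(paste0("c", 1:7), NULL))
    bin7[1, 1:7] <- 1L; bin7[2, 1:7] <- 1L   # some shared structure
    rs7 <- ratchetSearch(bin7, nIters = 10L, seed = 6)
    pd7 <- phangorn::phyDat(bin7, type = "USER", levels = c("0", "1"))
    all7 <- phangorn::allTrees(7, rooted = FALSE,
                               tip.label = rownames(bin7))
    best <- min(vapply(all7, function(t)
        as.numeric(phangorn::parsimony(t, pd7)), 0))
    expect_equal(rs7$score, best)

    expect_error(ratchetSearch(bin7[1:3, ], nIters = 1L, seed = 1),
                 "4 cells")
    expect_error(ratchetSearch(bin7, nIters = 1L), "seed")
})

test_that("subclones are >= 5-cell mutation-supported clades", {
    ## star tree: no internal edges, no subclones
    star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1,e:1,f:1);")
    expect_identical(nrow(findSubclones(star)), 0L)

    ## two clones of 10 + 10 cells: exactly the two clades
    sim <- makeTwoCloneSim(nA = 10L, nB = 10L, seed = 81)
    res <- runSnvPipeline(sim$sites, cleanNormal(sim$sites))
    rs <- ratchetSearch(asBinaryMatrix(res$matrix), nIters = 2L, seed = 7)
    sub <- findSubclones(rs$tree)
    expect_identical(nrow(sub), 2L)
    gotSets <- lapply(strsplit(sub$cells, ","), sort)
    cloneSets <- lapply(split(sim$assignments$cell_id,
                              sim$assignments$clone_id), sort)
    expect_setequal(vapply(gotSets, paste, "", collapse = ","),
                    vapply(cloneSets, paste, "", collapse = ","))

    ## a 4-cell clone is not reported at the >= 5 rule
    sim2 <- makeTwoCloneSim(nA = 12L, nB = 4L, seed = 82)
    res2 <- runSnvPipeline(sim2$sites, cleanNormal(sim2$sites))
    rs2 <- ratchetSearch(asBinaryMatrix(res2$matrix), nIters = 2L, seed = 8)
    sub2 <- findSubclones(rs2$tree)
    nB <- sum(sim2$assignments$clone_id == "C2")
    expect_false(any(sub2$n_cells == nB))
})

test_that("saturation curves match the closed-form rarefaction", {
    ## identical cells: flat at the total
    same <- replicate(6, paste0("s", 1:9), simplify = FALSE)
    names(same) <- paste0("c", 1:6)
    satS <- saturationCurve(same, nPerm = 20L, seed = 1)
    expect_true(all(satS$mc_mean == 9))
    expect_equal(satS$expected, rep(9, 6))

    ## pairwise-disjoint sets: linear growth
    disj <- lapply(1:5, function(i) paste0("s", i, "_", 1:4))
    names(disj) <- paste0("c", 1:5)
    satD <- saturationCurve(disj, nPerm = 20L, seed = 2)
    expect_equal(satD$mc_mean, 4 * (1:5))
    expect_equal(satD$expected, 4 * (1:5))

    ## random instance: Monte Carlo within 3 SDs of the closed form
    set.seed(16)
    rnd <- lapply(1:12, function(i)
        sample(paste0("s", 1:40), sample(5:20, 1)))
    names(rnd) <- paste0("c", 1:12)
    sat <- saturationCurve(rnd, nPerm = 300L, seed = 3)
    seMean <- sat$mc_sd / sqrt(300)
    expect_true(all(abs(sat$mc_mean - sat$expected) <=
                        3 * pmax(seMean, 1e-9)))
    ## monotone non-decreasing, ends at the union size
    expect_true(all(diff(sat$mc_mean) >= 0))
    expect_equal(sat$mc_mean[12], length(unique(unlist(rnd))))
})

test_that("incidence frequencies reproduce printed-count arithmetic", {
    fx <- makeIncidenceFixture()
    pt <- fx$PT; lmt <- fx$LMT
    ptCells <- colnames(statusMatrix(pt))
    lmtCells <- colnames(statusMatrix(lmt))

    a <- mutationFrequency(pt, "Arhgef11", ptCells)
    expect_identical(c(a$count, a$total), c(15L, 18L))
    expect_equal(a$percent, 83)

    p <- mutationFrequency(pt, "Plekha5", ptCells)
    expect_equal(p$percent, 55.5)

    co <- cooccurrenceFrequency(lmt, "Arhgef11", "Plekha5", lmtCells)
    expect_identical(co$count, 13L)
    expect_equal(co$percent, 65)

    expect_error(mutationFrequency(pt, "Arhgef11", character()), "empty")

    ## property: co-occurrence never exceeds either marginal
    set.seed(17)
    st <- matrix(sample(c("M", "W", "."), 4 * 30, TRUE), 4, 30,
                 dimnames = list(NULL, paste0("c", 1:30)))
    mm <- MutationMatrix(st, data.frame(chrom = "chr1", pos = 1:4,
                                        ref = "A", alt = "T",
                                        gene = c("gA", "gA", "gB", "gB")))
    cells <- paste0("c", 1:30)
    fA <- mutationFrequency(mm, "gA", cells)$count
    fB <- mutationFrequency(mm, "gB", cells)$count
    fAB <- cooccurrenceFrequency(mm, "gA", "gB", cells)$count
    expect_lte(fAB, min(fA, fB))
    ## counting oracle
    mutA <- apply(statusMatrix(mm)[1:2, ] == "M", 2, any)
    mutB <- apply(statusMatrix(mm)[3:4, ] == "M", 2, any)
    expect_identical(fAB, sum(mutA & mutB))
})
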