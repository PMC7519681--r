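test_that("clone trees satisfy their structural invariants", {
    gm <- simGeneModel(genesPerChrom = 30L)

    ## degenerate single-clone tree
    t1 <- buildCloneTree(1L, snvsPerEdge = 5L, geneModel = gm, seed = 1)
    expect_identical(nrow(t1@clones), 1L)
    expect_identical(nrow(cloneGenotype(t1, "C1")), 5L)

    ## no CNV spec: neutral genome everywhere
    expect_true(all(scExome:::.copyNumberPerGene(t1, "C1", gm) == 2L))

    ## genotype nesting: every clone's SNV set contains its parent's,
    ## verified by explicit path-union recomputation
    t4 <- buildCloneTree(4L, snvsPerEdge = 6L, geneModel = gm, seed = 7)
    for (k in seq_len(4L)) {
        cid <- t4@clones$clone_id[k]
        pid <- t4@clones$parent_id[k]
        ## independent oracle: walk parent pointers, union edge sets
        pathUnion <- function(id) {
            keys <- character()
            while (!is.na(id)) {
                s <- t4@snvAssignments[[id]]
                keys <- c(keys, paste(s$chrom, s$pos))
                id <- t4@clones$parent_id[match(id, t4@clones$clone_id)]
            }
            keys
        }
        g <- cloneGenotype(t4, cid)
        expect_setequal(paste(g$chrom, g$pos), pathUnion(cid))
        if (!is.na(pid))
            expect_true(all(pathUnion(pid) %in% pathUnion(cid)))
    }

    ## edge SNV sets are disjoint and each truth site appears once
    truth <- truthSites(t4)
    expect_identical(anyDuplicated(paste(truth$chrom, truth$pos)), 0L)

    expect_error(buildCloneTree(0L), "nClones")
})

test_that("cell sampling follows the clone fractions", {
    gm <- simGeneModel(genesPerChrom = 10L)
    tree <- buildCloneTree(2L, snvsPerEdge = 2L, geneModel = gm, seed = 1,
                           fractions = list(S1 = c(C1 = 0.6, C2 = 0.4),
                                            pure = c(C1 = 1, C2 = 0)))
    expect_error(sampleCells(tree, "nope", 5L), "nope")

    allA <- sampleCells(tree, "pure", 25L, seed = 2)
    expect_true(all(allA$clone_id == "C1"))

    expect_identical(nrow(sampleCells(tree, "S1", 0L)), 0L)

    big <- sampleCells(tree, "S1", 10000L, seed = 3)
    pA <- mean(big$clone_id == "C1")
    se <- sqrt(0.6 * 0.4 / 10000)
    expect_lt(abs(pA - 0.6), 3 * se)
})

test_that("site counts reproduce the heterozygous noise model", {
    gm <- simGeneModel(genesPerChrom = 10L)
    tree <- buildCloneTree(1L, snvsPerEdge = 1L, geneModel = gm, seed = 5)
    cells <- sampleCells(tree, "S1", 1000L, seed = 6)

    ## noiseless diploid het: mean VAF within 3 SDs of 0.5
    cfg <- simConfig(meanDepth = 50, wgaSigma = 0, adoRate = 0,
                     seqErrorRate = 0, seed = 7)
    sc <- simulateSiteCounts(cells, tree, cfg)
    vaf <- sc$alt_reads / (sc$ref_reads + sc$alt_reads)
    se <- sqrt(0.25 / (50 * 1000))   # binomial, Poisson-averaged depth
    expect_lt(abs(mean(vaf) - 0.5), 3 * se)

    ## zero mean depth: all sites uncovered
    sc0 <- simulateSiteCounts(cells, tree, simConfig(meanDepth = 0, seed = 1))
    expect_true(all(sc0$ref_reads + sc0$alt_reads == 0))

    ## wild-type site: alt fraction tracks the error rate
    treeWt <- buildCloneTree(2L, snvsPerEdge = 1L, geneModel = gm, seed = 5,
                             fractions = list(S1 = c(C1 = 1, C2 = 0)))
    wtCells <- sampleCells(treeWt, "S1", 400L, seed = 6)
    e <- 0.05
    scE <- simulateSiteCounts(wtCells, treeWt,
                              simConfig(meanDepth = 100, wgaSigma = 0,
                                        adoRate = 0, seqErrorRate = e,
                                        seed = 8))
    wtRows <- scE[!paste(scE$chrom, scE$pos) %in%
                      with(cloneGenotype(treeWt, "C1"), paste(chrom, pos)), ]
    altFrac <- sum(wtRows$alt_reads) / sum(wtRows$ref_reads + wtRows$alt_reads)
    expect_lt(abs(altFrac - e), 3 * sqrt(e * (1 - e) / (100 * 400)))
})

test_that("gene counts scale with copy number and exonic length", {
    gm <- simGeneModel(genesPerChrom = 50L, chroms = c("chr1", "chr2"))
    tree <- buildCloneTree(1L, snvsPerEdge = 2L, geneModel = gm, seed = 1,
                           cnvSpec = data.frame(clone = 1, chrom = "chr2",
                                                cn = 4))
    cells <- sampleCells(tree, "S1", 200L, seed = 2)
    cfg <- simConfig(wgaSigma = 0, librarySize = 1e5, seed = 3)
    counts <- simulateGeneCounts(cells, tree, gm, cfg)

    isChr2 <- gm$chrom == "chr2"
    ratio <- mean(counts[isChr2, ]) / mean(counts[!isChr2, ])
    expect_lt(abs(ratio - 2), 0.05)

    ## neutral equal-length genes share one expected count
    tN <- buildCloneTree(1L, snvsPerEdge = 2L, geneModel = gm, seed = 1)
    cN <- simulateGeneCounts(cells, tN, gm, cfg)
    perGene <- rowMeans(cN)
    expect_lt(max(abs(perGene - mean(perGene))) / mean(perGene), 0.1)

    ## homozygous deletion: zero reads
    tDel <- buildCloneTree(1L, snvsPerEdge = 2L, geneModel = gm, seed = 1,
                           cnvSpec = data.frame(clone = 1, chrom = "chr2",
                                                cn = 0))
    cDel <- simulateGeneCounts(cells[1:5, ], tDel, gm, cfg)
    expect_true(all(cDel[isChr2, ] == 0))
})

test_that("bulk mixing follows purity arithmetic and conserves depth", {
    sim <- makeTwoCloneSim(nA = 20L, nB = 0L, snvsPerEdge = 4L, seed = 11,
                           meanDepth = 80)
    gc <- simulateGeneCounts(sim$assignments, sim$tree, sim$gm, sim$cfg)

    ## purity 1, monoclonal het: bulk VAF ~ 0.5
    b1 <- mixBulk(sim$sites, gc, sim$gm, purity = 1, config = sim$cfg,
                  deterministic = TRUE)
    root <- cloneGenotype(sim$tree, "C1")
    rootRows <- paste(b1$bulkSites$chrom, b1$bulkSites$pos) %in%
        paste(root$chrom, root$pos)
    vaf1 <- with(b1$bulkSites[rootRows, ],
                 alt_reads / (ref_reads + alt_reads))
    expect_true(all(abs(vaf1 - 0.5) < 0.05))

    ## purity 0: only the error floor remains
    b0 <- mixBulk(sim$sites, purity = 0, config = sim$cfg,
                  deterministic = TRUE)
    expect_true(all(b0$bulkSites$alt_reads == 0))   # error rate 0 here

    ## purity 0.4 clonal diploid het: E[bulk VAF] = 0.2 exactly in
    ## deterministic mode given the realized cell counts
    b04 <- mixBulk(sim$sites, purity = 0.4, config = sim$cfg,
                   deterministic = TRUE)
    cellAlt <- tapply(sim$sites$alt_reads,
                      paste(sim$sites$chrom, sim$sites$pos), sum)
    cellDepth <- tapply(sim$sites$ref_reads + sim$sites$alt_reads,
                        paste(sim$sites$chrom, sim$sites$pos), sum)
    key <- paste(b04$bulkSites$chrom, b04$bulkSites$pos)
    expLoad <- 0.4 * as.numeric(cellAlt[key])
    expDepth <- 0.4 * as.numeric(cellDepth[key]) +
        0.6 * as.numeric(cellDepth[key])
    expect_equal(b04$bulkSites$alt_reads, expLoad, tolerance = 1e-12)
    ## conservation: bulk depth equals the weighted component sum
    expect_equal(b04$bulkSites$ref_reads + b04$bulkSites$alt_reads,
                 expDepth, tolerance = 1e-12)
    vafExpect <- as.numeric(cellAlt[key] / cellDepth[key]) * 0.4
    gotVaf <- with(b04$bulkSites, alt_reads / (ref_reads + alt_reads))
    expect_equal(gotVaf, vafExpect, tolerance = 1e-12)
})

test_that("the simulator is byte-deterministic under a fixed seed", {
    run <- function() {
        gm <- simGeneModel(genesPerChrom = 15L)
        tree <- buildCloneTree(3L, snvsPerEdge = 5L, geneModel = gm,
                               seed = 21)
        simulateExperiment(tree, simConfig(nCellsPerSample = 8L, seed = 22),
                           gm)
    }
    a <- run()
    b <- run()
    expect_identical(a$siteCounts, b$siteCounts)
    expect_identical(a$geneCounts, b$geneCounts)
    expect_identical(a$bulk$S1$bulkSites, b$bulk$S1$bulkSites)
})

test_that("simulator round-trips through VCF and BED text formats", {
    sim <- makeTwoCloneSim(nA = 3L, nB = 2L, snvsPerEdge = 3L, seed = 9)
    vcf <- tempfile(fileext = ".vcf")
    writeSiteVcf(sim$sites, vcf)
    back <- readSiteVcf(vcf)
    orig <- sim$sites[order(sim$sites$cell_id, sim$sites$chrom,
                            sim$sites$pos), ]
    back <- back[order(back$cell_id, back$chrom, back$pos), ]
    expect_equal(back$ref_reads, orig$ref_reads)
    expect_equal(back$alt_reads, orig$alt_reads)

    bed <- tempfile(fileext = ".bed")
    writeGeneModelBed(sim$gm, bed)
    gm2 <- readGeneModelBed(bed)
    expect_equal(gm2$gene_id, sim$gm$gene_id)
    expect_equal(gm2$exonic_length, sim$gm$exonic_length)

    nwk <- writeCloneNewick(sim$tree)
    expect_match(nwk, "^\\(.*C1;$|.*;$")
    expect_s3_class(ape::read.tree(text = nwk), "phylo")
})
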