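test_that("windowed pi matches the single-site hand enumeration", {
    # one site, 4 chromosomes, alt count 2, 100-bp window:
    # 4 mismatching pairs of 6 -> 2/3 per site, 0.0066667 per bp
    gm <- asGenotypeMatrix(matrix(c(1L, 1L), 1, 2), chromLength = 100)
    w <- tileWindows(c(chr1 = 100), 100)
    expect_equal(windowPi(gm, w)[1], (2 * 2 * 2 / (4 * 3)) / 100,
                 tolerance = 1e-12)
    # no variants and monomorphic sites contribute zero
    gm0 <- asGenotypeMatrix(matrix(c(0L, 0L), 1, 2), chromLength = 100)
    expect_equal(as.numeric(windowPi(gm0, w)), 0)
})

test_that("windowed pi equals brute-force pairwise enumeration on random matrices", {
    set.seed(101)
    for (i in 1:30) {
        nS <- sample(1:20, 1)
        nI <- sample(2:6, 1)
        gt <- randomDosageMatrix(nS, nI, pMissing = ifelse(i %% 2, 0, 0.15))
        gm <- asGenotypeMatrix(gt, chromLength = 1000)
        w <- tileWindows(c(chr1 = 1000), 1000)
        expect_equal(as.numeric(windowPi(gm, w)), bruteForcePi(gt, 1000),
                     tolerance = 1e-10)
    }
})

test_that("Tajima's D matches its defining constants and boundary behaviour", {
    # pi-hat == S/a1 makes the numerator exactly zero
    expect_equal(tajimaD(4, 11, 6), 0)
    expect_true(is.na(tajimaD(10, 0, 0)))
    expect_error(tajimaD(3, 5, 2), "n >= 4")
    # frozen from the independent constant transcription
    expect_equal(tajimaD(10, 16, 4.2), -1.1915314904, tolerance = 1e-9)
    # sweep across n and S against the oracle
    for (n in c(4, 8, 22, 46)) for (S in c(1, 5, 40)) {
        piHat <- S / 2
        expect_equal(tajimaD(n, S, piHat), oracleTajimaD(n, S, piHat),
                     tolerance = 1e-12)
    }
})

test_that("Tajima's D is negative for singleton-only and positive for intermediate-only spectra", {
    n <- 10   # 5 diploids
    singletons <- matrix(0L, 12, 5)
    singletons[cbind(1:12, rep(1:5, length.out = 12))] <- 1L
    gmS <- asGenotypeMatrix(singletons, chromLength = 1000)
    w <- tileWindows(c(chr1 = 1000), 1000)
    expect_lt(windowTajimaD(gmS, w)[1], 0)
    inter <- matrix(1L, 12, 5)   # every site at frequency 1/2
    gmI <- asGenotypeMatrix(inter, chromLength = 1000)
    expect_gt(windowTajimaD(gmI, w)[1], 0)
})

test_that("per-site Weir-Cockerham components match hand-checked values", {
    # fixed difference between two pairs of diploids -> estimate 1
    comp <- wcSiteComponents(2, 2, 0, 1, 0, 0)
    expect_equal(comp$a / (comp$a + comp$b + comp$c), 1)
    # identical genotype arrays -> a <= 0, estimate <= 0
    comp <- wcSiteComponents(3, 3, 0.5, 0.5, 1 / 3, 1 / 3)
    expect_lte(comp$a, 0)
    expect_lte(comp$a / (comp$a + comp$b + comp$c), 0)
    # frozen oracle values for pop1 {0/0, 0/1}, pop2 {1/1, 0/1}
    comp <- wcSiteComponents(2, 2, 1 / 4, 3 / 4, 1 / 2, 1 / 2)
    expect_equal(comp$a, 0.0625, tolerance = 1e-12)
    expect_equal(comp$b, 0, tolerance = 1e-12)
    expect_equal(comp$c, 0.25, tolerance = 1e-12)
    expect_equal(comp$a / (comp$a + comp$b + comp$c), 0.2, tolerance = 1e-12)
})

test_that("Weir-Cockerham components equal the independent oracle on random tables", {
    set.seed(202)
    for (i in 1:60) {
        n1 <- sample(2:8, 1)
        n2 <- sample(2:8, 1)
        g1 <- sample(0:2, n1, replace = TRUE)
        g2 <- sample(0:2, n2, replace = TRUE)
        ora <- oracleWcComponents(list(g1, g2))
        comp <- wcSiteComponents(n1, n2, sum(g1) / (2 * n1), sum(g2) / (2 * n2),
                                 mean(g1 == 1), mean(g2 == 1))
        expect_equal(comp$a, unname(ora["a"]), tolerance = 1e-12)
        expect_equal(comp$b, unname(ora["b"]), tolerance = 1e-12)
        expect_equal(comp$c, unname(ora["c"]), tolerance = 1e-12)
    }
})

test_that("window F_ST is the ratio of sums, not the mean of ratios", {
    # two sites, hand-composed from the oracle components
    g1 <- list(c(0L, 1L, 0L), c(2L, 1L, 1L))
    g2 <- list(c(2L, 2L, 1L), c(0L, 0L, 1L))
    o1 <- oracleWcComponents(list(g1[[1]], g2[[1]]))
    o2 <- oracleWcComponents(list(g1[[2]], g2[[2]]))
    expected <- (o1["a"] + o2["a"]) / (sum(o1) + sum(o2))
    gt <- rbind(c(g1[[1]], g2[[1]]), c(g1[[2]], g2[[2]]))
    groups <- stats::setNames(rep(c("A", "B"), each = 3),
                              paste0("s", 1:6))
    colnames(gt) <- names(groups)
    gm <- asGenotypeMatrix(gt, chromLength = 100, groups = groups)
    w <- tileWindows(c(chr1 = 100), 100)
    expect_equal(windowFst(gm, w)[1], unname(expected), tolerance = 1e-12)
    meanOfRatios <- mean(c(o1["a"] / sum(o1), o2["a"] / sum(o2)))
    expect_false(isTRUE(all.equal(windowFst(gm, w)[1], meanOfRatios)))
    # a single-site window reduces to that site's estimate
    gm1 <- asGenotypeMatrix(gt[1, , drop = FALSE], chromLength = 100,
                            groups = groups)
    expect_equal(windowFst(gm1, w)[1], unname(o1["a"] / sum(o1)),
                 tolerance = 1e-12)
})

test_that("F_ST is invariant to label swap, allele relabeling and site order", {
    set.seed(303)
    gt <- randomDosageMatrix(60, 8)
    groups <- stats::setNames(rep(c("A", "B"), each = 4), colnames(gt))
    gm <- asGenotypeMatrix(gt, groups = groups)
    w <- tileWindows(chromLengths(gm), 200)
    f0 <- windowFst(gm, w)
    # swap population labels
    swapped <- stats::setNames(ifelse(groups == "A", "B", "A"), names(groups))
    expect_equal(windowFst(gm, w, groupLabels = swapped[colnames(gm)]), f0)
    # relabel ref <-> alt
    gmFlip <- asGenotypeMatrix(2L - gt, groups = groups)
    expect_equal(windowFst(gmFlip, w), f0)
    # shuffle site order before construction (constructor re-sorts)
    o <- sample(nrow(gt))
    gmShuf <- GenotypeMatrix(gt[o, ], chrom = rep("chr1", nrow(gt)),
                             pos = (seq_len(nrow(gt)) * 10L)[o],
                             groups = groups,
                             chromLengths = chromLengths(gm))
    expect_equal(windowFst(gmShuf, w), f0)
})

test_that("ROD follows its defining arithmetic", {
    expect_equal(rod(2.5e-4, 5.0e-4), 0.5)
    expect_equal(rod(3e-4, 3e-4), 0)
    expect_equal(rod(0, 5e-4), 1)
    expect_true(is.na(rod(1e-4, 0)))
    # identity: rod(x, y) + x/y = 1 exactly
    set.seed(4)
    x <- runif(20); y <- runif(20, 0.1, 1)
    expect_equal(rod(x, y) + x / y, rep(1, 20), tolerance = 1e-15)
})
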