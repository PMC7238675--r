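test_that("two-population simulation is deterministic for a fixed seed", {
    cfg <- twoPopSimConfig(nSites = 300, seed = 9)
    s1 <- simulateTwoPopulations(cfg)
    s2 <- simulateTwoPopulations(cfg)
    expect_identical(genotypes(s1$genotypes), genotypes(s2$genotypes))
    expect_identical(s1$truth$p_pop, s2$truth$p_pop)
    p1 <- tempfile(fileext = ".vcf"); p2 <- tempfile(fileext = ".vcf")
    simulateTwoPopulationVCF(cfg, p1)
    simulateTwoPopulationVCF(cfg, p2)
    expect_identical(readLines(p1), readLines(p2))
})

test_that("simulated frequencies and dosages stay within bounds", {
    cfg <- twoPopSimConfig(nSites = 2000, divergenceF = 0.3, seed = 21)
    sim <- simulateTwoPopulations(cfg)
    expect_true(all(sim$truth$p_anc >= 0.05 & sim$truth$p_anc <= 0.95))
    expect_true(all(sim$truth$p_pop >= 0 & sim$truth$p_pop <= 1))
    expect_true(all(genotypes(sim$genotypes) %in% 0:2))
    expect_error(twoPopSimConfig(divergenceF = 1), "divergenceF")
    expect_warning(simulateTwoPopulations(twoPopSimConfig(nSites = 0)),
                   "empty")
})

test_that("undifferentiated populations give near-zero genome-wide F_ST", {
    cfg <- twoPopSimConfig(nSites = 5000, divergenceF = 0, seed = 5)
    sim <- simulateTwoPopulations(cfg)
    expect_lt(abs(windowFst(sim$genotypes)), 0.02)
})

test_that("Balding-Nichols divergence is recovered by the ratio-of-sums estimator", {
    for (F in c(0.05, 0.15, 0.30)) {
        cfg <- twoPopSimConfig(nSites = 10000, divergenceF = F,
                               seed = 1000 + round(100 * F))
        sim <- simulateTwoPopulations(cfg)
        expect_lt(abs(windowFst(sim$genotypes) - F), 0.02)
    }
})

test_that("sweep windows lose diversity in the sweep population (sign test)", {
    sw <- GRanges("chr1", IRanges(start = seq(2e6, 18e6, 4e6) + 1,
                                  width = 1e5))
    wins <- tileWindows(c(chr1 = 2e7), 1e5)
    planted <- which(start(wins) %in% start(sw))
    lower <- 0
    nRep <- 20
    for (s in seq_len(nRep)) {
        cfg <- twoPopSimConfig(nSites = 4000, chromLength = 2e7,
                               divergenceF = 0.15, sweepWindows = sw,
                               sweepPop = "pop1", seed = 5000 + s)
        sim <- simulateTwoPopulations(cfg)
        pop1 <- names(which(sampleGroups(sim$genotypes) == "pop1"))
        p <- windowPi(sim$genotypes, wins, samples = pop1)
        lower <- lower + (mean(p[planted]) < mean(p[-planted]))
    }
    expect_lt(binom.test(lower, nRep, alternative = "greater")$p.value, 0.01)
})

test_that("gene drop with a zero-length map copies one parental haplotype", {
    ped <- data.frame(id = c("f1", "f2", "kid"), sire = c(NA, NA, "f1"),
                      dam = c(NA, NA, "f2"))
    map <- data.frame(marker = paste0("m", 1:10), chrom = "chr1",
                      bp = seq(1e5, 1e6, 1e5), cM = 0)
    sim <- simulatePedigreeGenotypes(ped, map, seed = 2)
    kid <- sim$haplotypes$kid$chr1
    expect_equal(length(unique(kid[, "hap1"])), 1L)
    expect_equal(length(unique(kid[, "hap2"])), 1L)
    expect_match(unique(kid[, "hap1"]), "^f2_")
    expect_match(unique(kid[, "hap2"]), "^f1_")
    expect_equal(nrow(sim$truth$crossovers), 0L)
})

test_that("crossover counts follow the map length (Poisson mean 1 per 100 cM)", {
    nKids <- 300
    ped <- data.frame(id = c("f1", "f2", paste0("k", seq_len(nKids))),
                      sire = c(NA, NA, rep("f1", nKids)),
                      dam = c(NA, NA, rep("f2", nKids)))
    map <- data.frame(marker = paste0("m", 1:11), chrom = "chr1",
                      bp = seq(0, 1e7, 1e6) + 1, cM = seq(0, 100, 10))
    sim <- simulatePedigreeGenotypes(ped, map, seed = 77)
    perMeiosis <- nrow(sim$truth$crossovers) / (2 * nKids)
    expect_lt(abs(perMeiosis - 1), 0.15)
})

test_that("pedigree validation rejects half-specified parents and cycles", {
    expect_error(validatePedigree(
        data.frame(id = c("a", "b"), sire = c(NA, "a"), dam = c(NA, NA))),
        "one known parent")
    expect_error(validatePedigree(
        data.frame(id = c("a", "b"), sire = c("b", "a"), dam = c("b", "a"))),
        "cycle")
    expect_error(validateGeneticMap(
        data.frame(marker = c("m1", "m2"), chrom = "c", bp = c(1, 2),
                   cM = c(2, 1))), "monotone")
})

test_that("an ancestor on both parental lines contributes segments to both haplotypes", {
    ped <- data.frame(
        id = c("Payne", "ConwayMayette", "PI159568", "Pedro", "UC56224",
               "Chandler"),
        sire = c(NA, NA, NA, "Payne", "Payne", "UC56224"),
        dam = c(NA, NA, NA, "ConwayMayette", "PI159568", "Pedro"))
    map <- data.frame(marker = paste0("m", 1:50), chrom = "chr1",
                      bp = seq(4e5, 2e7, 4e5), cM = seq(0, 80, length.out = 50))
    both <- 0
    for (s in 1:10) {
        sim <- simulatePedigreeGenotypes(ped, map, seed = 9000 + s)
        segs <- sim$truth$segments
        segs <- segs[segs$individual == "Chandler", ]
        payne <- grepl("^Payne_", segs$founder_hap)
        both <- both + (any(payne & segs$hap == 1) & any(payne & segs$hap == 2))
    }
    expect_gte(both, 5)
})

test_that("anchoring fixture: decoys carry the planted defects and truth is recoverable", {
    # noiseless: the filter keeps everything and anchoring equals the truth
    fx <- simulateAnchoringFixture(5, 6, seed = 31, nLG = 2)
    kept <- filterProbeAlignments(fx$alignments)
    expect_equal(nrow(kept), nrow(fx$alignments))
    oo <- assignOrderOrient(kept, fx$geneticMap)
    truth <- fx$truth$layout[order(fx$truth$layout$LG, fx$truth$layout$order), ]
    expect_equal(oo$anchored$scaffold, truth$scaffold)
    expect_equal(oo$anchored$orientation, truth$orientation)
    # 20% multi-hit decoys: the filter removes exactly the planted set
    fx2 <- simulateAnchoringFixture(6, 10, noise = list(multiHit = 0.2),
                                    seed = 32)
    kept2 <- filterProbeAlignments(fx2$alignments)
    expect_setequal(setdiff(fx2$alignments$probe, kept2$probe),
                    fx2$truth$decoys)
})
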