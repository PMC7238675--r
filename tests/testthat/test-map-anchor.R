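alnRow <- function(probe, target, tstart, identity = 99, coverage = 0.99,
                   n_hits = 1L) {
    data.frame(probe = probe, target = target, tstart = tstart,
               tend = tstart + 70, identity = identity, coverage = coverage,
               n_hits = n_hits, stringsAsFactors = FALSE)
}

test_that("alignment filter applies the >= boundary rules and is idempotent", {
    aln <- rbind(alnRow("p1", "s1", 100, identity = 99, coverage = 0.99),
                 alnRow("p2", "s1", 200, identity = 98.0),
                 alnRow("p3", "s1", 300, identity = 97.9),
                 alnRow("p4", "s1", 400, coverage = 0.95),
                 alnRow("p5", "s1", 500, coverage = 0.949),
                 alnRow("p6", "s1", 600, n_hits = 2L))
    kept <- filterProbeAlignments(aln)
    expect_setequal(kept$probe, c("p1", "p2", "p4"))
    expect_identical(filterProbeAlignments(kept), kept)
})

test_that("orientation follows the sign of the cM-vs-bp rank correlation", {
    map <- data.frame(marker = c("a", "b", "c"), LG = "1", cM = c(10, 20, 30))
    fwd <- rbind(alnRow("a", "s1", 1e5), alnRow("b", "s1", 2e5),
                 alnRow("c", "s1", 3e5))
    expect_equal(assignOrderOrient(fwd, map)$anchored$orientation, "+")
    rev <- rbind(alnRow("a", "s1", 3e5), alnRow("b", "s1", 2e5),
                 alnRow("c", "s1", 1e5))
    expect_equal(assignOrderOrient(rev, map)$anchored$orientation, "-")
    # one marker: orientation unknown
    one <- alnRow("a", "s1", 1e5)
    expect_equal(assignOrderOrient(one, map)$anchored$orientation, "unknown")
    # two scaffolds with opposite true orientations
    map2 <- data.frame(marker = c("a", "b", "c", "d"), LG = "1",
                       cM = c(10, 20, 30, 40))
    both <- rbind(alnRow("a", "s1", 1e5), alnRow("b", "s1", 2e5),
                  alnRow("c", "s2", 2e5), alnRow("d", "s2", 1e5))
    oo <- assignOrderOrient(both, map2)$anchored
    expect_equal(oo$orientation, c("+", "-"))
    expect_equal(oo$scaffold, c("s1", "s2"))
})

test_that("scaffolds with strong linkage-group conflicts stay unanchored", {
    map <- data.frame(marker = c("a", "b", "c", "d"), LG = c("1", "1", "2", "2"),
                      cM = c(10, 20, 5, 15))
    aln <- rbind(alnRow("a", "s1", 1e5), alnRow("b", "s1", 2e5),
                 alnRow("c", "s1", 3e5), alnRow("d", "s1", 4e5))
    oo <- assignOrderOrient(aln, map)
    expect_equal(nrow(oo$anchored), 0L)
    expect_equal(oo$unanchored$reason, "LG conflict")
    expect_error(assignOrderOrient(alnRow("zz", "s1", 1), map), "absent")
})

test_that("pseudomolecule layout inserts fixed gaps and lifts coordinates exactly", {
    anchored <- data.frame(scaffold = c("s1", "s2"), LG = "1",
                           orientation = c("+", "-"), mean_cM = c(5, 15),
                           n_markers = c(3L, 3L))
    lens <- c(s1 = 1e6, s2 = 2e6)
    agp <- buildPseudomolecules(anchored, lens)
    expect_equal(max(agp$object_end), 1e6 + 1e5 + 2e6)   # 3,100,000
    expect_equal(agp$component_type, c("W", "N", "W"))
    expect_equal(agp$component_id[2], "100000")
    # single scaffold: no gap rows, length unchanged
    agp1 <- buildPseudomolecules(anchored[1, ], lens)
    expect_equal(nrow(agp1), 1L)
    expect_equal(agp1$object_end, 1e6)
    # minus-strand lift: x -> offset + (len - x + 1)
    lift <- liftToPseudomolecule(agp, "s2", 1)
    expect_equal(lift$pos, 1e6 + 1e5 + 2e6)
    # round-trip identity on 100 random positions in both scaffolds
    set.seed(8)
    sc <- sample(c("s1", "s2"), 100, replace = TRUE)
    p <- ifelse(sc == "s1", sample(1e6, 100, replace = TRUE),
                sample(2e6, 100, replace = TRUE))
    up <- liftToPseudomolecule(agp, sc, p)
    back <- liftFromPseudomolecule(agp, up$object, up$pos)
    expect_equal(back$scaffold, sc)
    expect_equal(back$pos, p)
    expect_error(buildPseudomolecules(rbind(anchored, anchored[1, ]), lens),
                 "more than once")
})

test_that("Marey rates recover a linear map exactly and need two markers", {
    mk <- data.frame(chrom = "chr1", bp = seq(2e5, 3e7, 2e5),
                     cM = seq(2e5, 3e7, 2e5) / 1e6 * 2)
    mr <- mareyRecombinationRate(mk, c(chr1 = 3e7))
    expect_true(all(abs(mr$rate_cM_Mb - 2) < 1e-9))
    # a window with a single marker is undefined
    mk1 <- data.frame(chrom = "chr1", bp = 5e6, cM = 10)
    mr1 <- mareyRecombinationRate(mk1, c(chr1 = 1.2e7))
    expect_true(all(is.na(mr1$rate_cM_Mb)))
    expect_true(all(mr1$n_markers <= 1))
})

test_that("sliding Marey rates transition monotonically between plateaus", {
    # piecewise map: flat (0 cM/Mb) for 20 Mb then 5 cM/Mb for 20 Mb
    bp <- seq(5e5, 4e7, 5e5)
    cM <- ifelse(bp <= 2e7, 0, (bp - 2e7) / 1e6 * 5)
    mr <- mareyRecombinationRate(data.frame(chrom = "chr1", bp = bp, cM = cM),
                                 c(chr1 = 4e7))
    r <- mr$rate_cM_Mb
    expect_equal(r[1], 0, tolerance = 1e-9)
    expect_equal(r[length(r)], 5, tolerance = 1e-9)
    expect_true(all(diff(r) >= -1e-9))
    expect_true(all(r >= -1e-9 & r <= 5 + 1e-9))
})
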