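outbredPedigree <- function() {
    data.frame(
        id = c("gm1", "gf1", "gm2", "gf2", "mom", "dad", "kid"),
        sire = c(NA, NA, NA, NA, "gf1", "gf2", "dad"),
        dam = c(NA, NA, NA, NA, "gm1", "gm2", "mom"))
}

denseMap <- function(n = 80, len = 2e7, cm = 60) {
    data.frame(marker = sprintf("m%03d", seq_len(n)), chrom = "chr1",
               bp = round(seq(len / n, len, length.out = n)),
               cM = seq(0, cm, length.out = n))
}

test_that("blocks partition the chromosome at the crossover union", {
    mk <- data.frame(marker = c("a", "b", "c"), bp = c(1e6, 5e6, 9e6))
    b <- defineBlocks(c(3e6, 7e6), 1e7, mk)
    expect_equal(start(b), c(1, 3e6 + 1, 7e6 + 1))
    expect_equal(end(b), c(3e6, 7e6, 1e7))
    expect_equal(sum(width(b)), 1e7)
    expect_equal(as.list(mcols(b)$markers),
                 list(c("a"), c("b"), c("c")))
    # no crossovers -> a single whole-chromosome block
    expect_equal(length(defineBlocks(numeric(0), 1e7)), 1L)
    # union over meioses dedupes shared positions
    b2 <- defineBlocks(list(3e6, c(3e6, 7e6)), 1e7, mk)
    expect_equal(start(b2), start(b))
    expect_error(defineBlocks(c(3e6), 1e7,
                              data.frame(marker = "x", bp = 2e7)),
                 "outside")
    expect_error(defineBlocks(c(2e7), 1e7), "within")
})

test_that("tracing picks the uniquely matching parental haplotype or reports unknown", {
    ped <- data.frame(id = c("dam", "sire", "kid"), sire = c(NA, NA, "sire"),
                      dam = c(NA, NA, "dam"))
    blocks <- defineBlocks(numeric(0), 1e6,
                           data.frame(marker = c("m1", "m2"),
                                      bp = c(2e5, 8e5)))
    haps <- list(
        dam = list(chr1 = matrix(c("A", "A", "B", "B"), 2,
                                 dimnames = list(c("m1", "m2"), NULL))),
        sire = list(chr1 = matrix(c("C", "C", "D", "D"), 2,
                                  dimnames = list(c("m1", "m2"), NULL))),
        kid = list(chr1 = matrix(c("A", "A", "C", "C"), 2,
                                 dimnames = list(c("m1", "m2"), NULL))))
    tr <- traceInheritance(ped, haps, blocks, "kid")
    expect_equal(tr$origin[tr$hap == "maternal"], "dam:1")
    expect_equal(tr$origin[tr$hap == "paternal"], "sire:1")
    # both dam haplotypes identical -> uninformative -> unknown
    haps$dam$chr1[] <- "A"
    haps$kid$chr1[, 1] <- "A"
    tr2 <- traceInheritance(ped, haps, blocks, "kid")
    expect_equal(tr2$origin[tr2$hap == "maternal"], "unknown")
})

test_that("with informative founders traced origins equal gene-drop truth on every block", {
    ped <- outbredPedigree()
    map <- denseMap()
    for (s in 1:5) {
        sim <- simulatePedigreeGenotypes(ped, map, seed = 400 + s)
        xo <- sim$truth$crossovers
        blocks <- defineBlocks(xo$bp, max(map$bp),
                               data.frame(marker = map$marker, bp = map$bp))
        tr <- traceInheritance(ped, sim$haplotypes, blocks, "kid")
        segs <- sim$truth$segments
        segs <- segs[segs$individual == "kid", ]
        for (i in seq_len(nrow(tr))) {
            if (!length(mcols(blocks)$markers[[tr$block[i]]])) next
            hp <- ifelse(tr$hap[i] == "maternal", 1, 2)
            truthLab <- segs$founder_hap[segs$hap == hp &
                                         segs$start <= tr$start[i] &
                                         segs$end >= tr$end[i]]
            expect_length(truthLab, 1L)
            expect_equal(tr$origin[i], sub("_", ":", truthLab))
        }
    }
})

test_that("ancestor identity is total for self and empty for unrelated founders", {
    ped <- outbredPedigree()
    map <- denseMap()
    sim <- simulatePedigreeGenotypes(ped, map, seed = 50)
    xo <- sim$truth$crossovers
    blocks <- defineBlocks(xo$bp, max(map$bp),
                           data.frame(marker = map$marker, bp = map$bp))
    bl <- list(chr1 = blocks)
    self <- ancestorIdentity(ped, sim$haplotypes, bl, "kid", "kid")
    expect_equal(self$matched_blocks, length(blocks))
    expect_equal(self$matched_bp, sum(width(blocks)))
    # two founders on opposite sides of the pedigree never match the kid's
    # other-side haplotype; founders unrelated to the kid's haplotypes match 0
    un <- ancestorIdentity(ped, sim$haplotypes, bl, "gm1", "gm2")
    expect_equal(un$matched_blocks, 0L)
    expect_error(ancestorIdentity(ped, sim$haplotypes, bl, "kid", "ghost"),
                 "not in pedigree")
})

test_that("removing markers from a block can break matches but never create them", {
    ped <- outbredPedigree()
    map <- denseMap()
    sim <- simulatePedigreeGenotypes(ped, map, seed = 51)
    blocks <- defineBlocks(sim$truth$crossovers$bp, max(map$bp),
                           data.frame(marker = map$marker, bp = map$bp))
    full <- ancestorIdentity(ped, sim$haplotypes, list(chr1 = blocks),
                             "kid", "gm1")
    # drop half the markers from every block: matched set can only grow
    thin <- blocks
    mcols(thin)$markers <- IRanges::CharacterList(lapply(
        mcols(blocks)$markers, function(m) m[seq_along(m) %% 2 == 1]))
    sub <- ancestorIdentity(ped, sim$haplotypes, list(chr1 = thin),
                            "kid", "gm1")
    expect_gte(sub$matched_blocks, full$matched_blocks)
})
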