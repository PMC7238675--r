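## Independent oracles used to cross-check the package implementations.
## These are deliberately written from the defining formulas/enumerations,
## not by calling package internals.

# Mean pairwise haplotype difference per bp by explicit enumeration: each
# diploid contributes two chromosomes (dosage 0 -> 0,0; 1 -> 0,1; 2 -> 1,1;
# NA -> none); every unordered chromosome pair is compared at each site.
bruteForcePi <- function(gt, windowLen) {
    total <- 0
    for (i in seq_len(nrow(gt))) {
        alleles <- unlist(lapply(gt[i, ], function(d) {
            if (is.na(d)) NULL else switch(as.character(d),
                                           "0" = c(0, 0), "1" = c(0, 1),
                                           "2" = c(1, 1))
        }))
        k <- length(alleles)
        if (k < 2) next
        diffs <- 0
        for (a in 1:(k - 1)) for (b in (a + 1):k)
            diffs <- diffs + (alleles[a] != alleles[b])
        total <- total + diffs / choose(k, 2)
    }
    unname(total) / windowLen
}

# Tajima's D with constants computed from their series definitions in loops
oracleTajimaD <- function(n, S, piHat) {
    a1 <- 0; a2 <- 0
    for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
    b1 <- (n + 1) / (3 * (n - 1))
    b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1
    c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    e1 <- c1 / a1
    e2 <- c2 / (a1^2 + a2)
    (piHat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Weir-Cockerham variance components for r populations of diploids, written
# for general r with the estimator's published moment expressions
oracleWcComponents <- function(pops) {
    r <- length(pops)
    n <- sapply(pops, length)
    p <- sapply(pops, function(g) sum(g) / (2 * length(g)))
    h <- sapply(pops, function(g) mean(g == 1))
    nbar <- mean(n)
    nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
    pbar <- sum(n * p) / sum(n)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / sum(n)
    a <- (nbar / nc) *
        (s2 - (1 / (nbar - 1)) *
             (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
             ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    c(a = a, b = b, c = cc)
}

# random small dosage matrix (optionally with missing calls)
randomDosageMatrix <- function(nSites, nSamples, pMissing = 0) {
    gt <- matrix(sample(0:2, nSites * nSamples, replace = TRUE),
                 nSites, nSamples)
    if (pMissing > 0)
        gt[stats::runif(length(gt)) < pMissing] <- NA_integer_
    colnames(gt) <- paste0("s", seq_len(nSamples))
    gt
}

# wrap a dosage matrix as a single-chromosome GenotypeMatrix
asGenotypeMatrix <- function(gt, chromLength = NULL, groups = NULL,
                             spacing = 10L) {
    pos <- seq_len(nrow(gt)) * spacing
    if (is.null(chromLength)) chromLength <- max(pos) + spacing
    GenotypeMatrix(gt, chrom = rep("chr1", nrow(gt)), pos = pos,
                   groups = groups, chromLengths = c(chr1 = chromLength))
}
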