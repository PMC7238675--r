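#' Configuration for the two-population genotype simulator
#'
#' Defaults mirror a founder panel of 23 diploids split into a Western
#' (EU/USA, 11) and an Eastern (Asia, 12) gene pool at moderate
#' differentiation.
#'
#' @param nPop1,nPop2 diploid sample sizes (>= 2); defaults 11 and 12.
#' @param nSites number of biallelic SNP sites.
#' @param chromLength chromosome length in bp.
#' @param divergenceF Balding-Nichols drift parameter `F` in `[0, 1)`;
#'   default 0.15.
#' @param sweepWindows `GRanges` (or `NULL`) of windows where the sweep
#'   population's allele frequencies are pushed toward fixation.
#' @param sweepPop which population carries the sweep signal (`"pop1"` or
#'   `"pop2"`).
#' @param popNames labels used in the sample-to-population mapping.
#' @param seed integer seed; all randomness flows from it.
#' @return a list of class `TwoPopSimConfig`.
#' @export
twoPopSimConfig <- function(nPop1 = 11, nPop2 = 12, nSites = 10000,
                            chromLength = 20e6, divergenceF = 0.15,
                            sweepWindows = NULL, sweepPop = "pop1",
                            popNames = c("pop1", "pop2"), seed = 1) {
    stopifnot(nPop1 >= 2, nPop2 >= 2, nSites >= 0,
              divergenceF >= 0, divergenceF < 1,
              sweepPop %in% c("pop1", "pop2"))
    if (!is.null(sweepWindows)) {
        stopifnot(is(sweepWindows, "GRanges"))
        if (any(end(sweepWindows) > chromLength))
            stop("sweep windows must lie within the chromosome")
    }
    structure(list(nPop1 = nPop1, nPop2 = nPop2, nSites = nSites,
                   chromLength = chromLength, divergenceF = divergenceF,
                   sweepWindows = sweepWindows, sweepPop = sweepPop,
                   popNames = popNames, seed = seed),
              class = "TwoPopSimConfig")
}

#' Simulate two diverged diploid populations (Balding-Nichols model)
#'
#' Ancestral allele frequencies are drawn `p ~ Uniform(0.05, 0.95)`;
#' population frequencies follow the Balding-Nichols law
#' `p_k ~ Beta(p (1-F)/F, (1-p)(1-F)/F)` (with `p_k = p` when `F = 0`), and
#' genotypes are `Binomial(2, p_k)` under Hardy-Weinberg equilibrium. Inside
#' sweep windows the sweep population's frequency is replaced, with
#' probability 0.9 per site, by a value near fixation — `Uniform(0.98, 1)`
#' when `round(p) == 1`, else `Uniform(0, 0.02)` — so sweep windows show
#' reduced diversity, an excess of rare alleles (negative Tajima's D) and
#' elevated F_ST.
#'
#' Stream order under the single seed: site positions, ancestral
#' frequencies, population-1 then population-2 frequencies, sweep
#' replacement draws, genotypes (population 1 then 2).
#'
#' @param config a [twoPopSimConfig()].
#' @return list with `genotypes` (a [GenotypeMatrix-class]) and `truth`
#'   (ancestral and per-population frequencies, sweep windows, sweep
#'   population).
#' @export
simulateTwoPopulations <- function(config) {
    stopifnot(inherits(config, "TwoPopSimConfig"))
    set.seed(config$seed)
    n1 <- config$nPop1
    n2 <- config$nPop2
    m <- config$nSites
    if (m == 0L) {
        warning("nSites = 0: returning an empty genotype matrix")
        empty <- matrix(integer(), 0L, n1 + n2)
        colnames(empty) <- c(sprintf("W%02d", seq_len(n1)),
                             sprintf("E%02d", seq_len(n2)))
        gm <- GenotypeMatrix(empty, character(), integer(),
                             chromLengths = c(chr1 = config$chromLength))
        return(list(genotypes = gm,
                    truth = list(p_anc = numeric(), p_pop = NULL,
                                 sweepWindows = config$sweepWindows,
                                 sweepPop = config$sweepPop)))
    }
    pos <- sort(sample.int(config$chromLength, m))
    p <- stats::runif(m, 0.05, 0.95)
    F <- config$divergenceF
    drawPop <- function() {
        if (F == 0) p
        else stats::rbeta(m, p * (1 - F) / F, (1 - p) * (1 - F) / F)
    }
    pk <- cbind(pop1 = drawPop(), pop2 = drawPop())
    if (!is.null(config$sweepWindows) && length(config$sweepWindows)) {
        siteGr <- GRanges("chr1", IRanges(pos, width = 1L))
        inSweep <- countOverlaps(siteGr, config$sweepWindows) > 0
        idx <- which(inSweep)
        if (length(idx)) {
            hit <- stats::runif(length(idx)) < 0.9
            sel <- idx[hit]
            side <- round(p[sel]) == 1
            repl <- ifelse(side, stats::runif(length(sel), 0.98, 1),
                           stats::runif(length(sel), 0, 0.02))
            pk[sel, config$sweepPop] <- repl
        }
    }
    g1 <- matrix(stats::rbinom(m * n1, 2L, rep(pk[, "pop1"], n1)), m, n1)
    g2 <- matrix(stats::rbinom(m * n2, 2L, rep(pk[, "pop2"], n2)), m, n2)
    calls <- cbind(g1, g2)
    colnames(calls) <- c(sprintf("W%02d", seq_len(n1)),
                         sprintf("E%02d", seq_len(n2)))
    groups <- stats::setNames(rep(config$popNames, c(n1, n2)), colnames(calls))
    gm <- GenotypeMatrix(calls, chrom = rep("chr1", m), pos = pos,
                         groups = groups,
                         chromLengths = c(chr1 = config$chromLength))
    list(genotypes = gm,
         truth = list(p_anc = p, p_pop = pk,
                      sweepWindows = config$sweepWindows,
                      sweepPop = config$sweepPop))
}

#' Simulate and write a two-population VCF with companion files
#'
#' Runs [simulateTwoPopulations()] and writes the VCF, a two-column
#' sample-to-population TSV and a truth JSON next to it.
#'
#' @param config a [twoPopSimConfig()].
#' @param vcfPath output VCF path; the groups file gets suffix
#'   `.groups.tsv`, the truth `.truth.json`.
#' @return list with `vcf`, `groups`, `truth` file paths and the `truth`
#'   object, invisibly.
#' @export
simulateTwoPopulationVCF <- function(config, vcfPath) {
    sim <- simulateTwoPopulations(config)
    writeVCF(sim$genotypes, vcfPath)
    groupsPath <- paste0(vcfPath, ".groups.tsv")
    writeGroupsFile(sampleGroups(sim$genotypes), groupsPath)
    truthPath <- paste0(vcfPath, ".truth.json")
    tr <- sim$truth
    jsonlite::write_json(
        list(p_anc = tr$p_anc,
             p_pop1 = unname(tr$p_pop[, "pop1"]),
             p_pop2 = unname(tr$p_pop[, "pop2"]),
             sweep_windows = if (is.null(tr$sweepWindows)) list() else
                 data.frame(start = start(tr$sweepWindows),
                            end = end(tr$sweepWindows)),
             sweep_pop = tr$sweepPop,
             seed = config$seed),
        truthPath, digits = NA)
    invisible(list(vcf = vcfPath, groups = groupsPath, truthFile = truthPath,
                   truth = tr))
}
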