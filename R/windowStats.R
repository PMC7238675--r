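#' Per-window summary statistics for a two-population scan
#'
#' Computes, for every window: the SNP count, per-group nucleotide diversity,
#' per-group segregating sites and Tajima's D, the ratio-of-sums
#' Weir-Cockerham F_ST, and the reduction-of-diversity coefficient
#' `ROD = 1 - pi_g1 / pi_g2`. Group 1 plays the "reduced-diversity
#' candidate" slot of the ROD formula (e.g. the Occidental gene pool against
#' an Asian reference pool).
#'
#' @param x a [GenotypeMatrix-class] with exactly two population labels.
#' @param windows `GRanges` of analysis windows (from [tileWindows()]).
#' @param groupOrder optional character vector of length 2 fixing which
#'   population is group 1 (ROD numerator) and group 2; defaults to the
#'   sorted label order.
#' @return a `data.frame` with one row per window: `chrom`, `start`, `end`
#'   (1-based, closed), `partial`, `n_snps`, `pi_g1`, `pi_g2`, `s_g1`,
#'   `s_g2`, `d_g1`, `d_g2`, `fst`, `rod`.
#' @export
computeWindowStats <- function(x, windows, groupOrder = NULL) {
    grp <- sampleGroups(x)
    lv <- sort(unique(grp[!is.na(grp)]))
    if (length(lv) != 2L)
        stop("computeWindowStats needs exactly two populations")
    if (!is.null(groupOrder)) {
        stopifnot(setequal(groupOrder, lv))
        lv <- groupOrder
    }
    g1 <- names(grp)[grp %in% lv[1L]]
    g2 <- names(grp)[grp %in% lv[2L]]
    pi1 <- windowPi(x, windows, samples = g1)
    pi2 <- windowPi(x, windows, samples = g2)
    d1 <- windowTajimaD(x, windows, samples = g1)
    d2 <- windowTajimaD(x, windows, samples = g2)
    fst <- windowFst(x, windows)
    out <- data.frame(
        chrom = as.character(seqnames(windows)),
        start = start(windows),
        end = end(windows),
        partial = if ("partial" %in% names(mcols(windows)))
            mcols(windows)$partial else FALSE,
        n_snps = countSnpsPerWindow(x, windows),
        pi_g1 = as.numeric(pi1),
        pi_g2 = as.numeric(pi2),
        s_g1 = attr(d1, "S"),
        s_g2 = attr(d2, "S"),
        d_g1 = as.numeric(d1),
        d_g2 = as.numeric(d2),
        fst = fst,
        rod = rod(as.numeric(pi1), as.numeric(pi2)),
        stringsAsFactors = FALSE)
    attr(out, "groups") <- lv
    out
}
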