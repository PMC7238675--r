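#' Call F_ST outlier windows at an empirical quantile
#'
#' The cutoff is the empirical quantile (linear interpolation between order
#' statistics, [stats::quantile()] type 7) of the defined window F_ST values;
#' windows with `fst >= cutoff` are flagged. Windows with undefined F_ST are
#' never flagged. With the default `quantile = 0.95` this selects the top 5%
#' of windows.
#'
#' @param fst numeric vector of window F_ST values (`NA` = undefined).
#' @param quantile quantile in (0, 1); default 0.95.
#' @return list with `cutoff` (numeric) and `calls`, a data.frame
#'   (`fst`, `is_outlier`, `cutoff_used`) with one row per input window.
#' @export
callFstOutliers <- function(fst, quantile = 0.95) {
    stopifnot(quantile > 0, quantile < 1)
    def <- fst[!is.na(fst)]
    if (!length(def)) stop("all window F_ST values are undefined")
    if (length(def) < 20L)
        warning("fewer than 20 windows with defined F_ST; cutoff is unstable")
    cutoff <- unname(stats::quantile(def, quantile, type = 7))
    if (length(unique(def)) == 1L)
        warning("all defined F_ST values are equal; every window ties at the cutoff")
    calls <- data.frame(fst = fst,
                        is_outlier = !is.na(fst) & fst >= cutoff,
                        cutoff_used = cutoff)
    list(cutoff = cutoff, calls = calls)
}

#' Permutation estimate of the outlier-scan false-discovery rate
#'
#' Population labels are shuffled across individuals genome-wide (group sizes
#' preserved, linkage within individuals intact), windowed F_ST is recomputed,
#' and the number of permuted windows reaching the observed cutoff is
#' recorded. The FDR estimate is the mean permuted count divided by the
#' observed outlier count (Benjamini-style empirical FDR). Deterministic for
#' a fixed seed.
#'
#' @param x a [GenotypeMatrix-class] with two population labels.
#' @param windows analysis windows (`GRanges`).
#' @param observedCutoff the cutoff from [callFstOutliers()].
#' @param nPermutations number of label permutations (default 1000).
#' @param seed integer seed.
#' @return list with `fdr` (NA when there are no observed outliers),
#'   `observed_count`, and `null_counts` (integer per permutation).
#' @export
permutationFdr <- function(x, windows, observedCutoff, nPermutations = 1000,
                           seed = 1) {
    stopifnot(nPermutations >= 1)
    grp <- sampleGroups(x)
    if (length(unique(grp[!is.na(grp)])) != 2L)
        stop("two populations are required")
    gt <- genotypes(x)
    h <- siteWindowHits(x, windows)
    qh <- S4Vectors::queryHits(h)
    sh <- S4Vectors::subjectHits(h)
    nW <- length(windows)
    fstFromLabels <- function(lab) {
        comp <- siteComponents(gt, lab)
        ok <- !is.na(comp$a)
        keep <- ok[qh]
        sumA <- sumByWindow(comp$a, qh[keep], sh[keep], nW)
        sumAll <- sumByWindow(comp$a + comp$b + comp$c, qh[keep], sh[keep], nW)
        nDef <- sumByWindow(rep(1, sum(keep)), qh[keep], sh[keep], nW)
        ifelse(nDef > 0 & sumAll != 0, sumA / sumAll, NA_real_)
    }
    obs <- fstFromLabels(grp)
    obsCount <- sum(obs >= observedCutoff, na.rm = TRUE)
    nullCounts <- integer(nPermutations)
    set.seed(seed)
    for (i in seq_len(nPermutations)) {
        perm <- sample(unname(grp))
        f <- fstFromLabels(perm)
        nullCounts[i] <- sum(f >= observedCutoff, na.rm = TRUE)
    }
    fdr <- if (obsCount == 0) {
        warning("no observed windows reach the cutoff; FDR undefined")
        NA_real_
    } else mean(nullCounts) / obsCount
    list(fdr = fdr, observed_count = obsCount, null_counts = nullCounts)
}

#' Classify F_ST outlier windows as sweep candidates
#'
#' Each outlier window is classified by the sign of the per-group Tajima's D:
#' a sweep candidate in group 1 when `d_g1 < 0`, in group 2 when `d_g2 < 0`
#' (both are possible). The ROD value of the window is attached as evidence.
#' Windows with missing group statistics are left unclassified and flagged.
#'
#' @param stats per-window data.frame from [computeWindowStats()].
#' @param outliers result of [callFstOutliers()] on `stats$fst`.
#' @return data.frame of outlier windows with columns `direction`
#'   (`"group1"`, `"group2"`, `"both"`, `"none"` or `"unclassified"`),
#'   plus the window stats and `rod`.
#' @export
classifySweeps <- function(stats, outliers) {
    sel <- which(outliers$calls$is_outlier)
    out <- stats[sel, , drop = FALSE]
    d1 <- out$d_g1
    d2 <- out$d_g2
    dir <- ifelse(is.na(d1) | is.na(d2), "unclassified",
           ifelse(d1 < 0 & d2 < 0, "both",
           ifelse(d1 < 0, "group1",
           ifelse(d2 < 0, "group2", "none"))))
    out$direction <- dir
    out$cutoff_used <- outliers$cutoff
    rownames(out) <- NULL
    out
}

#' Overlap trait-associated loci with scan windows
#'
#' Assigns each locus to the window(s) whose interval contains its position
#' (1-based) and reports the window statistics and outlier status. Loci on
#' chromosomes absent from the windows are reported as unplaced.
#'
#' @param loci data.frame with columns `marker`, `chrom`, `pos`, `trait`.
#' @param windows analysis windows (`GRanges`).
#' @param stats per-window data.frame from [computeWindowStats()] (same
#'   window order).
#' @param outliers result of [callFstOutliers()] on `stats$fst`.
#' @return data.frame with one row per (locus, containing window) pair;
#'   unplaced loci get a single row with `window = NA` and
#'   `placed = FALSE`.
#' @export
overlapTraitLoci <- function(loci, windows, stats, outliers) {
    stopifnot(all(c("marker", "chrom", "pos", "trait") %in% names(loci)))
    lociGr <- GRanges(loci$chrom, IRanges(loci$pos, width = 1L))
    GenomeInfoDb::seqlevels(lociGr) <-
        union(GenomeInfoDb::seqlevels(lociGr), seqlevels(windows))
    h <- findOverlaps(lociGr, windows)
    qh <- S4Vectors::queryHits(h)
    sh <- S4Vectors::subjectHits(h)
    rows <- lapply(seq_len(nrow(loci)), function(i) {
        wins <- sh[qh == i]
        if (!length(wins))
            return(cbind(loci[i, , drop = FALSE],
                         data.frame(window = NA_integer_, placed = FALSE,
                                    fst = NA_real_, rod = NA_real_,
                                    d_g1 = NA_real_, d_g2 = NA_real_,
                                    is_outlier = NA)))
        cbind(loci[rep(i, length(wins)), , drop = FALSE],
              data.frame(window = wins, placed = TRUE,
                         fst = stats$fst[wins], rod = stats$rod[wins],
                         d_g1 = stats$d_g1[wins], d_g2 = stats$d_g2[wins],
                         is_outlier = outliers$calls$is_outlier[wins]))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
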