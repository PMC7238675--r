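## Per-site allele summaries and windowed diversity statistics.
## Sites are biallelic; "k" is the number of non-missing chromosomes at a
## site (2 x non-missing diploids), "c" the alternate-allele count.

# per-site summaries over a column subset of the dosage matrix
siteAlleleCounts <- function(gt) {
    nInd <- rowSums(!is.na(gt))
    list(nInd = nInd,
         k = 2L * nInd,
         c = rowSums(gt, na.rm = TRUE),
         het = rowSums(gt == 1L, na.rm = TRUE))
}

# unbiased per-site mean pairwise difference: 2 c (k - c) / (k (k - 1));
# sites with k < 2 contribute 0 (they carry no haplotype pair)
sitePairwiseDiff <- function(k, c) {
    out <- numeric(length(k))
    ok <- k >= 2
    out[ok] <- 2 * c[ok] * (k[ok] - c[ok]) / (k[ok] * (k[ok] - 1))
    out
}

# sum per-site values into windows (windows with no site get 0)
sumByWindow <- function(values, siteIdx, windowIdx, nWindows) {
    out <- numeric(nWindows)
    if (length(siteIdx)) {
        s <- rowsum(values[siteIdx], windowIdx)
        out[as.integer(rownames(s))] <- s[, 1L]
    }
    out
}

#' Windowed nucleotide diversity
#'
#' Per-bp nucleotide diversity per window: the sum over sites of the unbiased
#' mean pairwise haplotype difference `2c(k-c) / (k(k-1))` divided by the
#' window length in bp. Monomorphic and unobserved positions contribute 0 to
#' the numerator but remain in the denominator (windowed-pi convention).
#' Sites with fewer than two non-missing chromosomes are skipped; their count
#' is returned as an attribute `skipped_sites`.
#'
#' @param x a [GenotypeMatrix-class].
#' @param windows `GRanges` of analysis windows.
#' @param samples optional character vector restricting the computation to a
#'   sample subset (e.g. one population).
#' @return numeric vector of per-bp diversity, one entry per window.
#' @export
windowPi <- function(x, windows, samples = NULL) {
    gt <- genotypes(x)
    if (!is.null(samples)) gt <- gt[, samples, drop = FALSE]
    sc <- siteAlleleCounts(gt)
    pd <- sitePairwiseDiff(sc$k, sc$c)
    h <- siteWindowHits(x, windows)
    res <- sumByWindow(pd, S4Vectors::queryHits(h), S4Vectors::subjectHits(h),
                       length(windows)) / width(windows)
    attr(res, "skipped_sites") <- sum(sc$k < 2)
    res
}

#' Tajima's D from summary quantities
#'
#' Computes Tajima's D from the sample size in chromosomes, the number of
#' segregating sites and the mean pairwise difference summed over sites,
#' using the standard normalizing constants
#' `a1 = sum(1/i)`, `a2 = sum(1/i^2)` for `i = 1..n-1`,
#' `b1 = (n+1)/(3(n-1))`, `b2 = 2(n^2+n+3)/(9n(n-1))`,
#' `c1 = b1 - 1/a1`, `c2 = b2 - (n+2)/(a1 n) + a2/a1^2`,
#' `e1 = c1/a1`, `e2 = c2/(a1^2 + a2)`, and
#' `D = (piHat - S/a1) / sqrt(e1 S + e2 S (S-1))`.
#'
#' @param n number of sampled chromosomes (>= 4).
#' @param S number of segregating sites (vectorized).
#' @param piHat mean pairwise differences summed over sites (same length
#'   as `S`).
#' @return numeric vector of D values; `NA` where `S == 0`.
#' @export
tajimaD <- function(n, S, piHat) {
    if (any(n < 4)) stop("Tajima's D requires n >= 4 chromosomes")
    stopifnot(length(S) == length(piHat))
    kons <- tajimaConstants(n)
    d <- rep(NA_real_, length(S))
    pos <- which(S > 0)
    if (length(pos)) {
        if (length(n) == 1L) kk <- kons[rep(1L, length(pos)), , drop = FALSE]
        else kk <- kons[pos, , drop = FALSE]
        num <- piHat[pos] - S[pos] / kk[, "a1"]
        den <- sqrt(kk[, "e1"] * S[pos] + kk[, "e2"] * S[pos] * (S[pos] - 1))
        d[pos] <- num / den
    }
    d
}

# normalizing constants, one row per n
tajimaConstants <- function(n) {
    t(vapply(n, function(nn) {
        i <- seq_len(nn - 1L)
        a1 <- sum(1 / i)
        a2 <- sum(1 / i^2)
        b1 <- (nn + 1) / (3 * (nn - 1))
        b2 <- 2 * (nn^2 + nn + 3) / (9 * nn * (nn - 1))
        c1 <- b1 - 1 / a1
        c2 <- b2 - (nn + 2) / (a1 * nn) + a2 / a1^2
        c(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
    }, numeric(4)))
}

#' Windowed Tajima's D
#'
#' Computes D per window for a sample subset. `n` is `2 x` the number of
#' samples when the window has no missing data; with missing data the modal
#' per-site chromosome count in the window is used and the window is flagged
#' in the `mixed_n` attribute.
#'
#' @inheritParams windowPi
#' @return numeric vector of D, one per window (`NA` where no segregating
#'   sites or `n < 4`), with attribute `mixed_n` (logical per window).
#' @export
windowTajimaD <- function(x, windows, samples = NULL) {
    gt <- genotypes(x)
    if (!is.null(samples)) gt <- gt[, samples, drop = FALSE]
    sc <- siteAlleleCounts(gt)
    seg <- sc$c > 0 & sc$c < sc$k
    pd <- sitePairwiseDiff(sc$k, sc$c)
    h <- siteWindowHits(x, windows)
    qh <- S4Vectors::queryHits(h)
    sh <- S4Vectors::subjectHits(h)
    nW <- length(windows)
    Svec <- sumByWindow(as.numeric(seg), qh, sh, nW)
    piHat <- sumByWindow(pd, qh, sh, nW)
    d <- rep(NA_real_, nW)
    mixed <- logical(nW)
    kByW <- split(sc$k[qh], sh)
    for (wname in names(kByW)) {
        w <- as.integer(wname)
        ks <- kByW[[wname]]
        ks <- ks[ks >= 2]
        if (!length(ks)) next
        tab <- table(ks)
        nUse <- as.integer(names(tab)[which.max(tab)])
        mixed[w] <- length(tab) > 1L
        if (nUse >= 4 && Svec[w] > 0)
            d[w] <- tajimaD(nUse, Svec[w], piHat[w])
    }
    attr(d, "S") <- as.integer(Svec)
    attr(d, "mixed_n") <- mixed
    d
}

#' Reduction-of-diversity coefficient
#'
#' `rod(pi1, pi2) = 1 - pi1/pi2`, the fractional diversity loss of group 1
#' relative to group 2. Undefined (NA) where `pi2 == 0`.
#'
#' @param pi1,pi2 per-window nucleotide diversity of the two groups
#'   (vectorized).
#' @return numeric vector; `NA` where `pi2` is zero or missing.
#' @export
rod <- function(pi1, pi2) {
    out <- 1 - pi1 / pi2
    out[!is.finite(out)] <- NA_real_
    out
}
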