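## Weir-Cockerham (1984) variance components for two populations and the
## windowed ratio-of-sums ("weighted") F_ST estimator.

#' Per-site Weir-Cockerham variance components (two populations)
#'
#' Computes the among-population (a), among-individual-within-population (b)
#' and within-individual (c) variance components for each site, from
#' population sample sizes (non-missing diploids), alternate-allele
#' frequencies and heterozygote frequencies. The per-site estimate is
#' `a / (a + b + c)`; the windowed estimator sums components before dividing
#' (see [windowFst()]).
#'
#' @param n1,n2 non-missing diploid counts per site in each population.
#' @param p1,p2 alternate-allele frequencies per site.
#' @param h1,h2 heterozygote frequencies per site (heterozygous individuals /
#'   non-missing individuals).
#' @return data.frame with columns `a`, `b`, `c`; rows are `NA` where a
#'   population has no non-missing individual or the pooled sample is a
#'   single diploid.
#' @export
wcSiteComponents <- function(n1, n2, p1, p2, h1, h2) {
    r <- 2
    nbar <- (n1 + n2) / 2
    valid <- n1 >= 1 & n2 >= 1 & nbar > 1
    nc <- r * nbar - (n1^2 + n2^2) / (r * nbar)
    # r - 1 = 1 in the denominators below
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - s2 * (r - 1) / r -
             hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    a[!valid] <- b[!valid] <- cc[!valid] <- NA_real_
    data.frame(a = a, b = b, c = cc)
}

# per-site components straight from a dosage matrix + a 2-level group factor
siteComponents <- function(gt, groupLabels) {
    lv <- levels(factor(groupLabels[!is.na(groupLabels)]))
    if (length(lv) != 2L)
        stop("exactly two populations are required, got: ",
             paste(lv, collapse = ", "))
    i1 <- which(groupLabels == lv[1L])
    i2 <- which(groupLabels == lv[2L])
    s1 <- siteAlleleCounts(gt[, i1, drop = FALSE])
    s2 <- siteAlleleCounts(gt[, i2, drop = FALSE])
    p1 <- ifelse(s1$k > 0, s1$c / s1$k, NA_real_)
    p2 <- ifelse(s2$k > 0, s2$c / s2$k, NA_real_)
    h1 <- ifelse(s1$nInd > 0, s1$het / s1$nInd, NA_real_)
    h2 <- ifelse(s2$nInd > 0, s2$het / s2$nInd, NA_real_)
    wcSiteComponents(s1$nInd, s2$nInd, p1, p2, h1, h2)
}

#' Windowed Weir-Cockerham F_ST (ratio of sums)
#'
#' Sums the per-site variance components over the sites of each window and
#' returns `sum(a) / sum(a + b + c)` — the "weighted" windowed estimator.
#' Negative estimates are reported as computed (no clipping), preserving the
#' empirical distribution used for quantile cutoffs. Sites with undefined
#' components (a population entirely missing) are excluded from both sums.
#'
#' @param x a [GenotypeMatrix-class] whose samples carry exactly two
#'   population labels.
#' @param windows `GRanges` of analysis windows; when `NULL` a single
#'   genome-wide estimate is returned.
#' @param groupLabels optional label vector overriding `sampleGroups(x)`
#'   (used by the permutation test).
#' @return numeric vector of window F_ST (`NA` where no site has defined
#'   components), or a single number when `windows` is `NULL`.
#' @export
windowFst <- function(x, windows = NULL, groupLabels = NULL) {
    if (is.null(groupLabels)) groupLabels <- sampleGroups(x)
    comp <- siteComponents(genotypes(x), groupLabels)
    ok <- !is.na(comp$a)
    if (is.null(windows)) {
        den <- sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
        if (!length(which(ok)) || den == 0) return(NA_real_)
        return(sum(comp$a[ok]) / den)
    }
    h <- siteWindowHits(x, windows)
    qh <- S4Vectors::queryHits(h)
    sh <- S4Vectors::subjectHits(h)
    keep <- ok[qh]
    nW <- length(windows)
    sumA <- sumByWindow(comp$a, qh[keep], sh[keep], nW)
    sumAll <- sumByWindow(comp$a + comp$b + comp$c, qh[keep], sh[keep], nW)
    nDef <- sumByWindow(rep(1, sum(keep)), qh[keep], sh[keep], nW)
    out <- ifelse(nDef > 0 & sumAll != 0, sumA / sumAll, NA_real_)
    out
}
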