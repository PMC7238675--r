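#' Tile or slide analysis windows along chromosomes
#'
#' With `step == size` (the default) the chromosome is tiled end to end with
#' non-overlapping windows; the final window may be shorter than `size` and is
#' flagged `partial`. With `step < size`, sliding windows are emitted at every
#' step whose full extent fits on the chromosome (e.g. a 12-Mb chromosome with
#' 10-Mb windows at a 1-Mb step yields windows starting at 0, 1 and 2 Mb); a
#' chromosome shorter than `size` yields one truncated window.
#'
#' @param chromLengths named numeric vector of chromosome lengths (bp).
#' @param size window size in bp.
#' @param step step in bp; defaults to `size` (tiling).
#' @return a `GRanges` (1-based, closed intervals) with metadata column
#'   `partial` (logical: window shorter than `size`).
#' @examples
#' tileWindows(c(chr1 = 250000), size = 1e5)
#' @export
tileWindows <- function(chromLengths, size, step = size) {
    if (size <= 0) stop("window size must be positive")
    if (step <= 0 || step > size) stop("step must satisfy 0 < step <= size")
    stopifnot(!is.null(names(chromLengths)))
    pieces <- lapply(names(chromLengths), function(chr) {
        L <- as.numeric(chromLengths[[chr]])
        if (step == size) {
            starts0 <- seq(0, max(0, L - 1), by = size)
        } else if (L >= size) {
            starts0 <- seq(0, L - size, by = step)
        } else {
            starts0 <- 0
        }
        ends0 <- pmin(starts0 + size, L)
        data.frame(chrom = chr, start = starts0 + 1, end = ends0,
                   partial = (ends0 - starts0) < size)
    })
    tab <- do.call(rbind, pieces)
    GRanges(tab$chrom, IRanges(tab$start, tab$end), partial = tab$partial,
            seqlengths = chromLengths)
}

#' Filter variants on missingness and minor-allele frequency
#'
#' Retains sites whose missing-call fraction is at most `maxMissingFraction`
#' and whose minor-allele frequency, computed over non-missing calls, is
#' strictly greater than `mafMin`. The defaults reproduce a "no missing data,
#' MAF > 10%" filter. Site order is preserved and the operation is idempotent.
#'
#' @param x a [GenotypeMatrix-class].
#' @param mafMin minor-allele frequency threshold in `[0, 0.5]`; sites with
#'   MAF strictly above it are kept.
#' @param maxMissingFraction maximum tolerated fraction of missing calls
#'   (non-strict).
#' @return the filtered `GenotypeMatrix`; the number of removed sites is in
#'   `metadata(x)$filtered_sites`.
#' @export
filterVariants <- function(x, mafMin = 0.10, maxMissingFraction = 0.0) {
    stopifnot(mafMin >= 0, mafMin <= 0.5)
    gt <- genotypes(x)
    nMiss <- rowSums(is.na(gt))
    k <- 2L * (ncol(gt) - nMiss)
    cnt <- rowSums(gt, na.rm = TRUE)
    af <- ifelse(k > 0, cnt / k, NA_real_)
    maf <- pmin(af, 1 - af)
    keep <- (nMiss / ncol(gt)) <= maxMissingFraction & !is.na(maf) & maf > mafMin
    out <- x[keep, ]
    metadata(out)$filtered_sites <- sum(!keep)
    out
}

#' Count SNPs per window
#'
#' Counts retained sites in each window; with `heterozygousOnly = TRUE` only
#' sites where the focal sample carries a heterozygous call (dosage 1) are
#' counted — the single-genotype heterozygosity scan.
#'
#' @param x a [GenotypeMatrix-class].
#' @param windows `GRanges` from [tileWindows()].
#' @param heterozygousOnly count only heterozygous calls of `focalSample`.
#' @param focalSample sample name; required when `heterozygousOnly` and the
#'   matrix holds more than one sample.
#' @return integer vector of counts, one per window.
#' @export
countSnpsPerWindow <- function(x, windows, heterozygousOnly = FALSE,
                               focalSample = NULL) {
    sites <- rowRanges(x)
    if (heterozygousOnly) {
        if (is.null(focalSample)) {
            if (ncol(x) != 1L)
                stop("heterozygousOnly requires 'focalSample' when >1 sample present")
            focalSample <- colnames(x)[1L]
        }
        stopifnot(focalSample %in% colnames(x))
        het <- genotypes(x)[, focalSample] == 1L
        het[is.na(het)] <- FALSE
        sites <- sites[het]
    }
    countOverlaps(windows, sites)
}

# site index -> window index (NA when a site falls in no window / several
# windows are allowed only for sliding tilings, where a site maps to each)
siteWindowHits <- function(x, windows) {
    findOverlaps(rowRanges(x), windows)
}
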