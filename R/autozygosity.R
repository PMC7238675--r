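## Single-genotype low-heterozygosity (autozygosity) scan: flag 1-Mb windows
## whose heterozygous-SNP count falls below a genome-wide percentile and
## merge adjacent flagged windows into candidate autozygous regions.

#' Low-heterozygosity threshold from the genome-wide count distribution
#'
#' The threshold is an empirical percentile (linear interpolation,
#' [stats::quantile()] type 7) of the per-window SNP counts, so fractional
#' thresholds are possible. Partial terminal windows should be excluded from
#' estimation (pass `partial`); they are rescaled before flagging in
#' [callLowHetRegions()].
#'
#' @param counts integer vector of per-window heterozygous-SNP counts.
#' @param percentile percentile in (0, 100); default 10.
#' @param partial optional logical vector marking partial windows to exclude
#'   from the estimation.
#' @return the threshold (numeric scalar).
#' @export
lowHetThreshold <- function(counts, percentile = 10, partial = NULL) {
    if (!is.null(partial)) counts <- counts[!partial]
    if (!length(counts)) stop("no windows to estimate the threshold from")
    if (length(counts) < 10L)
        warning("fewer than 10 windows; percentile threshold is unstable")
    unname(stats::quantile(counts, percentile / 100, type = 7))
}

#' Call and merge low-heterozygosity regions
#'
#' Windows whose count is strictly below the threshold are flagged; runs of
#' adjacent flagged windows (sharing a boundary on the same chromosome) are
#' merged into regions. Partial terminal windows are flagged on their
#' rescaled count (`count * size / actual_length`) so short windows are not
#' spuriously called.
#'
#' @param windows tiled windows (`GRanges`, step = size) with optional
#'   `partial` metadata column.
#' @param counts per-window heterozygous-SNP counts (same order).
#' @param threshold numeric threshold, typically from [lowHetThreshold()].
#' @return a `GRanges` of merged regions with metadata columns `n_windows`,
#'   `total_snps` (raw counts summed) and `threshold`; empty when no window
#'   is flagged.
#' @export
callLowHetRegions <- function(windows, counts, threshold) {
    stopifnot(length(windows) == length(counts))
    size <- max(width(windows))
    eff <- counts * size / width(windows)
    flag <- eff < threshold
    if (!any(flag)) {
        out <- GRanges()
        mcols(out) <- DataFrame(n_windows = integer(), total_snps = numeric(),
                                threshold = numeric())
        return(out)
    }
    flagged <- windows[flag]
    regions <- GenomicRanges::reduce(flagged, min.gapwidth = 1L)
    h <- findOverlaps(flagged, regions)
    nW <- tabulate(S4Vectors::subjectHits(h), length(regions))
    tot <- sumByWindow(counts[flag], S4Vectors::queryHits(h),
                       S4Vectors::subjectHits(h), length(regions))
    mcols(regions)$n_windows <- nW
    mcols(regions)$total_snps <- tot
    mcols(regions)$threshold <- threshold
    regions
}
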