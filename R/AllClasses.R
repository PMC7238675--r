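#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end width mcols mcols<- findOverlaps countOverlaps
#' @importFrom GenomeInfoDb seqlengths seqlevels
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges colData assays
NULL

#' Biallelic diploid genotype matrix with population labels
#'
#' `GenotypeMatrix` holds biallelic SNP calls as alternate-allele dosages
#' (0, 1, 2 or `NA` for missing) at ordered genomic positions, together with
#' an optional sample-to-population mapping. It extends
#' [SummarizedExperiment::RangedSummarizedExperiment]: rows are SNP sites
#' (width-1 `GRanges`, 1-based), columns are samples, and the single assay
#' `"GT"` stores the dosage matrix. The population label of each sample lives
#' in `colData(x)$group`.
#'
#' @slot ... inherited from `RangedSummarizedExperiment`.
#'
#' @seealso [GenotypeMatrix()] for construction, [readVCF()] to import from
#'   VCF, [filterVariants()] for the MAF/missingness filter.
#' @export
setClass("GenotypeMatrix", contains = "RangedSummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
    msg <- character()
    if (!"GT" %in% names(assays(object)))
        msg <- c(msg, "assay 'GT' (dosage matrix) is required")
    else {
        gt <- assay(object, "GT")
        ok <- is.na(gt) | gt %in% c(0L, 1L, 2L)
        if (!all(ok))
            msg <- c(msg, "dosages must be 0, 1, 2 or NA")
    }
    if (!"group" %in% names(colData(object)))
        msg <- c(msg, "colData must contain a 'group' column (may be NA)")
    rr <- rowRanges(object)
    if (length(rr) > 1L) {
        chr <- as.character(seqnames(rr))
        pos <- start(rr)
        same <- chr[-1L] == chr[-length(chr)]
        if (any(same & diff(pos) <= 0))
            msg <- c(msg, "positions must be strictly increasing within each chromosome")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param calls integer matrix of alternate-allele dosages (sites x samples);
#'   values 0, 1, 2 or `NA`. Column names are sample identifiers.
#' @param chrom character vector of chromosome names, one per site.
#' @param pos integer vector of 1-based positions, one per site; must be
#'   strictly increasing within each chromosome (rows are reordered if not).
#' @param groups named character vector mapping sample name to population
#'   label, or `NULL` for unlabelled samples (e.g. the single-genotype
#'   heterozygosity scan).
#' @param chromLengths named numeric vector of chromosome lengths in bp. Needed
#'   for window tiling; inferred as `max(pos)` per chromosome when omitted.
#'
#' @return A [GenotypeMatrix-class] object.
#' @examples
#' gm <- GenotypeMatrix(matrix(c(0L, 1L, 2L, 1L), 2,
#'                             dimnames = list(NULL, c("s1", "s2"))),
#'                      chrom = c("chr1", "chr1"), pos = c(100L, 200L),
#'                      chromLengths = c(chr1 = 1000))
#' nSites(gm)
#' @export
GenotypeMatrix <- function(calls, chrom, pos, groups = NULL, chromLengths = NULL) {
    calls <- as.matrix(calls)
    storage.mode(calls) <- "integer"
    if (is.null(colnames(calls)))
        colnames(calls) <- paste0("sample", seq_len(ncol(calls)))
    stopifnot(length(chrom) == nrow(calls), length(pos) == nrow(calls))
    chrom <- as.character(chrom)
    pos <- as.integer(pos)
    o <- order(chrom, pos)
    if (is.unsorted(o)) {
        calls <- calls[o, , drop = FALSE]
        chrom <- chrom[o]
        pos <- pos[o]
    }
    if (is.null(chromLengths)) {
        chromLengths <- tapply(pos, chrom, max)
        chromLengths <- stats::setNames(as.numeric(chromLengths), names(chromLengths))
    }
    rr <- GRanges(chrom, IRanges(pos, width = 1L),
                  seqlengths = chromLengths[unique(chrom)])
    grp <- rep(NA_character_, ncol(calls))
    if (!is.null(groups)) {
        miss <- setdiff(colnames(calls), names(groups))
        if (length(miss))
            stop("no group label for sample(s): ", paste(miss, collapse = ", "))
        grp <- unname(groups[colnames(calls)])
    }
    se <- SummarizedExperiment(
        assays = list(GT = calls),
        rowRanges = rr,
        colData = DataFrame(group = grp, row.names = colnames(calls)))
    new("GenotypeMatrix", se)
}

#' @describeIn GenotypeMatrix number of SNP sites (rows).
#' @param x a `GenotypeMatrix`.
#' @export
nSites <- function(x) nrow(x)

#' Accessors for GenotypeMatrix
#'
#' `genotypes()` returns the dosage matrix (sites x samples), `sampleGroups()`
#' the named vector of population labels, and `chromLengths()` the chromosome
#' lengths recorded for window tiling.
#'
#' @param x a [GenotypeMatrix-class].
#' @return see individual descriptions.
#' @export
genotypes <- function(x) assay(x, "GT")

#' @rdname genotypes
#' @export
sampleGroups <- function(x) stats::setNames(colData(x)$group, colnames(x))

#' @rdname genotypes
#' @export
chromLengths <- function(x) seqlengths(rowRanges(x))

setMethod("show", "GenotypeMatrix", function(object) {
    grp <- colData(object)$group
    cat("GenotypeMatrix with", nrow(object), "sites x", ncol(object), "samples\n")
    cat("  chromosomes:", paste(seqlevels(rowRanges(object)), collapse = ", "), "\n")
    if (any(!is.na(grp))) {
        tab <- table(grp, useNA = "no")
        cat("  groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    } else cat("  groups: none\n")
    invisible(object)
})
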