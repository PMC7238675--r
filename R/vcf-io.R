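#' Read a VCF into a GenotypeMatrix
#'
#' Ingests diploid GT calls from a VCF (v4.x) file. Only biallelic SNP records
#' (single-base REF and single-base ALT) are kept; multiallelic records and
#' indels are dropped and counted. Dosages are derived from the GT field
#' regardless of the phasing separator (`/` or `|`); any call containing `.`
#' is treated as missing.
#'
#' @param path path to a VCF file (plain or gzipped).
#' @param groupsPath optional path to a two-column, tab-separated
#'   sample-to-population file (no header: sample, population). Every listed
#'   sample must be present in the VCF.
#' @param chromLengths optional named vector of chromosome lengths; when
#'   omitted, lengths are taken from `##contig` header lines if present.
#'
#' @return A [GenotypeMatrix-class]. The number of dropped non-biallelic-SNP
#'   records is stored in `metadata(x)$dropped_records`.
#' @export
readVCF <- function(path, groupsPath = NULL, chromLengths = NULL) {
    stopifnot(file.exists(path))
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(fix) || nrow(v@gt) == 0L && nrow(fix) == 0L) {
        warning("empty VCF: ", path)
        samples <- colnames(v@gt)[-1L]
        if (is.null(samples)) samples <- character()
        empty <- matrix(integer(), 0L, length(samples),
                        dimnames = list(NULL, samples))
        return(GenotypeMatrix(empty, character(), integer(),
                              chromLengths = chromLengths))
    }
    fix <- matrix(fix, ncol = ncol(vcfR::getFIX(v)),
                  dimnames = dimnames(vcfR::getFIX(v)))
    ref <- fix[, "REF"]
    alt <- fix[, "ALT"]
    keep <- !is.na(ref) & !is.na(alt) &
        nchar(ref) == 1L & nchar(alt) == 1L &
        ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
    dropped <- sum(!keep)
    gt <- v@gt[keep, -1L, drop = FALSE]
    samples <- colnames(gt)
    dos <- gtToDosage(gt)
    if (is.null(chromLengths)) {
        meta <- v@meta
        ctg <- grep("^##contig=", meta, value = TRUE)
        if (length(ctg)) {
            ids <- sub(".*ID=([^,>]+).*", "\\1", ctg)
            lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", ctg)))
            if (!anyNA(lens))
                chromLengths <- stats::setNames(lens, ids)
        }
    }
    groups <- NULL
    if (!is.null(groupsPath)) {
        groups <- readGroupsFile(groupsPath)
        absent <- setdiff(names(groups), samples)
        if (length(absent))
            stop("sample(s) in groups file absent from VCF: ",
                 paste(absent, collapse = ", "))
        full <- stats::setNames(rep(NA_character_, length(samples)), samples)
        full[names(groups)] <- groups
        groups <- full
    }
    gm <- GenotypeMatrix(dos,
                         chrom = fix[keep, "CHROM"],
                         pos = as.integer(fix[keep, "POS"]),
                         groups = groups, chromLengths = chromLengths)
    metadata(gm)$dropped_records <- dropped
    gm
}

# GT character matrix -> integer dosage matrix (NA when any allele missing)
gtToDosage <- function(gt) {
    # strip any non-GT FORMAT fields, then count "1" alleles
    core <- sub(":.*$", "", gt)
    dos <- matrix(NA_integer_, nrow(core), ncol(core),
                  dimnames = list(NULL, colnames(core)))
    a1 <- substr(core, 1L, 1L)
    a2 <- substr(core, 3L, 3L)
    ok <- a1 %in% c("0", "1") & a2 %in% c("0", "1")
    dos[ok] <- (a1 == "1")[ok] + (a2 == "1")[ok]
    dos
}

#' Read a two-column sample-to-population file
#'
#' @param path tab-separated file, no header: sample identifier, population.
#' @return named character vector (names are samples).
#' @export
readGroupsFile <- function(path) {
    stopifnot(file.exists(path))
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE,
                             col.names = c("sample", "group"))
    stats::setNames(tab$group, tab$sample)
}

#' Write a GenotypeMatrix to a plain-text VCF v4.2
#'
#' Emits GT-only biallelic SNP records (REF "A", ALT "T" unless allele columns
#' are present in `mcols(rowRanges(x))` as `ref`/`alt`). Unphased separators
#' are used; missing calls become `./.`.
#'
#' @param x a [GenotypeMatrix-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeVCF <- function(x, path) {
    gt <- genotypes(x)
    rr <- rowRanges(x)
    lens <- seqlengths(rr)
    hdr <- c("##fileformat=VCFv4.2",
             "##source=divscan",
             sprintf("##contig=<ID=%s,length=%d>", names(lens), as.integer(lens)),
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", colnames(gt)), collapse = "\t"))
    ref <- if ("ref" %in% names(mcols(rr))) mcols(rr)$ref else rep("A", length(rr))
    alt <- if ("alt" %in% names(mcols(rr))) mcols(rr)$alt else rep("T", length(rr))
    code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    gtChar <- matrix("./.", nrow(gt), ncol(gt))
    idx <- !is.na(gt)
    gtChar[idx] <- code[as.character(gt[idx])]
    body <- character(length(rr))
    if (length(rr)) {
        left <- paste(as.character(seqnames(rr)), start(rr), ".", ref, alt,
                      ".", "PASS", ".", "GT", sep = "\t")
        body <- paste(left, apply(gtChar, 1L, paste, collapse = "\t"), sep = "\t")
        if (ncol(gt) == 0L) body <- left
    }
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' Write a sample-to-population table
#'
#' @param groups named character vector (names are samples).
#' @param path output path (tab-separated, no header).
#' @return `path`, invisibly.
#' @export
writeGroupsFile <- function(groups, path) {
    utils::write.table(data.frame(names(groups), unname(groups)),
                       path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
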