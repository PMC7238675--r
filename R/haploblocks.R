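## Haplotype blocks: map intervals free of ancestral recombination, traced
## through a pedigree from phased marker data.

#' Define haplotype blocks from ancestral recombination sites
#'
#' Block boundaries are the sorted union of crossover positions across the
#' supplied ancestral meioses; the blocks are the resulting intervals, which
#' partition the chromosome. Markers are assigned to blocks by position.
#'
#' @param recombPositions numeric vector (or list of vectors, one per
#'   meiosis) of crossover bp positions on one chromosome. A crossover at
#'   position `x` separates `[1, x]` from `[x + 1, len]`.
#' @param chromLength chromosome length in bp.
#' @param markers data.frame with columns `marker` and `bp` (positions on
#'   this chromosome); optional.
#' @param chrom chromosome name for the output ranges.
#' @return `GRanges` of blocks with metadata column `markers`
#'   (CharacterList of marker ids per block).
#' @export
defineBlocks <- function(recombPositions, chromLength, markers = NULL,
                         chrom = "chr1") {
    pos <- sort(unique(unlist(recombPositions)))
    if (length(pos) && (any(pos < 1) || any(pos >= chromLength)))
        stop("recombination positions must lie within the chromosome")
    starts <- c(1, pos + 1)
    ends <- c(pos, chromLength)
    blocks <- GRanges(chrom, IRanges(starts, ends))
    ids <- replicate(length(blocks), character(0), simplify = FALSE)
    if (!is.null(markers)) {
        stopifnot(all(c("marker", "bp") %in% names(markers)))
        if (any(markers$bp < 1 | markers$bp > chromLength))
            stop("marker position outside the chromosome")
        idx <- findInterval(markers$bp, starts)
        for (b in seq_along(blocks))
            ids[[b]] <- markers$marker[idx == b]
    }
    mcols(blocks)$markers <- IRanges::CharacterList(ids)
    blocks
}

# alleles of one individual haplotype at the given markers (NA-safe)
blockAlleles <- function(haplotypes, individual, chrom, markerIds, hap) {
    m <- haplotypes[[individual]][[chrom]]
    if (is.null(m)) return(rep(NA_character_, length(markerIds)))
    as.character(m[markerIds, hap])
}

# TRUE when two allele strings agree at every mutually non-missing marker
# and at least one such marker exists
allelesMatch <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    any(ok) && all(a[ok] == b[ok])
}

#' Trace block inheritance through a pedigree
#'
#' For each block and each haplotype of the focal individual, the parental
#' haplotype carrying identical alleles at all non-missing block markers is
#' identified; the match is propagated up the pedigree while it stays
#' unique, and recorded as `"unknown"` as soon as zero or several ancestral
#' haplotypes match (uninformative markers are never guessed). Untyped
#' pedigree members stop the propagation.
#'
#' @param ped validated pedigree (see [validatePedigree()]).
#' @param haplotypes phased alleles, `[[individual]][[chrom]]` markers x 2
#'   matrices as produced by [simulatePedigreeGenotypes()] (or read from a
#'   wide TSV).
#' @param blocks `GRanges` from [defineBlocks()] with a `markers` column.
#' @param individual focal individual id.
#' @param chrom chromosome name of `blocks`.
#' @return data.frame with one row per (block, haplotype): `block`, `start`,
#'   `end`, `hap` (`"maternal"`/`"paternal"`), `origin` (deepest uniquely
#'   matched ancestor haplotype, `"<id>:<1|2>"`, or `"unknown"`), `depth`
#'   (generations climbed), and the block allele string.
#' @export
traceInheritance <- function(ped, haplotypes, blocks, individual,
                             chrom = "chr1") {
    ped <- validatePedigree(ped)
    rows <- list()
    for (b in seq_along(blocks)) {
        mk <- mcols(blocks)$markers[[b]]
        for (hp in 1:2) {
            al <- blockAlleles(haplotypes, individual, chrom, mk, hp)
            origin <- "unknown"
            depth <- 0L
            if (length(mk) && any(!is.na(al))) {
                cur <- individual
                curHap <- hp
                repeat {
                    prow <- ped[ped$id == cur, ]
                    parent <- if (curHap == 1L) prow$dam else prow$sire
                    if (is.na(parent) || is.null(haplotypes[[parent]])) {
                        origin <- paste0(cur, ":", curHap)
                        break
                    }
                    p1 <- blockAlleles(haplotypes, parent, chrom, mk, 1L)
                    p2 <- blockAlleles(haplotypes, parent, chrom, mk, 2L)
                    m1 <- allelesMatch(al, p1)
                    m2 <- allelesMatch(al, p2)
                    if (m1 + m2 != 1L) {
                        origin <- if (depth == 0L) "unknown"
                                  else paste0(cur, ":", curHap)
                        break
                    }
                    cur <- parent
                    curHap <- if (m1) 1L else 2L
                    depth <- depth + 1L
                }
            }
            rows[[length(rows) + 1L]] <- data.frame(
                block = b, start = start(blocks)[b], end = end(blocks)[b],
                hap = c("maternal", "paternal")[hp],
                origin = origin, depth = depth,
                alleles = paste(ifelse(is.na(al), ".", al), collapse = ","),
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    attr(out, "individual") <- individual
    attr(out, "chrom") <- chrom
    out
}

#' Allele identity between a focal individual and an ancestor, per block
#'
#' A block is "matched" when either focal haplotype is allele-identical
#' (at all mutually non-missing block markers) to either haplotype of the
#' ancestor. Blocks with no informative marker never match.
#'
#' @param ped validated pedigree.
#' @param haplotypes phased alleles (see [traceInheritance()]).
#' @param blocksByChrom named list of block `GRanges`, one per chromosome.
#' @param individual focal individual id.
#' @param ancestor ancestor id (must be in the pedigree and typed).
#' @return data.frame per chromosome: `chrom`, `n_blocks`,
#'   `matched_blocks`, `matched_bp`, `total_bp`.
#' @export
ancestorIdentity <- function(ped, haplotypes, blocksByChrom, individual,
                             ancestor) {
    ped <- validatePedigree(ped)
    if (!ancestor %in% ped$id) stop("ancestor not in pedigree: ", ancestor)
    rows <- lapply(names(blocksByChrom), function(chr) {
        blocks <- blocksByChrom[[chr]]
        matched <- logical(length(blocks))
        for (b in seq_along(blocks)) {
            mk <- mcols(blocks)$markers[[b]]
            if (!length(mk)) next
            f1 <- blockAlleles(haplotypes, individual, chr, mk, 1L)
            f2 <- blockAlleles(haplotypes, individual, chr, mk, 2L)
            a1 <- blockAlleles(haplotypes, ancestor, chr, mk, 1L)
            a2 <- blockAlleles(haplotypes, ancestor, chr, mk, 2L)
            matched[b] <- allelesMatch(f1, a1) || allelesMatch(f1, a2) ||
                allelesMatch(f2, a1) || allelesMatch(f2, a2)
        }
        data.frame(chrom = chr, n_blocks = length(blocks),
                   matched_blocks = sum(matched),
                   matched_bp = sum(width(blocks)[matched]),
                   total_bp = sum(width(blocks)),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
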