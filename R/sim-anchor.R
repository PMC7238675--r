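#' Simulate a scaffold/marker/alignment fixture for anchoring
#'
#' Builds a toy assembly whose true layout is known: scaffolds with random
#' lengths are placed in order on one or more linkage groups with random
#' orientations; markers are placed on each scaffold and given cM positions
#' proportional to their true global position (2 cM/Mb); probe-alignment
#' records are emitted, with a controllable fraction degraded into
#' low-identity (< 98%), low-coverage (< 95%) or multi-hit decoys that the
#' alignment filter must remove.
#'
#' @param nScaffolds number of scaffolds (>= 1).
#' @param markersPerScaffold markers per scaffold (>= 1; >= 2 needed to
#'   recover orientation).
#' @param noise list with fractions `multiHit`, `lowIdentity`,
#'   `lowCoverage` (applied to disjoint probe subsets; default all 0).
#' @param seed integer seed.
#' @param nLG number of linkage groups scaffolds are distributed over.
#' @param lengthRange scaffold length range in bp.
#' @return list: `scaffoldLengths` (named), `geneticMap` (`marker`, `LG`,
#'   `cM`), `alignments` (probe TSV schema of
#'   [filterProbeAlignments()]), and `truth` (`layout` data.frame with
#'   `scaffold`, `LG`, `order`, `orientation`; `decoys` probe ids;
#'   `cmPerMb`).
#' @export
simulateAnchoringFixture <- function(nScaffolds, markersPerScaffold,
                                     noise = list(), seed = 1, nLG = 1,
                                     lengthRange = c(8e5, 2e6)) {
    stopifnot(nScaffolds >= 1, markersPerScaffold >= 1)
    noise <- utils::modifyList(
        list(multiHit = 0, lowIdentity = 0, lowCoverage = 0), noise)
    set.seed(seed)
    cmPerMb <- 2
    lens <- round(stats::runif(nScaffolds, lengthRange[1], lengthRange[2]))
    names(lens) <- sprintf("scaffold_%02d", seq_len(nScaffolds))
    lg <- rep(seq_len(nLG), length.out = nScaffolds)[order(seq_len(nScaffolds))]
    lg <- sort(lg)
    ori <- sample(c("+", "-"), nScaffolds, replace = TRUE)
    layout <- data.frame(scaffold = names(lens), LG = as.character(lg),
                         orientation = ori, stringsAsFactors = FALSE)
    layout$order <- stats::ave(seq_len(nScaffolds), layout$LG,
                               FUN = seq_along)
    mapRows <- list()
    alnRows <- list()
    for (g in unique(layout$LG)) {
        offset <- 0
        sub <- layout[layout$LG == g, , drop = FALSE]
        for (i in seq_len(nrow(sub))) {
            sc <- sub$scaffold[i]
            len <- lens[[sc]]
            x <- sort(sample.int(len - 80L, markersPerScaffold))
            globalBp <- if (sub$orientation[i] == "+") offset + x
                        else offset + (len - x + 1)
            probes <- sprintf("%s_m%02d", sc, seq_len(markersPerScaffold))
            mapRows[[length(mapRows) + 1L]] <- data.frame(
                marker = probes, LG = g, cM = globalBp / 1e6 * cmPerMb,
                stringsAsFactors = FALSE)
            alnRows[[length(alnRows) + 1L]] <- data.frame(
                probe = probes, target = sc, tstart = x, tend = x + 70L,
                identity = stats::runif(markersPerScaffold, 98.5, 100),
                coverage = stats::runif(markersPerScaffold, 0.96, 1),
                n_hits = 1L, stringsAsFactors = FALSE)
            offset <- offset + len
        }
    }
    geneticMap <- do.call(rbind, mapRows)
    alignments <- do.call(rbind, alnRows)
    # plant decoys on disjoint probe subsets
    n <- nrow(alignments)
    fr <- c(noise$multiHit, noise$lowIdentity, noise$lowCoverage)
    nDecoy <- round(fr * n)
    pool <- sample.int(n)
    take <- function(k) {
        out <- utils::head(pool, k)
        pool <<- utils::tail(pool, length(pool) - k)
        out
    }
    iMulti <- take(nDecoy[1])
    iIdent <- take(nDecoy[2])
    iCov <- take(nDecoy[3])
    if (length(iMulti))
        alignments$n_hits[iMulti] <- sample(2:5, length(iMulti), replace = TRUE)
    if (length(iIdent))
        alignments$identity[iIdent] <- stats::runif(length(iIdent), 90, 97.9)
    if (length(iCov))
        alignments$coverage[iCov] <- stats::runif(length(iCov), 0.5, 0.945)
    decoys <- alignments$probe[sort(c(iMulti, iIdent, iCov))]
    list(scaffoldLengths = lens, geneticMap = geneticMap,
         alignments = alignments,
         truth = list(layout = layout, decoys = decoys, cmPerMb = cmPerMb))
}

#' Write an alignment TSV
#' @param alignments alignment data.frame (see [filterProbeAlignments()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAlignmentsTSV <- function(alignments, path) {
    utils::write.table(alignments, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read an alignment TSV
#' @param path file path.
#' @return alignment data.frame.
#' @export
readAlignmentsTSV <- function(path) {
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
}
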