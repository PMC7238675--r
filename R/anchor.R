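## Anchoring assembly scaffolds to a genetic map: probe-alignment filtering,
## linkage-group assignment, ordering and orientation, AGP pseudomolecule
## layout with fixed 100-kb gaps, and Marey-map recombination rates.

#' Filter probe alignments
#'
#' Retains alignments with identity at or above `minIdentity` percent,
#' probe coverage at or above `minCoverage`, and (by default) a single hit
#' genome-wide, i.e. filters out alignments with identity < 98%, covering
#' < 95% of the probe, or aligning multiple times. Idempotent.
#'
#' @param alignments data.frame with columns `probe`, `target`, `tstart`,
#'   `tend`, `identity` (percent), `coverage` (fraction), `n_hits`.
#' @param minIdentity minimum percent identity (default 98).
#' @param minCoverage minimum covered fraction of the probe (default 0.95).
#' @param uniqueOnly keep only probes with `n_hits == 1` (default TRUE).
#' @return the retained subset, same columns.
#' @export
filterProbeAlignments <- function(alignments, minIdentity = 98,
                                  minCoverage = 0.95, uniqueOnly = TRUE) {
    need <- c("probe", "target", "tstart", "tend", "identity", "coverage",
              "n_hits")
    stopifnot(all(need %in% names(alignments)))
    keep <- alignments$identity >= minIdentity &
        alignments$coverage >= minCoverage
    if (uniqueOnly) keep <- keep & alignments$n_hits == 1L
    out <- alignments[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Assign scaffolds to linkage groups, order and orient them
#'
#' Each scaffold is assigned to the modal linkage group of its retained
#' markers, but only when the mode holds more than 2/3 of them (otherwise
#' the scaffold is left unanchored with a conflict flag). Within a linkage
#' group, scaffolds are ordered by the mean cM of their markers.
#' Orientation is the sign of the Spearman rank correlation between marker
#' cM and scaffold bp: positive is `"+"`, negative `"-"`; fewer than two
#' distinct positions (or a zero correlation) gives `"unknown"`, laid out
#' as `"+"`.
#'
#' @param retained filtered alignments (see [filterProbeAlignments()]).
#' @param geneticMap data.frame with columns `marker`, `LG`, `cM`; every
#'   retained probe must appear in it.
#' @return list with `anchored` (data.frame: `scaffold`, `LG`,
#'   `orientation`, `mean_cM`, `n_markers`) ordered by LG then mean cM, and
#'   `unanchored` (data.frame: `scaffold`, `reason`).
#' @export
assignOrderOrient <- function(retained, geneticMap) {
    stopifnot(all(c("marker", "LG", "cM") %in% names(geneticMap)))
    missing <- setdiff(retained$probe, geneticMap$marker)
    if (length(missing))
        stop("retained probe(s) absent from the genetic map: ",
             paste(utils::head(missing, 5), collapse = ", "))
    mIdx <- match(retained$probe, geneticMap$marker)
    tab <- data.frame(scaffold = retained$target,
                      bp = (retained$tstart + retained$tend) / 2,
                      LG = geneticMap$LG[mIdx],
                      cM = geneticMap$cM[mIdx],
                      stringsAsFactors = FALSE)
    anchored <- list()
    unanchored <- list()
    for (sc in unique(tab$scaffold)) {
        sub <- tab[tab$scaffold == sc, , drop = FALSE]
        lgTab <- table(sub$LG)
        modal <- names(lgTab)[which.max(lgTab)]
        if (max(lgTab) <= 2 / 3 * nrow(sub) && length(lgTab) > 1L) {
            unanchored[[length(unanchored) + 1L]] <-
                data.frame(scaffold = sc, reason = "LG conflict",
                           stringsAsFactors = FALSE)
            next
        }
        sub <- sub[sub$LG == modal, , drop = FALSE]
        orientation <- "unknown"
        if (length(unique(sub$cM)) >= 2L && length(unique(sub$bp)) >= 2L) {
            rho <- stats::cor(sub$cM, sub$bp, method = "spearman")
            if (!is.na(rho) && rho > 0) orientation <- "+"
            else if (!is.na(rho) && rho < 0) orientation <- "-"
        }
        anchored[[length(anchored) + 1L]] <-
            data.frame(scaffold = sc, LG = modal, orientation = orientation,
                       mean_cM = mean(sub$cM), n_markers = nrow(sub),
                       stringsAsFactors = FALSE)
    }
    anchored <- if (length(anchored)) do.call(rbind, anchored) else
        data.frame(scaffold = character(), LG = character(),
                   orientation = character(), mean_cM = numeric(),
                   n_markers = integer())
    anchored <- anchored[order(anchored$LG, anchored$mean_cM), , drop = FALSE]
    rownames(anchored) <- NULL
    unanchored <- if (length(unanchored)) do.call(rbind, unanchored) else
        data.frame(scaffold = character(), reason = character())
    list(anchored = anchored, unanchored = unanchored)
}

#' Build pseudomolecules (AGP v2.1 layout) from anchored scaffolds
#'
#' Concatenates the ordered, oriented scaffolds of each linkage group into a
#' pseudomolecule, separating consecutive scaffolds by fixed-length gaps
#' (100,000 bp by default), emitted as known-length `N` gap rows of type
#' `contig`. Scaffolds with `"unknown"` orientation are laid out as `"+"`.
#'
#' @param anchored data.frame from [assignOrderOrient()]`$anchored`.
#' @param scaffoldLengths named numeric vector of scaffold lengths (bp).
#' @param gapBp gap length between consecutive scaffolds (default 100000).
#' @param objectPrefix name prefix for pseudomolecules (default `"chr"`, so
#'   LG "1" becomes object "chr1"; a prefix already present is not doubled).
#' @return data.frame of AGP v2.1 rows: `object`, `object_beg`,
#'   `object_end`, `part_number`, `component_type` (`W`/`N`),
#'   `component_id` (gap length for `N` rows), `component_beg` (gap type),
#'   `component_end` (linkage), `orientation` (evidence for gap rows).
#' @export
buildPseudomolecules <- function(anchored, scaffoldLengths, gapBp = 100000,
                                 objectPrefix = "chr") {
    if (anyDuplicated(anchored$scaffold))
        stop("scaffold assigned more than once")
    miss <- setdiff(anchored$scaffold, names(scaffoldLengths))
    if (length(miss)) stop("missing scaffold length(s): ",
                           paste(miss, collapse = ", "))
    rows <- list()
    for (lg in unique(anchored$LG)) {
        sub <- anchored[anchored$LG == lg, , drop = FALSE]
        obj <- if (startsWith(as.character(lg), objectPrefix))
            as.character(lg) else paste0(objectPrefix, lg)
        pos <- 0
        part <- 0L
        for (i in seq_len(nrow(sub))) {
            if (i > 1L && gapBp > 0) {
                part <- part + 1L
                rows[[length(rows) + 1L]] <- data.frame(
                    object = obj, object_beg = pos + 1,
                    object_end = pos + gapBp, part_number = part,
                    component_type = "N", component_id = format(gapBp, scientific = FALSE),
                    component_beg = "contig", component_end = "yes",
                    orientation = "map", stringsAsFactors = FALSE)
                pos <- pos + gapBp
            }
            len <- scaffoldLengths[[sub$scaffold[i]]]
            part <- part + 1L
            ori <- if (sub$orientation[i] == "-") "-" else "+"
            rows[[length(rows) + 1L]] <- data.frame(
                object = obj, object_beg = pos + 1, object_end = pos + len,
                part_number = part, component_type = "W",
                component_id = sub$scaffold[i], component_beg = "1",
                component_end = as.character(len), orientation = ori,
                stringsAsFactors = FALSE)
            pos <- pos + len
        }
    }
    agp <- do.call(rbind, rows)
    rownames(agp) <- NULL
    agp
}

#' Lift coordinates between scaffolds and pseudomolecules
#'
#' `liftToPseudomolecule()` maps a 1-based scaffold position to its
#' pseudomolecule coordinate, honouring orientation (`-` scaffolds map
#' `x` to `object_beg - 1 + (len - x + 1)`); `liftFromPseudomolecule()` is
#' its exact inverse on component spans.
#'
#' @param agp AGP data.frame from [buildPseudomolecules()].
#' @param scaffold scaffold id(s).
#' @param pos 1-based position(s) on the scaffold.
#' @return data.frame `object`, `pos` (or `scaffold`, `pos` for the
#'   inverse); positions falling in gaps return `NA` scaffolds.
#' @export
liftToPseudomolecule <- function(agp, scaffold, pos) {
    w <- agp[agp$component_type == "W", , drop = FALSE]
    idx <- match(scaffold, w$component_id)
    if (anyNA(idx)) stop("scaffold not in AGP: ",
                         paste(scaffold[is.na(idx)], collapse = ", "))
    len <- w$object_end[idx] - w$object_beg[idx] + 1
    stopifnot(all(pos >= 1 & pos <= len))
    out <- ifelse(w$orientation[idx] == "-",
                  w$object_beg[idx] - 1 + (len - pos + 1),
                  w$object_beg[idx] - 1 + pos)
    data.frame(object = w$object[idx], pos = out, stringsAsFactors = FALSE)
}

#' @rdname liftToPseudomolecule
#' @param object pseudomolecule name(s).
#' @export
liftFromPseudomolecule <- function(agp, object, pos) {
    out <- data.frame(scaffold = rep(NA_character_, length(pos)),
                      pos = rep(NA_real_, length(pos)),
                      stringsAsFactors = FALSE)
    w <- agp[agp$component_type == "W", , drop = FALSE]
    for (i in seq_along(pos)) {
        row <- w[w$object == object[i] & w$object_beg <= pos[i] &
                     w$object_end >= pos[i], , drop = FALSE]
        if (!nrow(row)) next
        len <- row$object_end - row$object_beg + 1
        off <- pos[i] - row$object_beg + 1
        out$scaffold[i] <- row$component_id
        out$pos[i] <- if (row$orientation == "-") len - off + 1 else off
    }
    out
}

#' Marey-map recombination rate in sliding windows
#'
#' For markers carrying both a pseudomolecule bp position and a cM position,
#' the recombination rate of each sliding window (10 Mb / 1 Mb step by
#' default) is the least-squares slope of cM on Mb over the markers inside
#' the window. Windows with fewer than `minMarkers` markers are undefined.
#'
#' @param markers data.frame with columns `chrom`, `bp`, `cM`.
#' @param chromLengths named numeric vector of pseudomolecule lengths.
#' @param windowBp,stepBp sliding-window size and step (default 10 Mb, 1 Mb).
#' @param minMarkers minimum markers per window (default 2).
#' @return data.frame: `chrom`, `start`, `end`, `n_markers`, `rate_cM_Mb`.
#' @export
mareyRecombinationRate <- function(markers, chromLengths, windowBp = 1e7,
                                   stepBp = 1e6, minMarkers = 2) {
    stopifnot(all(c("chrom", "bp", "cM") %in% names(markers)))
    nonmono <- unlist(lapply(split(markers[order(markers$bp), ], markers$chrom[order(markers$bp)]),
                             function(z) any(diff(z$cM) < 0)))
    if (any(nonmono))
        warning("cM not monotone within chromosome(s): ",
                paste(names(nonmono)[nonmono], collapse = ", "))
    wins <- tileWindows(chromLengths, windowBp, stepBp)
    mGr <- GRanges(markers$chrom, IRanges(markers$bp, width = 1L))
    GenomeInfoDb::seqlevels(mGr) <- union(GenomeInfoDb::seqlevels(mGr),
                                          seqlevels(wins))
    h <- findOverlaps(wins, mGr)
    rate <- rep(NA_real_, length(wins))
    nM <- countOverlaps(wins, mGr)
    for (w in unique(S4Vectors::queryHits(h))) {
        idx <- S4Vectors::subjectHits(h)[S4Vectors::queryHits(h) == w]
        if (length(idx) < minMarkers) next
        x <- markers$bp[idx] / 1e6
        y <- markers$cM[idx]
        if (length(unique(x)) < 2L) next
        rate[w] <- stats::cov(x, y) / stats::var(x)
    }
    data.frame(chrom = as.character(seqnames(wins)), start = start(wins),
               end = end(wins), n_markers = nM, rate_cM_Mb = rate,
               stringsAsFactors = FALSE)
}
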