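## Gene-dropping through a pedigree: founders receive uniquely labelled
## haplotypes; each meiosis draws crossovers as a Poisson process along the
## cM map (Haldane model, no interference) and children inherit recombinant
## mosaics. Ground truth (segment origins and crossover positions) is kept
## for recovery tests.

#' Validate a pedigree table
#'
#' @param ped data.frame with columns `id`, `sire`, `dam` (`NA` for
#'   founders). Individuals must have both parents known or neither, and the
#'   pedigree must be acyclic.
#' @return the pedigree in topological order (parents before children), with
#'   a logical `founder` column.
#' @export
validatePedigree <- function(ped) {
    stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
    ped$id <- as.character(ped$id)
    ped$sire <- as.character(ped$sire)
    ped$dam <- as.character(ped$dam)
    if (anyDuplicated(ped$id)) stop("duplicated individual ids")
    one <- xor(is.na(ped$sire), is.na(ped$dam))
    if (any(one))
        stop("individual(s) with exactly one known parent: ",
             paste(ped$id[one], collapse = ", "))
    known <- c(ped$sire, ped$dam)
    known <- known[!is.na(known)]
    if (!all(known %in% ped$id))
        stop("parent(s) not present as individuals: ",
             paste(setdiff(known, ped$id), collapse = ", "))
    ped$founder <- is.na(ped$sire)
    # Kahn topological sort; failure to place everyone means a cycle
    placed <- character()
    remaining <- ped
    order <- integer()
    while (nrow(remaining)) {
        ready <- which(remaining$founder |
                       (remaining$sire %in% placed & remaining$dam %in% placed))
        if (!length(ready)) stop("pedigree contains a cycle")
        placed <- c(placed, remaining$id[ready])
        order <- c(order, match(remaining$id[ready], ped$id))
        remaining <- remaining[-ready, , drop = FALSE]
    }
    ped[order, , drop = FALSE]
}

#' Validate a genetic map table
#'
#' @param map data.frame with columns `marker`, `chrom`, `bp`, `cM`.
#' @return the map ordered by chromosome and bp; errors when cM is not
#'   monotone non-decreasing in bp within a chromosome.
#' @export
validateGeneticMap <- function(map) {
    stopifnot(all(c("marker", "chrom", "bp", "cM") %in% names(map)))
    map <- map[order(map$chrom, map$bp), , drop = FALSE]
    bad <- unlist(lapply(split(map$cM, map$chrom),
                         function(z) any(diff(z) < 0)))
    if (any(bad))
        stop("cM not monotone in bp on chromosome(s): ",
             paste(names(bad)[bad], collapse = ", "))
    map
}

# clip a segment table (start, end, label; closed bp intervals) to [lo, hi]
clipSegments <- function(segs, lo, hi) {
    keep <- segs$end >= lo & segs$start <= hi
    out <- segs[keep, , drop = FALSE]
    out$start <- pmax(out$start, lo)
    out$end <- pmin(out$end, hi)
    out
}

# one meiosis: recombine a parent's two haplotype segment tables at the
# given crossover breakpoints (bp), starting from haplotype `startHap`
composeMeiosis <- function(hapSegs, breaks, startHap, chromLen) {
    bounds <- c(0, sort(breaks), chromLen)
    cur <- startHap
    pieces <- list()
    for (j in seq_len(length(bounds) - 1L)) {
        lo <- bounds[j] + 1
        hi <- bounds[j + 1L]
        if (hi >= lo)
            pieces[[length(pieces) + 1L]] <- clipSegments(hapSegs[[cur]], lo, hi)
        cur <- 3L - cur
    }
    out <- do.call(rbind, pieces)
    out <- out[order(out$start), , drop = FALSE]
    # merge touching runs of the same origin
    if (nrow(out) > 1L) {
        same <- out$label[-1L] == out$label[-nrow(out)] &
            out$start[-1L] == out$end[-nrow(out)] + 1
        grp <- cumsum(c(TRUE, !same))
        out <- data.frame(start = tapply(out$start, grp, min),
                          end = tapply(out$end, grp, max),
                          label = out$label[!duplicated(grp)],
                          stringsAsFactors = FALSE)
    }
    rownames(out) <- NULL
    out
}

#' Gene-drop simulation of phased genotypes through a pedigree
#'
#' Each founder receives two uniquely labelled haplotypes (`"<id>_1"`,
#' `"<id>_2"`). Every meiosis draws a `Poisson(L_cM / 100)` number of
#' crossovers placed uniformly on the cM scale (Haldane, no interference),
#' converted to bp by piecewise-linear interpolation through the marker map.
#' By convention haplotype 1 of a child is maternal, haplotype 2 paternal.
#'
#' @param ped pedigree data.frame (`id`, `sire`, `dam`).
#' @param map genetic map (`marker`, `chrom`, `bp`, `cM`).
#' @param seed integer seed.
#' @param founderAlleles `"labels"` for fully informative alleles (each
#'   founder haplotype is its own allele) or `"biallelic"` for 0/1 alleles
#'   drawn Bernoulli(0.5) per founder haplotype and marker.
#' @param chromLengths named bp lengths; defaults to the last mapped marker
#'   position per chromosome.
#' @return list with
#'   `haplotypes` — `[[individual]][[chrom]]`: markers x 2 matrix of
#'   alleles (phased; column 1 maternal);
#'   `truth` — `segments` (individual, chrom, hap, start, end,
#'   founder_hap) and `crossovers` (child, parent role, chrom, bp);
#'   `map`, `pedigree`, `chromLengths`.
#' @export
simulatePedigreeGenotypes <- function(ped, map, seed = 1,
                                      founderAlleles = c("labels", "biallelic"),
                                      chromLengths = NULL) {
    founderAlleles <- match.arg(founderAlleles)
    ped <- validatePedigree(ped)
    map <- validateGeneticMap(map)
    chroms <- unique(map$chrom)
    if (is.null(chromLengths)) {
        chromLengths <- vapply(split(map$bp, map$chrom), max, numeric(1))
        chromLengths <- chromLengths[chroms]
    }
    if (any(map$bp > chromLengths[map$chrom]))
        stop("marker position beyond chromosome length")
    set.seed(seed)
    founderIds <- ped$id[ped$founder]
    alleleOf <- NULL
    if (founderAlleles == "biallelic") {
        hapNames <- as.vector(outer(founderIds, 1:2, paste, sep = "_"))
        alleleOf <- matrix(stats::rbinom(nrow(map) * length(hapNames), 1L, 0.5),
                           nrow(map), length(hapNames),
                           dimnames = list(map$marker, hapNames))
    }
    segs <- list()   # [[id]][[chrom]] = list(hap1 = df, hap2 = df)
    xovers <- list()
    for (i in seq_len(nrow(ped))) {
        id <- ped$id[i]
        segs[[id]] <- list()
        for (chr in chroms) {
            L <- chromLengths[[chr]]
            sub <- map[map$chrom == chr, , drop = FALSE]
            Lcm <- max(sub$cM)
            if (ped$founder[i]) {
                segs[[id]][[chr]] <- list(
                    hap1 = data.frame(start = 1, end = L,
                                      label = paste0(id, "_1"),
                                      stringsAsFactors = FALSE),
                    hap2 = data.frame(start = 1, end = L,
                                      label = paste0(id, "_2"),
                                      stringsAsFactors = FALSE))
                next
            }
            drop1 <- function(parent, role) {
                k <- stats::rpois(1L, Lcm / 100)
                xcCm <- sort(stats::runif(k, 0, Lcm))
                breaks <- numeric(0)
                if (k > 0) {
                    breaks <- round(stats::approx(
                        x = c(0, sub$cM, Lcm + 1e-9),
                        y = c(0, sub$bp, L),
                        xout = xcCm, ties = "ordered")$y)
                    breaks <- unique(pmin(pmax(breaks, 1), L - 1))
                    if (length(breaks))
                        xovers[[length(xovers) + 1L]] <<-
                            data.frame(child = id, parent = role, chrom = chr,
                                       bp = breaks, stringsAsFactors = FALSE)
                }
                startHap <- sample.int(2L, 1L)
                composeMeiosis(segs[[parent]][[chr]], breaks, startHap, L)
            }
            segs[[id]][[chr]] <- list(hap1 = drop1(ped$dam[i], "dam"),
                                      hap2 = drop1(ped$sire[i], "sire"))
        }
    }
    # emit marker alleles per haplotype
    haplotypes <- lapply(segs, function(byChr) {
        out <- list()
        for (chr in names(byChr)) {
            sub <- map[map$chrom == chr, , drop = FALSE]
            lab1 <- segmentLabelAt(byChr[[chr]]$hap1, sub$bp)
            lab2 <- segmentLabelAt(byChr[[chr]]$hap2, sub$bp)
            if (founderAlleles == "labels") {
                m <- cbind(lab1, lab2)
            } else {
                m <- cbind(alleleOf[cbind(sub$marker, lab1)],
                           alleleOf[cbind(sub$marker, lab2)])
            }
            dimnames(m) <- list(sub$marker, c("hap1", "hap2"))
            out[[chr]] <- m
        }
        out
    })
    segTab <- do.call(rbind, lapply(names(segs), function(id) {
        do.call(rbind, lapply(names(segs[[id]]), function(chr) {
            do.call(rbind, lapply(1:2, function(hp) {
                s <- segs[[id]][[chr]][[paste0("hap", hp)]]
                data.frame(individual = id, chrom = chr, hap = hp,
                           start = s$start, end = s$end,
                           founder_hap = s$label, stringsAsFactors = FALSE)
            }))
        }))
    }))
    crossovers <- if (length(xovers)) do.call(rbind, xovers) else
        data.frame(child = character(), parent = character(),
                   chrom = character(), bp = numeric())
    list(haplotypes = haplotypes,
         truth = list(segments = segTab, crossovers = crossovers),
         map = map, pedigree = ped, chromLengths = chromLengths)
}

# founder-haplotype label of the segment containing each position
segmentLabelAt <- function(segTab, pos) {
    idx <- findInterval(pos, segTab$start)
    bad <- idx < 1 | pos > segTab$end[pmax(idx, 1L)]
    lab <- segTab$label[pmax(idx, 1L)]
    lab[bad] <- NA_character_
    lab
}

#' True autozygous (IBD) segments of one simulated individual
#'
#' Intersects the two haplotype segment tables of an individual: regions
#' where both haplotypes descend from the same founder haplotype are
#' identical by descent.
#'
#' @param sim result of [simulatePedigreeGenotypes()].
#' @param individual individual id.
#' @return `GRanges` of IBD segments (possibly empty).
#' @export
trueIbdSegments <- function(sim, individual) {
    segs <- sim$truth$segments
    segs <- segs[segs$individual == individual, , drop = FALSE]
    hit <- list()
    for (chr in unique(segs$chrom)) {
        s1 <- segs[segs$chrom == chr & segs$hap == 1, , drop = FALSE]
        s2 <- segs[segs$chrom == chr & segs$hap == 2, , drop = FALSE]
        for (i in seq_len(nrow(s1))) for (j in seq_len(nrow(s2))) {
            if (s1$founder_hap[i] != s2$founder_hap[j]) next
            lo <- max(s1$start[i], s2$start[j])
            hi <- min(s1$end[i], s2$end[j])
            if (lo <= hi)
                hit[[length(hit) + 1L]] <- data.frame(chrom = chr, start = lo,
                                                      end = hi)
        }
    }
    if (!length(hit)) return(GRanges())
    tab <- do.call(rbind, hit)
    GenomicRanges::reduce(GRanges(tab$chrom, IRanges(tab$start, tab$end)),
                          min.gapwidth = 1L)
}

#' Per-window heterozygous-marker counts from phased simulation output
#'
#' A marker is heterozygous when the two phased alleles differ; with fully
#' informative founder labels this is equivalent to the two haplotypes
#' having distinct founder origins at the marker.
#'
#' @param sim result of [simulatePedigreeGenotypes()].
#' @param individual focal individual id.
#' @param windows `GRanges` of windows (e.g. 1-Mb tiling of
#'   `sim$chromLengths`).
#' @return integer vector of heterozygous-marker counts per window.
#' @export
phasedHetCounts <- function(sim, individual, windows) {
    haps <- sim$haplotypes[[individual]]
    hetPos <- list()
    for (chr in names(haps)) {
        m <- haps[[chr]]
        sub <- sim$map[sim$map$chrom == chr, , drop = FALSE]
        het <- m[, 1L] != m[, 2L]
        if (any(het))
            hetPos[[chr]] <- data.frame(chrom = chr, bp = sub$bp[het])
    }
    if (!length(hetPos)) return(integer(length(windows)))
    tab <- do.call(rbind, hetPos)
    countOverlaps(windows, GRanges(tab$chrom, IRanges(tab$bp, width = 1L)))
}

#' Write pedigree and genetic-map tables
#'
#' @param ped pedigree data.frame; written as CSV (`id,sire,dam`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePedigreeCSV <- function(ped, path) {
    utils::write.csv(ped[, c("id", "sire", "dam")], path, row.names = FALSE,
                     quote = FALSE, na = "")
    invisible(path)
}

#' @rdname writePedigreeCSV
#' @param map genetic map data.frame; written as TSV
#'   (`marker`, `chrom`, `bp`, `cM`).
#' @export
writeGeneticMapTSV <- function(map, path) {
    utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a pedigree CSV (`id,sire,dam`; empty fields = founder)
#' @param path file path.
#' @return validated pedigree data.frame.
#' @export
readPedigreeCSV <- function(path) {
    ped <- utils::read.csv(path, stringsAsFactors = FALSE,
                           na.strings = c("", "NA"))
    validatePedigree(ped)
}

#' Read a genetic-map TSV (`marker`, `chrom`, `bp`, `cM`)
#' @param path file path.
#' @return validated map data.frame.
#' @export
readGeneticMapTSV <- function(path) {
    validateGeneticMap(utils::read.table(path, header = TRUE, sep = "\t",
                                         stringsAsFactors = FALSE))
}
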