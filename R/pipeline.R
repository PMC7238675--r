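#' Default run configuration
#'
#' Returns the configuration skeleton consumed by [runPipeline()]. Paths may
#' point to existing inputs; when `simulate` is `TRUE` the two-population
#' generator provides the VCF and groups file. Thresholds default to the
#' standard analysis settings: MAF > 0.10 with no missing data, 100-kb scan
#' windows plus a 500-kb track, 0.95 outlier quantile, 1,000 permutations,
#' 1-Mb density windows with a 10th-percentile low-heterozygosity threshold.
#'
#' @param ... named overrides of the defaults.
#' @return a list of class `RunConfig`.
#' @export
runConfig <- function(...) {
    cfg <- list(
        seed = 1,
        outDir = "divscan-out",
        simulate = TRUE,
        sim = list(nPop1 = 11, nPop2 = 12, nSites = 10000,
                   chromLength = 20e6, divergenceF = 0.15),
        vcf = NULL, groups = NULL,
        mafMin = 0.10, maxMissingFraction = 0.0,
        scanWindowSizes = c(100000, 500000),
        outlierQuantile = 0.95,
        nPermutations = 1000,
        densityWindowSize = 1e6,
        lowHetPercentile = 10,
        focalSample = NULL,
        traitLoci = NULL,
        anchor = NULL)
    over <- list(...)
    cfg[names(over)] <- over
    stopifnot(cfg$outlierQuantile > 0, cfg$outlierQuantile < 1,
              cfg$mafMin >= 0, cfg$mafMin <= 0.5,
              cfg$lowHetPercentile > 0, cfg$lowHetPercentile < 100)
    class(cfg) <- "RunConfig"
    cfg
}

#' Read a run configuration from a YAML file
#' @param path YAML file whose keys match [runConfig()] arguments.
#' @return a `RunConfig` list.
#' @export
readRunConfig <- function(path) {
    stopifnot(file.exists(path))
    do.call(runConfig, yaml::read_yaml(path))
}

writeTsv <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

grToBed <- function(gr, path) {
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = start(gr) - 1L, end = end(gr))
    extra <- as.data.frame(mcols(gr))
    if (ncol(extra)) df <- cbind(df, extra)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    path
}

#' Run the genome-scan pipeline end to end
#'
#' Executes, in order: input acquisition (simulation or VCF + groups file),
#' variant filtering, the SNP-density / heterozygosity scan, the windowed
#' divergence scan with outlier calling and permutation FDR, optional
#' trait-locus overlap, optional anchoring, and writes per-window TSVs, a
#' BED of low-heterozygosity regions, an AGP (when anchoring runs) and a
#' JSON run manifest recording the seed, package version and stage counts.
#' Any stage failure aborts with the stage name; a `.partial` marker file is
#' left in the output directory.
#'
#' @param config a `RunConfig` from [runConfig()] or [readRunConfig()].
#' @return (invisibly) a list with the computed objects and output paths.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "RunConfig"))
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    partial <- file.path(config$outDir, ".partial")
    file.create(partial)
    manifest <- list(seed = config$seed,
                     package = "divscan",
                     version = as.character(utils::packageVersion("divscan")),
                     stages = list())
    outputs <- list()
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }
    ## -- input
    gm <- stage("input", {
        if (isTRUE(config$simulate)) {
            sim <- simulateTwoPopulations(do.call(
                twoPopSimConfig, c(config$sim, list(seed = config$seed))))
            vcfPath <- file.path(config$outDir, "simulated.vcf")
            writeVCF(sim$genotypes, vcfPath)
            writeGroupsFile(sampleGroups(sim$genotypes),
                            file.path(config$outDir, "simulated.groups.tsv"))
            outputs$vcf <- vcfPath
            sim$genotypes
        } else {
            if (is.null(config$vcf) || !file.exists(config$vcf))
                stop("input VCF not found: ", config$vcf)
            if (is.null(config$groups) || !file.exists(config$groups))
                stop("groups file not found: ", config$groups)
            readVCF(config$vcf, config$groups)
        }
    })
    manifest$stages$input <- list(n_sites = nSites(gm), n_samples = ncol(gm))
    ## -- filtering
    flt <- stage("filter", filterVariants(gm, config$mafMin,
                                          config$maxMissingFraction))
    manifest$stages$filter <- list(retained = nSites(flt),
                                   removed = metadata(flt)$filtered_sites)
    ## -- density / heterozygosity scan
    stage("density", {
        dw <- tileWindows(chromLengths(gm), config$densityWindowSize)
        focal <- config$focalSample
        counts <- countSnpsPerWindow(gm, dw,
                                     heterozygousOnly = !is.null(focal),
                                     focalSample = focal)
        thr <- lowHetThreshold(counts, config$lowHetPercentile,
                               partial = mcols(dw)$partial)
        regions <- callLowHetRegions(dw, counts, thr)
        outputs$density <- writeTsv(
            data.frame(chrom = as.character(seqnames(dw)), start = start(dw),
                       end = end(dw), n_snps = counts),
            file.path(config$outDir, "window_density.tsv"))
        outputs$low_het_bed <- grToBed(
            regions, file.path(config$outDir, "low_het_regions.bed"))
        manifest$stages$density <- list(windows = length(dw),
                                         threshold = unname(thr),
                                         regions = length(regions))
    })
    ## -- divergence scan per window size
    scanRes <- list()
    for (ws in config$scanWindowSizes) {
        scanRes[[as.character(ws)]] <- stage(paste0("scan_", ws), {
            wins <- tileWindows(chromLengths(flt), ws)
            stats <- computeWindowStats(flt, wins)
            out <- callFstOutliers(stats$fst, config$outlierQuantile)
            fdr <- permutationFdr(flt, wins, out$cutoff,
                                  nPermutations = config$nPermutations,
                                  seed = config$seed)
            stats$is_outlier <- out$calls$is_outlier
            sweeps <- classifySweeps(stats, out)
            tag <- sprintf("%dkb", ws / 1000)
            outputs[[paste0("stats_", tag)]] <- writeTsv(
                stats, file.path(config$outDir,
                                 sprintf("window_stats_%s.tsv", tag)))
            outputs[[paste0("sweeps_", tag)]] <- writeTsv(
                sweeps, file.path(config$outDir,
                                  sprintf("sweep_candidates_%s.tsv", tag)))
            manifest$stages[[paste0("scan_", tag)]] <-
                list(windows = length(wins), cutoff = out$cutoff,
                     outliers = sum(out$calls$is_outlier),
                     fdr = fdr$fdr)
            list(windows = wins, stats = stats, outliers = out, fdr = fdr,
                 sweeps = sweeps)
        })
    }
    ## -- trait loci (optional)
    if (!is.null(config$traitLoci)) {
        stage("trait_loci", {
            loci <- utils::read.table(config$traitLoci, header = TRUE,
                                      sep = "\t", stringsAsFactors = FALSE)
            first <- scanRes[[1L]]
            hits <- overlapTraitLoci(loci, first$windows, first$stats,
                                     first$outliers)
            outputs$trait_loci <- writeTsv(
                hits, file.path(config$outDir, "trait_locus_overlap.tsv"))
            manifest$stages$trait_loci <-
                list(n_loci = nrow(loci), placed = sum(hits$placed))
        })
    }
    ## -- anchoring (optional)
    if (!is.null(config$anchor)) {
        stage("anchor", {
            a <- config$anchor
            aln <- readAlignmentsTSV(a$alignments)
            gmap <- utils::read.table(a$geneticMap, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE)
            lens <- utils::read.table(a$scaffoldLengths, header = TRUE,
                                      sep = "\t", stringsAsFactors = FALSE)
            lens <- stats::setNames(lens[[2L]], lens[[1L]])
            kept <- filterProbeAlignments(aln)
            oo <- assignOrderOrient(kept, gmap)
            agp <- buildPseudomolecules(oo$anchored, lens)
            outputs$agp <- writeTsv(agp, file.path(config$outDir,
                                                    "pseudomolecules.agp"))
            outputs$anchoring <- writeTsv(
                oo$anchored, file.path(config$outDir, "anchoring_report.tsv"))
            manifest$stages$anchor <- list(alignments = nrow(aln),
                                            retained = nrow(kept),
                                            anchored = nrow(oo$anchored))
        })
    }
    manifestPath <- file.path(config$outDir, "manifest.json")
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    file.remove(partial)
    invisible(list(genotypes = gm, filtered = flt, scans = scanRes,
                   outputs = outputs, manifest = manifest,
                   manifestPath = manifestPath))
}
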