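#' Read and write methylation datasets
#'
#' The on-disk dialect is plain text: a manifest CSV with header
#' `probe_id,chrom,pos,design_type`, and beta / detection-p TSVs with a
#' `probe_id` key column and one column per sample; missing values are
#' written as `NA`. Gzipped files are read transparently. `read` and `write`
#' round-trip: `readMethylationDataset(writeMethylationDataset(x, dir), ...)`
#' reproduces `x`'s matrices, manifest and roles.
#'
#' @param manifestFile,betaFile,detectionPFile input paths.
#' @param case,controls case/control design, as in
#'   [MethylationExperiment()].
#' @return `readMethylationDataset()`: a [MethylationExperiment-class];
#'   `writeMethylationDataset()`: the directory, invisibly.
#' @export
readMethylationDataset <- function(manifestFile, betaFile, detectionPFile,
                                   case, controls = "all-others") {
    manifest <- read.csv(manifestFile, stringsAsFactors = FALSE)
    beta <- read_matrix_tsv(betaFile)
    detP <- read_matrix_tsv(detectionPFile)
    MethylationExperiment(manifest, beta, detP, case = case,
                          controls = controls)
}

read_matrix_tsv <- function(file) {
    df <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
    if (colnames(df)[1L] != "probe_id")
        stop(file, ": first column must be 'probe_id', found '",
             colnames(df)[1L], "'")
    ids <- df[[1L]]
    if (anyDuplicated(ids))
        stop(file, ": duplicate probe ids: ",
             paste(head(unique(ids[duplicated(ids)]), 5), collapse = ", "))
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) {
        bad <- which(!vapply(df[-1L], is.numeric, TRUE))
        stop(file, ": non-numeric values in column(s) ",
             paste(colnames(df)[-1L][bad], collapse = ", "))
    }
    rownames(m) <- ids
    m
}

#' @rdname readMethylationDataset
#' @param x a [MethylationExperiment-class].
#' @param dir output directory (created if needed).
#' @export
writeMethylationDataset <- function(x, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(probeManifest(x), file.path(dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
    write_matrix_tsv(betaValues(x), file.path(dir, "beta.tsv"))
    write_matrix_tsv(detectionP(x), file.path(dir, "detection_p.tsv"))
    invisible(dir)
}

write_matrix_tsv <- function(m, file) {
    df <- data.frame(probe_id = rownames(m), m, check.names = FALSE)
    write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write region and probe reports
#'
#' `writeRegionReport()` emits the region table as TSV with 1-based
#' inclusive coordinates; `writeRegionsBed()` converts to BED6 (0-based
#' half-open, score = min(-10 * log10 P, 1000)); `writeProbeResults()` emits
#' the per-probe table with 1-based manifest coordinates. Coordinate
#' conventions are stated in a `#` header line of each file.
#'
#' @param regions a `GRanges` from [callRegions()].
#' @param file output path.
#' @export
writeRegionReport <- function(regions, file) {
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(regions)),
        start = GenomicRanges::start(regions),
        end = GenomicRanges::end(regions),
        k = regions$k, fisher_chi2 = regions$fisherChi2,
        df = regions$fisherDf, log10_p = regions$log10P,
        p_display = regions$pDisplay, mean_delta_m = regions$meanDeltaM,
        probe_ids = vapply(regions$probeIDs, paste, "", collapse = ","))
    con <- file(file, "wt")
    on.exit(close(con))
    writeLines("# soloMeth region calls; coordinates 1-based inclusive", con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname writeRegionReport
#' @export
writeRegionsBed <- function(regions, file) {
    score <- pmin(round(-10 * regions$log10P), 1000)
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(regions)),
        start = GenomicRanges::start(regions) - 1L,  # BED is 0-based
        end = GenomicRanges::end(regions),
        name = sprintf("region_%03d", seq_along(regions)),
        score = if (length(regions)) score else integer(0),
        strand = rep(".", length(regions)))
    con <- file(file, "wt")
    on.exit(close(con))
    writeLines("# soloMeth region calls; BED6, 0-based half-open", con)
    if (nrow(df))
        write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                    col.names = FALSE)
}

#' @rdname writeRegionReport
#' @param probeResults data.frame from [testProbes()].
#' @export
writeProbeResults <- function(probeResults, file) {
    con <- file(file, "wt")
    on.exit(close(con))
    writeLines("# soloMeth probe results; positions 1-based", con)
    write.table(probeResults, con, sep = "\t", quote = FALSE,
                row.names = FALSE)
}

#' Run the whole single-sample pipeline
#'
#' Reads (or accepts) a dataset, pre-processes it, tests every probe against
#' the controls, filters candidate hypomethylated hemimethylated CpGs, calls
#' regions with Fisher-combined P values, and writes `probes.tsv`,
#' `regions.tsv`, `regions.bed` and a plain-text `run.log` recording every
#' filter's removal counts, the effective control count, the thresholds and
#' the seed. Deterministic given identical inputs and configuration.
#'
#' @param x a [MethylationExperiment-class], or a list of paths
#'   (`manifest`, `beta`, `detectionP`) plus `case`/`controls`.
#' @param outputDir directory for the four output files.
#' @param method single-case test (default `"CH"`).
#' @param filter a [filterConfig()].
#' @param case,controls used when `x` is a list of paths.
#' @param seed recorded in the log; the analysis itself is deterministic.
#' @param ... passed to [preprocess()].
#' @return Invisibly, a list: `probes` (data.frame), `regions` (GRanges),
#'   `dataset` (the processed experiment), `log` (character).
#' @export
runPipeline <- function(x, outputDir, method = "CH",
                        filter = filterConfig(), case = NULL,
                        controls = "all-others", seed = NA_integer_, ...) {
    if (!is(x, "MethylationExperiment")) {
        x <- readMethylationDataset(x$manifest, x$beta, x$detectionP,
                                    case = case %||% x$case,
                                    controls = controls)
    }
    nIn <- nrow(x)
    x <- preprocess(x, ...)
    res <- testProbes(x, method = method)
    cand <- filterCandidates(res, filter)
    regions <- callRegions(cand, res, filter)

    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    writeProbeResults(res, file.path(outputDir, "probes.tsv"))
    writeRegionReport(regions, file.path(outputDir, "regions.tsv"))
    writeRegionsBed(regions, file.path(outputDir, "regions.bed"))

    pp <- S4Vectors::metadata(x)$preprocessing
    logLines <- c(
        sprintf("soloMeth run: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
        sprintf("seed: %s", seed),
        sprintf("method: %s", method),
        sprintf("case: %s", caseSample(x)),
        sprintf("controls (effective): %d", length(controlSamples(x))),
        sprintf("probes in: %d", nIn),
        vapply(pp, function(s) {
            sprintf("step %s: removed %s", s$step,
                    if (is.null(s$removed)) "0" else as.character(s$removed))
        }, ""),
        sprintf("probes tested: %d (untestable: %d)", nrow(res),
                sum(res$untestable)),
        sprintf("filter: p<%g%s, control M in [%g, %g], direction=%s",
                filter$pThreshold,
                if (filter$stringent)
                    sprintf(" (stringent: BH-FDR < %g)",
                            filter$stringentFdrThreshold) else "",
                filter$controlMLow, filter$controlMHigh, filter$direction),
        sprintf("candidate CpGs: %d", nrow(cand)),
        sprintf("regions called (k >= %d, gap <= %d nt): %d",
                filter$minProbes, filter$maxGapNt, length(regions)))
    writeLines(logLines, file.path(outputDir, "run.log"))
    invisible(list(probes = res, regions = regions, dataset = x,
                   log = logLines))
}

#' Read a pipeline run configuration
#'
#' A YAML document holding the paths, case/control design, method, filter
#' settings, preprocessing toggles, output directory and seed; unknown keys
#' are rejected so typos fail loudly. Used by the command-line interface
#' (`inst/scripts/soloMeth.R`); `runPipeline()` consumes the result.
#'
#' @param file path to a YAML config.
#' @return A named list with a `filter` element built by [filterConfig()].
#' @export
readRunConfig <- function(file) {
    cfg <- yaml::read_yaml(file)
    known <- c("manifest", "beta", "detectionP", "case", "controls",
               "method", "outputDir", "seed", "filter", "preprocess")
    bad <- setdiff(names(cfg), known)
    if (length(bad))
        stop("unknown config key(s): ", paste(bad, collapse = ", "))
    for (k in c("manifest", "beta", "detectionP", "case"))
        if (is.null(cfg[[k]])) stop("config key '", k, "' is required")
    cfg$controls <- cfg$controls %||% "all-others"
    cfg$method <- cfg$method %||% "CH"
    cfg$filter <- do.call(filterConfig, as.list(cfg$filter))
    cfg
}
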