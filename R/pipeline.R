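#' Read and validate a pipeline configuration
#'
#' Configurations are YAML with the following top-level keys:
#'
#' ```yaml
#' samples:                      # one entry per sequencing library
#'   - {id: glu_r1, condition: Glu, replicate: 1, bam: glu1.bam}
#'   - {id: glu_r2, condition: Glu, replicate: 2, bam: glu2.bam}
#' genome:
#'   chrom_sizes: genome.sizes   # two-column TSV
#'   tss: tss.tsv                # gene_id, chrom, tss_position, strand
#'   fasta: genome.fa            # optional, for peak sequences
#' gem_events:                   # optional, per condition
#'   Glu: glu.GEM_events.txt
#' params:
#'   tf_length_nt: 912           # or trim_length: 19
#'   min_mapq: 20
#'   min_snr: 2
#'   tss_distance: 1000
#'   bin_size: 1000
#' output_dir: results
#' seed: 1
#' ```
#'
#' All referenced paths are checked before any computation; thresholds
#' default to the standard pipeline values shown above.
#'
#' @param path YAML file path, or a list with the same structure.
#' @return A validated config list of class `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
    cfg <- if (is.character(path)) yaml::read_yaml(path) else path
    if (is.null(cfg$samples) || !length(cfg$samples))
        stop("config error: no samples declared")
    if (is.null(cfg$genome$chrom_sizes))
        stop("config error: genome$chrom_sizes is required")
    if (is.null(cfg$genome$tss))
        stop("config error: genome$tss is required")
    for (s in cfg$samples) {
        for (f in c("id", "condition", "bam"))
            if (is.null(s[[f]]))
                stop("config error: sample entry missing field '", f, "'")
        if (!file.exists(s$bam))
            stop("config error: BAM not found for sample ", s$id, ": ", s$bam)
    }
    for (f in c(cfg$genome$chrom_sizes, cfg$genome$tss, cfg$genome$fasta,
                unlist(cfg$gem_events)))
        if (!is.null(f) && !file.exists(f))
            stop("config error: file not found: ", f)
    p <- cfg$params
    defaults <- list(min_mapq = 20L, min_snr = 2, tss_distance = 1000L,
                     bin_size = 1000L, tss_flank = 1000L, peak_flank = 30L,
                     seq_width = 60L)
    for (nm in names(defaults)) if (is.null(p[[nm]])) p[[nm]] <- defaults[[nm]]
    if (is.null(p$trim_length)) {
        if (is.null(p$tf_length_nt) && is.null(p$tf_length_aa))
            stop("config error: give params$trim_length, tf_length_nt or tf_length_aa")
        len <- if (!is.null(p$tf_length_nt)) p$tf_length_nt else 3 * p$tf_length_aa
        p$trim_length <- tfFootprint(computeFootprint(len))
    }
    cfg$params <- p
    conds <- vapply(cfg$samples, `[[`, character(1), "condition")
    single <- names(which(table(conds) < 2))
    if (length(single))
        warning("condition(s) with a single replicate (correlation QC needs 2): ",
                paste(single, collapse = ", "))
    if (is.null(cfg$output_dir)) cfg$output_dir <- "exoPipe_results"
    if (is.null(cfg$seed)) cfg$seed <- 1L
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Run the full ChIP-exo downstream pipeline
#'
#' Executes, per sample: quality filter, PCR-duplicate removal, read_1
#' extraction, trimming to the footprint length, strand coverage, the
#' both-strand-overlap combination, and background normalization; then
#' merges replicates per condition, writes wiggle tracks, produces the
#' replicate-correlation and TSS meta-profile QC (figures plus the TSVs of
#' their plotted values), and — when GEM events are configured — the
#' SNR-filtered peak outputs (gene-target CSV, per-assignment CSV, BED,
#' peak sequences).  A provenance JSON records parameters, seeds and
#' per-stage read counts.
#'
#' @param config A [readPipelineConfig()] result, a YAML path, or a list.
#' @return Invisibly, the provenance list (also written to
#'   `output_dir/provenance.json`).
#' @export
runPipeline <- function(config) {
    if (!is(config, "PipelineConfig")) config <- readPipelineConfig(config)
    out <- config$output_dir
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    layout <- stage("layout", readChromSizes(config$genome$chrom_sizes))
    tss <- stage("tss", readTssTable(config$genome$tss, layout))
    p <- config$params
    counts <- list()
    read1ByS <- list(); profByS <- list()
    for (s in config$samples) {
        pr <- stage(paste0("read:", s$id),
                    readAlignedPairs(s$bam, layout))
        tly <- attr(pr, "tally")
        qf <- filterQuality(pr, p$min_mapq)
        dd <- deduplicate(qf)
        r1 <- extractRead1(dd$pairs)
        counts[[s$id]] <- list(pairs_in = unname(tly[["pairs_kept"]]),
                               dropped_unpaired = unname(tly[["dropped_unpaired"]]),
                               post_quality = length(qf),
                               duplicates_removed = dd$nDuplicatesRemoved,
                               post_dedup = length(dd$pairs))
        read1ByS[[s$id]] <- r1
        tr <- trimReads(r1, p$trim_length)
        cov <- coverageByStrand(tr, layout)
        prof <- backgroundNormalize(combineStrands(cov$plus, cov$minus, layout))
        profByS[[s$id]] <- prof
        stage(paste0("wig:", s$id),
              writeWig(prof, file.path(out, paste0(s$id, ".wig"))))
    }
    conds <- vapply(config$samples, `[[`, character(1), "condition")
    ids <- vapply(config$samples, `[[`, character(1), "id")
    merged <- list()
    for (cond in unique(conds)) {
        m <- mergeReplicates(profByS[ids[conds == cond]])
        merged[[cond]] <- m
        stage(paste0("wig:", cond),
              writeWig(m, file.path(out, paste0(cond, "_merged.wig"))))
    }
    # QC: replicate correlation over all samples, TSS profile per condition
    if (length(read1ByS) >= 2) {
        bins <- lapply(read1ByS, binReads, layout = layout,
                       binSize = p$bin_size)
        stage("qc:correlation",
              correlateSamples(bins,
                  plotFile = file.path(out, "sample_correlation.pdf"),
                  tsvFile = file.path(out, "sample_correlation.tsv")))
    }
    for (cond in names(merged))
        stage(paste0("qc:tss:", cond),
              tssMetaprofile(merged[[cond]], tss, flank = p$tss_flank,
                  tsvFile = file.path(out, paste0(cond, "_tss_profile.tsv")),
                  plotFile = file.path(out, paste0(cond, "_tss_profile.pdf"))))
    # peaks
    assignAll <- data.frame()
    if (!is.null(config$gem_events)) {
        for (cond in names(config$gem_events)) {
            pk <- stage(paste0("peaks:", cond),
                        parseGemEvents(config$gem_events[[cond]],
                                       condition = cond, layout = layout))
            pk <- snrFilter(pk, p$min_snr)
            stage(paste0("peaks:bed:", cond),
                  writePeaksBed(pk, file.path(out, paste0(cond, "_peaks.bed"))))
            asg <- assignPeaksToGenes(pk, tss, p$tss_distance)
            assignAll <- rbind(assignAll, asg)
            r1cond <- read1ByS[ids[conds == cond]]
            if (length(r1cond))
                stage(paste0("qc:peakshape:", cond),
                      peakShapeProfiles(do.call(c, unname(r1cond)), pk,
                          flank = p$peak_flank,
                          tsvFile = file.path(out, paste0(cond, "_peak_shape.tsv")),
                          plotFile = file.path(out, paste0(cond, "_peak_shape.pdf"))))
            if (!is.null(config$genome$fasta))
                stage(paste0("peaks:seq:", cond),
                      extractPeakSequences(pk, config$genome$fasta,
                          width = p$seq_width,
                          file = file.path(out, paste0(cond, "_peak_seqs.fasta"))))
        }
        buildGeneTargetTable(assignAll, tss,
                             conditions = names(config$gem_events),
                             file = file.path(out, "geneTargets.csv"))
        writeGemAnalysisFile(assignAll, file.path(out, "gemAnalysis.csv"))
    }
    prov <- list(package = "exoPipe",
                 version = as.character(utils::packageVersion("exoPipe")),
                 date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                 parameters = p, seed = config$seed,
                 samples = counts)
    jsonlite::write_json(prov, file.path(out, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(prov)
}
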