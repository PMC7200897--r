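#' 5' anchor points of reads
#'
#' Collapses stranded reads to their 1-bp 5' positions (the exonuclease
#' border on read_1).
#'
#' @param reads A stranded `GRanges`.
#' @return A width-1 `GRanges` at each read's 5' end.
#' @export
fivePrimeEnds <- function(reads) {
    resize(reads, width = 1L, fix = "start")
}

#' Bin read 5' ends over the genome
#'
#' Counts deduplicated read_1 5' ends in consecutive fixed-width genomic
#' bins (1 kb by default).  Binning reduces the genome to a manageable
#' number of variables and smooths positional noise, which is what makes
#' the replicate-correlation QC stable.
#'
#' @param read1s `GRanges` of read_1 spans (post-dedup, untrimmed).
#' @param layout Genome [GenomeInfoDb::Seqinfo].
#' @param binSize Bin width in bp (default 1000); the last bin of each
#'   chromosome may be shorter.
#' @return A `GRanges` of bins (chromosome order of `layout`) with a
#'   `count` metadata column.
#' @export
binReads <- function(read1s, layout, binSize = 1000L) {
    bins <- GenomicRanges::tileGenome(seqlengths(layout),
                                      tilewidth = binSize,
                                      cut.last.tile.in.chrom = TRUE)
    anchors <- fivePrimeEnds(read1s)
    strand(anchors) <- "*"
    mcols(bins)$count <- GenomicRanges::countOverlaps(bins, anchors)
    bins
}

#' Replicate correlation on log2 binned counts
#'
#' The first-line QC of a ChIP-exo experiment: bin every sample's reads
#' into 1-kb bins, drop bins with zero reads in *all* samples, transform
#' counts as `log2(count + 1)` (the pseudocount keeps bins that are zero in
#' only some samples finite) and compute pairwise Pearson correlations.
#' Replicates of a clean experiment correlate at r >= 0.85, good ones at
#' >= 0.9.
#'
#' @param samples A named list (>= 2) of binned samples from [binReads()]
#'   (identical layout and bin size), or a numeric matrix with one column
#'   per sample.
#' @param plotFile Optional path; if given, a PDF of all pairwise scatter
#'   plots annotated with their coefficient is written.
#' @param tsvFile Optional path for the correlation matrix as TSV.
#' @return A list: `correlation` (symmetric matrix, unit diagonal),
#'   `nBinsUsed`, and `log2Counts` (the filtered transformed matrix).
#' @export
correlateSamples <- function(samples, plotFile = NULL, tsvFile = NULL) {
    if (is.list(samples)) {
        if (length(samples) < 2L)
            stop("need at least 2 samples for correlation QC")
        nb <- vapply(samples, length, integer(1))
        if (length(unique(nb)) != 1L)
            stop("samples have differing bin grids")
        mat <- vapply(samples, function(b) mcols(b)$count, numeric(nb[[1]]))
        colnames(mat) <- if (!is.null(names(samples))) names(samples) else
            paste0("sample", seq_along(samples))
    } else mat <- as.matrix(samples)
    if (ncol(mat) < 2L) stop("need at least 2 samples for correlation QC")
    keep <- rowSums(mat) > 0
    if (sum(keep) < 3L)
        stop("fewer than 3 bins with reads; correlation is degenerate")
    lg <- log2(mat[keep, , drop = FALSE] + 1)
    cc <- stats::cor(lg, method = "pearson")
    if (!is.null(tsvFile))
        utils::write.table(data.frame(sample = rownames(cc), cc,
                                      check.names = FALSE),
                           tsvFile, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    if (!is.null(plotFile)) {
        grDevices::pdf(plotFile)
        on.exit(grDevices::dev.off(), add = TRUE)
        k <- ncol(lg)
        graphics::par(mfrow = c(k - 1, k - 1), mar = c(4, 4, 2, 1))
        for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
            graphics::plot(lg[, i], lg[, j], pch = ".", col = "#00000044",
                           xlab = colnames(lg)[i], ylab = colnames(lg)[j],
                           main = sprintf("r = %.3f", cc[i, j]))
        }
    }
    list(correlation = cc, nBinsUsed = sum(keep), log2Counts = lg)
}

#' Meta-profile of binding signal around TSSs
#'
#' Averages a normalized binding profile over windows centred on every
#' transcription start site, flipping minus-strand genes so upstream is
#' always to the left.  Window positions truncated at chromosome ends are
#' excluded per position (each relative position averages only the anchors
#' that cover it).  Since most factors bind upstream of the TSS, a clean
#' experiment shows a promoter-region enrichment peak left of the anchor.
#'
#' @param profile A normalized [BindingProfile-class].
#' @param tss A width-1 stranded `GRanges` of TSS positions (e.g. from
#'   [readTssTable()]).
#' @param flank Half-window size in bp (default 1000).
#' @param tsvFile,plotFile Optional output paths for the profile values
#'   (TSV: relative position, mean) and a line plot.
#' @return A list: `values` (numeric, length `2*flank+1`,
#'   fold-over-background; index `flank+1` is the TSS), `position`
#'   (relative coordinates), `nAnchors`.
#' @export
tssMetaprofile <- function(profile, tss, flank = 1000L, tsvFile = NULL,
                           plotFile = NULL) {
    if (!length(tss)) stop("empty TSS annotation")
    if (!isNormalized(profile))
        stop("profile must be normalized (fold-over-background)")
    flank <- as.integer(flank)
    w <- 2L * flank + 1L
    sums <- numeric(w)
    cnts <- numeric(w)
    sig <- profileSignal(profile)
    sl <- seqlengths(seqinfo(profile))
    for (ch in seqlevels(seqinfo(profile))) {
        sub <- tss[as.character(seqnames(tss)) == ch]
        if (!length(sub)) next
        v <- as.numeric(sig[[ch]])
        pos <- start(sub)
        minus <- as.character(strand(sub)) == "-"
        # genomic offsets; flipped for minus-strand genes
        offs <- -flank:flank
        for (k in seq_along(pos)) {
            g <- pos[k] + (if (minus[k]) -offs else offs)
            ok <- g >= 1L & g <= sl[[ch]]
            sums[ok] <- sums[ok] + v[g[ok]]
            cnts[ok] <- cnts[ok] + 1
        }
    }
    vals <- ifelse(cnts > 0, sums / cnts, NA_real_)
    rel <- -flank:flank
    if (!is.null(tsvFile))
        utils::write.table(data.frame(position = rel, mean = vals), tsvFile,
                           sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(plotFile)) {
        grDevices::pdf(plotFile, width = 7, height = 4)
        on.exit(grDevices::dev.off(), add = TRUE)
        graphics::plot(rel, vals, type = "l", xlab = "position relative to TSS (bp)",
                       ylab = "fold over background", main = "TSS meta-profile")
        graphics::abline(v = 0, lty = 2, col = "grey40")
    }
    list(values = vals, position = rel, nAnchors = length(tss))
}

#' Promoter-region enrichment of a profile
#'
#' Mean fold-over-background of a normalized profile over the upstream
#' window of every TSS (strand-aware; `window = c(-1000, -1)` is the 1-kb
#' promoter region).  Pure noise gives ~1; a clean ChIP-exo sample is
#' strongly enriched.
#'
#' @inheritParams tssMetaprofile
#' @param window Integer length-2 vector of relative positions (inclusive),
#'   negative = upstream.
#' @return A single number: mean fold-over-background over all in-bounds
#'   window positions.
#' @export
tssEnrichment <- function(profile, tss, window = c(-1000L, -1L)) {
    if (!length(tss)) stop("empty TSS annotation")
    sig <- profileSignal(profile)
    sl <- seqlengths(seqinfo(profile))
    tot <- 0; nbp <- 0
    for (ch in seqlevels(seqinfo(profile))) {
        sub <- tss[as.character(seqnames(tss)) == ch]
        if (!length(sub)) next
        pos <- start(sub)
        minus <- as.character(strand(sub)) == "-"
        st <- ifelse(minus, pos - window[2], pos + window[1])
        en <- ifelse(minus, pos - window[1], pos + window[2])
        st <- pmax(st, 1L); en <- pmin(en, sl[[ch]])
        ok <- en >= st
        if (!any(ok)) next
        vw <- Views(sig[[ch]], start = st[ok], end = en[ok])
        tot <- tot + sum(viewSums(vw))
        nbp <- nbp + sum(en[ok] - st[ok] + 1)
    }
    if (nbp == 0) stop("no in-bounds TSS window positions")
    tot / nbp
}

#' Read a TSS annotation table
#'
#' Reads a TSV/CSV with columns `gene_id`, `chrom`, `tss_position`
#' (1-based) and `strand`.
#'
#' @param path File path (delimiter inferred from the extension: `.csv`
#'   comma, otherwise tab).
#' @param layout Genome [GenomeInfoDb::Seqinfo].
#' @return A width-1 stranded `GRanges` with a `gene_id` column.
#' @export
readTssTable <- function(path, layout) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    tab <- utils::read.table(path, sep = sep, header = TRUE,
                             stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "tss_position", "strand")
    miss <- setdiff(need, names(tab))
    if (length(miss))
        stop("TSS table missing columns: ", paste(miss, collapse = ", "))
    if (anyDuplicated(tab$gene_id))
        stop("duplicate gene_id in TSS table")
    GRanges(tab$chrom, IRanges(tab$tss_position, width = 1L),
            strand = tab$strand, gene_id = tab$gene_id, seqinfo = layout)
}

#' Per-peak read distributions around peak centres
#'
#' For each called peak, counts read_1 5' ends at every relative position
#' in `[-flank, +flank]`, keeping the strands separate.  The per-peak rows
#' are the input of the peak-shape histogram; their column means give the
#' averaged border profile whose plus/minus maxima flank the centre at
#' about half the factor's footprint — the key visual check that trim
#' length and peak calling agree.
#'
#' @param read1s `GRanges` of read_1 spans (deduplicated, untrimmed).
#' @param peaks Width-1 `GRanges` of peak centres.
#' @param flank Half-window in bp (default 30).
#' @param plotFile,tsvFile Optional outputs: a two-panel PDF (per-peak
#'   lines, averaged profile) and a TSV of the averaged profiles.
#' @return A list: `plusMatrix`, `minusMatrix` (peaks x positions),
#'   `plusMean`, `minusMean`, `position`.
#' @export
peakShapeProfiles <- function(read1s, peaks, flank = 30L, plotFile = NULL,
                              tsvFile = NULL) {
    flank <- as.integer(flank)
    w <- 2L * flank + 1L
    np <- length(peaks)
    plusM <- matrix(0L, np, w)
    minusM <- matrix(0L, np, w)
    if (np && length(read1s)) {
        anchors <- fivePrimeEnds(read1s)
        win <- suppressWarnings(IRanges::trim(
            resize(granges(peaks), width = w, fix = "center")))
        hits <- GenomicRanges::findOverlaps(anchors, win, ignore.strand = TRUE)
        if (length(hits)) {
            q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
            rel <- start(anchors)[q] - start(granges(peaks))[s] + flank + 1L
            isPlus <- as.character(strand(anchors))[q] == "+"
            ok <- rel >= 1L & rel <= w
            for (strandSel in c(TRUE, FALSE)) {
                sel <- ok & (isPlus == strandSel)
                if (!any(sel)) next
                tab <- table(factor(s[sel], levels = seq_len(np)),
                             factor(rel[sel], levels = seq_len(w)))
                if (strandSel) plusM <- plusM + unclass(tab)
                else minusM <- minusM + unclass(tab)
            }
        }
    }
    rel <- -flank:flank
    res <- list(plusMatrix = plusM, minusMatrix = minusM,
                plusMean = colMeans(plusM), minusMean = colMeans(minusM),
                position = rel)
    if (!is.null(tsvFile))
        utils::write.table(data.frame(position = rel, plus = res$plusMean,
                                      minus = res$minusMean),
                           tsvFile, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    if (!is.null(plotFile)) {
        grDevices::pdf(plotFile, width = 7, height = 8)
        on.exit(grDevices::dev.off(), add = TRUE)
        graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
        ymax <- max(plusM, minusM, 1)
        graphics::matplot(rel, t(plusM), type = "l", lty = 1,
                          col = "#0000ff22", ylim = c(0, ymax),
                          xlab = "position relative to peak centre (bp)",
                          ylab = "read_1 5' ends", main = "per-peak profiles")
        graphics::matlines(rel, t(minusM), lty = 1, col = "#ff000022")
        graphics::plot(rel, res$plusMean, type = "l", col = "blue",
                       ylim = range(0, res$plusMean, res$minusMean),
                       xlab = "position relative to peak centre (bp)",
                       ylab = "mean read_1 5' ends", main = "averaged profile")
        graphics::lines(rel, res$minusMean, col = "red")
    }
    res
}
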