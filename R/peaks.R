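#' Parse a GEM events file into peaks
#'
#' Reads the tab-delimited "GEM events" output of the GEM peak caller
#' (header row; `Position` column formatted `chrom:coordinate`) and returns
#' the peaks with their IP and expected (control) strengths and the derived
#' signal-to-noise ratio.  GEM's historical header spelling `expectd` is
#' accepted alongside `expected` and `control`; when no expected column is
#' present, expected strength is recorded as 0 and flagged.
#'
#' The SNR of a peak is its measured IP strength divided by the expected
#' strength at that position, with a pseudocount guarding the denominator:
#' `snr = ip / max(expected, pseudocount)`.
#'
#' @param path Path to the GEM events file.
#' @param condition Condition label attached to every peak (default the
#'   file name without extension).
#' @param layout Optional [GenomeInfoDb::Seqinfo]; if supplied, peak
#'   chromosomes are validated against it.
#' @param pseudocount Denominator floor for the SNR (default 1).
#' @return A width-1 `GRanges` of peak centres (1-based, as printed by
#'   GEM) with metadata columns `ipStrength`, `expectedStrength`, `snr`,
#'   `qvalueNegLog` (NA when absent), `expectedMissing` and `condition`.
#' @export
parseGemEvents <- function(path, condition = NULL, layout = NULL,
                           pseudocount = 1) {
    if (is.null(condition))
        condition <- tools::file_path_sans_ext(basename(path))
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, check.names = TRUE,
                             comment.char = "")
    if (nrow(tab) == 0L) {
        gr <- GRanges()
        mcols(gr) <- DataFrame(ipStrength = numeric(), expectedStrength = numeric(),
                               snr = numeric(), qvalueNegLog = numeric(),
                               expectedMissing = logical(), condition = character())
        return(gr)
    }
    lcn <- tolower(names(tab))
    posCol <- which(lcn == "position")[1]
    if (is.na(posCol)) stop("GEM events file has no Position column: ", path)
    parts <- strsplit(as.character(tab[[posCol]]), ":", fixed = TRUE)
    bad <- which(lengths(parts) != 2L |
                 vapply(parts, function(p) is.na(suppressWarnings(
                     as.numeric(p[length(p)]))), logical(1)))
    if (length(bad))
        stop("unparseable Position field at data line ", bad[1], " of ", path)
    chrom <- vapply(parts, `[`, character(1), 1L)
    pos <- as.integer(vapply(parts, `[`, character(1), 2L))
    ipCol <- which(lcn == "ip")[1]
    if (is.na(ipCol)) stop("GEM events file has no IP column: ", path)
    expCol <- which(lcn %in% c("expectd", "expected", "control"))[1]
    expectedMissing <- is.na(expCol)
    expected <- if (expectedMissing) rep(0, nrow(tab)) else
        as.numeric(tab[[expCol]])
    if (expectedMissing)
        warning("no expected/control column in ", path,
                "; expected strength recorded as 0")
    qCol <- grep("^q[._-]", lcn)[1]
    qv <- if (is.na(qCol)) rep(NA_real_, nrow(tab)) else as.numeric(tab[[qCol]])
    ip <- as.numeric(tab[[ipCol]])
    gr <- GRanges(chrom, IRanges(pos, width = 1L))
    if (!is.null(layout)) {
        unknown <- setdiff(unique(chrom), seqlevels(layout))
        if (length(unknown))
            stop("peak chromosome not in layout: ",
                 paste(unknown, collapse = ", "))
        gr <- GRanges(chrom, IRanges(pos, width = 1L), seqinfo = layout)
    }
    mcols(gr) <- DataFrame(ipStrength = ip, expectedStrength = expected,
                           snr = ip / pmax(expected, pseudocount),
                           qvalueNegLog = qv,
                           expectedMissing = rep(expectedMissing, nrow(tab)),
                           condition = rep(condition, nrow(tab)))
    gr
}

#' Filter peaks on signal-to-noise ratio
#'
#' Retains peaks whose SNR (IP strength over expected strength) is
#' strictly above the threshold; peaks with SNR <= `minSnr` are removed.
#'
#' @param peaks Peak `GRanges` from [parseGemEvents()] (must carry `snr`).
#' @param minSnr SNR cutoff (default 2).
#' @return The retained peaks.
#' @export
snrFilter <- function(peaks, minSnr = 2) {
    if (!"snr" %in% colnames(mcols(peaks)))
        stop("peaks carry no snr column; parse them with parseGemEvents()")
    peaks[mcols(peaks)$snr > minSnr]
}

#' Assign peaks to genes by TSS distance
#'
#' A peak is assigned to every gene whose TSS lies strictly within
#' `maxDistance` bp of the peak centre, independent of whether the peak is
#' upstream or downstream; a peak close enough to two genes is assigned to
#' both, and a peak near no TSS yields no assignment.  The reported
#' distance is signed by gene orientation: negative = peak upstream of the
#' TSS.
#'
#' @param peaks Peak `GRanges` (width-1 centres, with `condition`,
#'   `ipStrength`, `snr` columns; typically post-[snrFilter()]).
#' @param tss Width-1 stranded TSS `GRanges` with `gene_id`.
#' @param maxDistance Strict distance bound in bp (default 1000).
#' @return A data.frame with one row per (peak, gene) assignment:
#'   `condition`, `chrom`, `position` (1-based peak centre), `ipStrength`,
#'   `snr`, `gene_id`, `distance`.
#' @export
assignPeaksToGenes <- function(peaks, tss, maxDistance = 1000L) {
    if (!length(peaks) || !length(tss))
        return(data.frame(condition = character(), chrom = character(),
                          position = integer(), ipStrength = numeric(),
                          snr = numeric(), gene_id = character(),
                          distance = integer()))
    win <- suppressWarnings(IRanges::trim(resize(granges(tss),
        width = 2L * maxDistance - 1L, fix = "center")))
    hits <- GenomicRanges::findOverlaps(granges(peaks), win,
                                        ignore.strand = TRUE)
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    dGenomic <- start(peaks)[q] - start(tss)[s]
    keep <- abs(dGenomic) < maxDistance
    q <- q[keep]; s <- s[keep]; dGenomic <- dGenomic[keep]
    minus <- as.character(strand(tss))[s] == "-"
    pk <- mcols(peaks)
    data.frame(condition = if ("condition" %in% colnames(pk))
                   pk$condition[q] else NA_character_,
               chrom = as.character(seqnames(peaks))[q],
               position = start(peaks)[q],
               ipStrength = if ("ipStrength" %in% colnames(pk))
                   pk$ipStrength[q] else NA_real_,
               snr = if ("snr" %in% colnames(pk)) pk$snr[q] else NA_real_,
               gene_id = mcols(tss)$gene_id[s],
               distance = as.integer(ifelse(minus, -dGenomic, dGenomic)))
}

#' Build the gene-target table
#'
#' The pipeline's principal text output: a genes x conditions matrix of
#' assigned-peak counts.  A gene is a target of the factor in a condition
#' iff its count there is >= 1.  Every gene of the TSS annotation appears
#' as a row, so absence of binding is explicit.
#'
#' @param assignments Assignment data.frame from [assignPeaksToGenes()]
#'   (possibly several conditions concatenated with `rbind`).
#' @param tss TSS `GRanges` defining the gene universe.
#' @param conditions Optional condition order; defaults to the order of
#'   appearance in `assignments`.
#' @param file Optional CSV output path (header `gene_id` + conditions).
#' @return A data.frame, first column `gene_id`, one integer column per
#'   condition.
#' @export
buildGeneTargetTable <- function(assignments, tss, conditions = NULL,
                                 file = NULL) {
    genes <- mcols(tss)$gene_id
    if (is.null(conditions))
        conditions <- unique(assignments$condition)
    if (!length(conditions)) conditions <- "all"
    tab <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
    for (cond in conditions) {
        sub <- assignments[assignments$condition %in% cond, , drop = FALSE]
        cnt <- table(factor(sub$gene_id, levels = genes))
        tab[[cond]] <- as.integer(cnt)
    }
    if (!is.null(file))
        utils::write.csv(tab, file, row.names = FALSE, quote = FALSE)
    tab
}

#' Write the per-peak assignment (GEM analysis) file
#'
#' One row per peak-gene assignment, listing the peak's condition,
#' position and strength together with the assigned gene and signed TSS
#' distance; a peak assigned to two genes appears on two rows.
#'
#' @param assignments Assignment data.frame from [assignPeaksToGenes()].
#' @param file CSV output path.
#' @return The assignments, invisibly.
#' @export
writeGemAnalysisFile <- function(assignments, file) {
    utils::write.csv(assignments, file, row.names = FALSE, quote = FALSE)
    invisible(assignments)
}

#' Write peaks as BED
#'
#' Six-column BED (0-based half-open) of peak centres with the SNR as
#' score, for genome-browser inspection.
#'
#' @param peaks Peak `GRanges`.
#' @param file Output path.
#' @export
writePeaksBed <- function(peaks, file) {
    df <- data.frame(chrom = as.character(seqnames(peaks)),
                     start = start(peaks) - 1L, end = start(peaks),
                     name = sprintf("peak%04d", seq_along(peaks)),
                     score = mcols(peaks)$snr, strand = ".")
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(file)
}

#' Extract sequences under peaks for motif discovery
#'
#' Pulls the genomic sequence centred on each peak (60 bp by default), the
#' standard input for a downstream MEME motif search.  Windows are clipped
#' at chromosome ends (with a warning).
#'
#' @param peaks Width-1 peak `GRanges`.
#' @param genome A [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param width Window width in bp (default 60).
#' @param file Optional FASTA output path.
#' @return A `DNAStringSet` named `chrom:start-end` (1-based).
#' @export
extractPeakSequences <- function(peaks, genome, width = 60L, file = NULL) {
    if (is.character(genome))
        genome <- Biostrings::readDNAStringSet(genome)
    nm <- sub("\\s.*$", "", names(genome))
    names(genome) <- nm
    chrom <- as.character(seqnames(peaks))
    unknown <- setdiff(unique(chrom), nm)
    if (length(unknown))
        stop("peak chromosome missing from FASTA: ",
             paste(unknown, collapse = ", "))
    half <- as.integer(width) %/% 2L
    st <- start(peaks) - half
    en <- st + as.integer(width) - 1L
    len <- Biostrings::width(genome)[match(chrom, nm)]
    clipped <- st < 1L | en > len
    if (any(clipped))
        warning(sum(clipped), " peak window(s) clipped at chromosome ends")
    st <- pmax(st, 1L); en <- pmin(en, len)
    seqs <- Biostrings::DNAStringSet(vapply(seq_along(st), function(i)
        as.character(Biostrings::subseq(genome[[chrom[i]]], st[i], en[i])),
        character(1)))
    names(seqs) <- sprintf("%s:%d-%d", chrom, st, en)
    if (!is.null(file)) Biostrings::writeXStringSet(seqs, file)
    seqs
}
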