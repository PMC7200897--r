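#' Read a chromosome-sizes table
#'
#' Reads a two-column TSV (`chrom<TAB>length`, no header) of the kind
#' emitted by `samtools faidx` / UCSC `fetchChromSizes`.
#'
#' @param path Path to the chrom.sizes file.
#' @return A [GenomeInfoDb::Seqinfo] with one entry per chromosome, in file
#'   order.
#' @export
readChromSizes <- function(path) {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             col.names = c("chrom", "length"),
                             colClasses = c("character", "integer"))
    if (any(tab$length <= 0L))
        stop("chromosome lengths must be positive in ", path)
    Seqinfo(seqnames = tab$chrom, seqlengths = tab$length)
}

#' Import properly paired alignments from SAM/BAM
#'
#' Ingests a coordinate- or name-sorted SAM/BAM of paired-end alignments and
#' returns one [ExoPairs-class] record per properly paired fragment.  Only
#' primary, properly paired records are used; secondary, supplementary and
#' unpaired/discordant records are dropped and counted.  The pair-level
#' mapping quality is the minimum over the two mates.
#'
#' @param path Path to a SAM or BAM file.
#' @param layout A [GenomeInfoDb::Seqinfo] giving the expected chromosomes
#'   and lengths.
#' @return An [ExoPairs-class] object; `metadata()`-style drop tally is
#'   attached as attribute `tally`, a named integer vector with elements
#'   `pairs_kept`, `dropped_unpaired`, `dropped_secondary`.
#' @examples
#' \dontrun{pairs <- readAlignedPairs("sample.bam", readChromSizes("g.sizes"))}
#' @export
readAlignedPairs <- function(path, layout) {
    if (!file.exists(path)) stop("alignment file not found: ", path)
    bam <- path
    if (grepl("\\.sam$", path, ignore.case = TRUE))
        bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                                indexDestination = FALSE)
    what <- c("qname", "flag", "rname", "strand", "pos", "qwidth", "mapq")
    res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(what = what))[[1]]
    flag <- res$flag
    n <- length(flag)
    if (n == 0L) {
        empty <- GRanges(seqinfo = layout)
        out <- ExoPairs(empty)
        attr(out, "tally") <- c(pairs_kept = 0L, dropped_unpaired = 0L,
                                dropped_secondary = 0L)
        return(out)
    }
    secondary <- bitwAnd(flag, 0x100L) != 0L | bitwAnd(flag, 0x800L) != 0L
    proper <- bitwAnd(flag, 0x1L) != 0L & bitwAnd(flag, 0x2L) != 0L &
        bitwAnd(flag, 0x4L) == 0L & bitwAnd(flag, 0x8L) == 0L
    keep <- !secondary & proper
    first <- bitwAnd(flag, 0x40L) != 0L
    r1 <- which(keep & first)
    r2 <- which(keep & !first)
    m <- match(res$qname[r1], res$qname[r2])
    paired1 <- r1[!is.na(m)]
    paired2 <- r2[m[!is.na(m)]]
    nOrphan <- sum(is.na(m)) + (length(r2) - sum(!is.na(m)))
    chroms <- as.character(res$rname[paired1])
    unknown <- setdiff(unique(chroms), seqlevels(layout))
    if (length(unknown))
        stop("chromosome not in layout: ", paste(unknown, collapse = ", "))
    s1 <- as.character(res$strand[paired1])
    start1 <- res$pos[paired1]
    end1 <- start1 + res$qwidth[paired1] - 1L
    s2minus <- as.character(res$strand[paired2]) == "-"
    r2five <- ifelse(s2minus, res$pos[paired2] + res$qwidth[paired2] - 1L,
                     res$pos[paired2])
    mapq <- pmin(res$mapq[paired1], res$mapq[paired2], na.rm = TRUE)
    gr <- GRanges(chroms, IRanges(start1, end1), strand = s1, seqinfo = layout)
    names(gr) <- res$qname[paired1]
    out <- ExoPairs(gr, mapq = mapq, r2five = as.integer(r2five))
    nDropUnpaired <- sum(!proper & !secondary) + nOrphan
    attr(out, "tally") <- c(pairs_kept = length(gr),
                            dropped_unpaired = as.integer(nDropUnpaired),
                            dropped_secondary = as.integer(sum(secondary)))
    out
}

#' Write fragment pairs to BAM
#'
#' Serializes an [ExoPairs-class] object back to a coordinate-sorted,
#' indexed BAM with standard FR flags (99/147 for plus-strand read_1,
#' 83/163 for minus).  Mates are written with the read_1 length; base and
#' quality strings are omitted (`*`), as downstream analysis uses positions
#' only.
#'
#' @param pairs An `ExoPairs` object.
#' @param path Output path; `".bam"` is appended if absent.
#' @return The BAM path, invisibly.
#' @export
writePairsBam <- function(pairs, path) {
    gr <- pairRanges(pairs)
    si <- seqinfo(gr)
    hdr <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", seqlevels(si),
                     unname(seqlengths(si))))
    sam <- tempfile(fileext = ".sam")
    con <- file(sam, "w")
    on.exit(close(con), add = TRUE)
    writeLines(hdr, con)
    if (length(gr)) {
        w <- width(gr)
        plus1 <- as.character(strand(gr)) == "+"
        qn <- names(gr)
        if (is.null(qn)) qn <- sprintf("frag%07d", seq_along(gr))
        r2f <- r2FivePrime(pairs)
        mq <- pairMapq(pairs)
        chr <- as.character(seqnames(gr))
        # leftmost coordinate of each mate; read_2 takes read_1's length
        pos1 <- start(gr)
        pos2 <- ifelse(plus1, r2f - w + 1L, r2f)
        cig <- paste0(w, "M")
        tlen <- ifelse(plus1, r2f - pos1 + 1L, -(end(gr) - pos2 + 1L))
        l1 <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t%d\t*\t*",
                      qn, ifelse(plus1, 99L, 83L), chr, pos1, mq, cig,
                      pos2, tlen)
        l2 <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t%d\t*\t*",
                      qn, ifelse(plus1, 147L, 163L), chr, pos2, mq, cig,
                      pos1, -tlen)
        writeLines(c(l1, l2), con)
    }
    close(con)
    on.exit()
    dest <- sub("\\.bam$", "", path)
    bam <- Rsamtools::asBam(sam, dest, overwrite = TRUE)
    invisible(bam)
}

#' Filter fragment pairs on mapping quality
#'
#' Removes low-quality alignments before duplicate marking.
#'
#' @param pairs An [ExoPairs-class] object.
#' @param minMapq Minimum pair-level mapping quality retained
#'   (default 20; pairs with `mapq < minMapq` are dropped).
#' @return The retained `ExoPairs`.
#' @export
filterQuality <- function(pairs, minMapq = 20L) {
    pairs[pairMapq(pairs) >= minMapq]
}

#' Remove PCR duplicates
#'
#' PCR duplicates are read pairs with an identical read_1 *and* an identical
#' read_2.  Because the exonuclease pins read_1's 5' end to the binding-site
#' border, many genuine fragments share a read_1 position; read_2 positions
#' come from random sonication breaks, so fragments agreeing on *both* mates
#' are amplification copies.  The key is
#' `(chrom, read_1 strand, read_1 5', read_2 5')`; the first pair of each
#' group (input order) survives and input order is preserved, so the
#' operation is idempotent.
#'
#' @param pairs An [ExoPairs-class] object (quality-filtered).
#' @return A list with elements `pairs` (the deduplicated `ExoPairs`) and
#'   `nDuplicatesRemoved`.
#' @export
deduplicate <- function(pairs) {
    gr <- pairRanges(pairs)
    key <- data.frame(chrom = as.character(seqnames(gr)),
                      strand = as.character(strand(gr)),
                      r1five = r1FivePrime(pairs),
                      r2five = r2FivePrime(pairs))
    dup <- duplicated(key)
    list(pairs = pairs[!dup], nDuplicatesRemoved = sum(dup))
}

#' Extract read_1 records
#'
#' After deduplication only read_1 carries positional information (its 5'
#' end is the exonuclease border); this drops the mate and returns the
#' read_1 alignment spans.
#'
#' @param pairs An [ExoPairs-class] object (deduplicated).
#' @return A `GRanges` of read_1 spans, one per pair, in input order.
#' @export
extractRead1 <- function(pairs) {
    gr <- granges(pairRanges(pairs))
    gr
}

#' Trim reads to the footprint length
#'
#' Re-anchors every read_1 at its 5' end and extends it `trimLength` bases
#' in the read direction, so that border reads from the two strands overlap
#' across the binding site.  Reads running past a chromosome end are clipped
#' (not dropped), preserving signal near telomeres.
#'
#' @param read1s A stranded `GRanges` of read_1 spans (from
#'   [extractRead1()]), with seqlengths set.
#' @param trimLength Trim length in bp (usually [computeFootprint()]'s
#'   result); must be >= 1.
#' @return A `GRanges` of trimmed reads, same length and order as the input.
#' @export
trimReads <- function(read1s, trimLength) {
    trimLength <- as.integer(trimLength)
    if (is.na(trimLength) || trimLength < 1L)
        stop("trimLength must be a positive integer")
    # resize may transiently run past a chromosome end; trim() clips it back
    out <- suppressWarnings(resize(read1s, width = trimLength, fix = "start"))
    suppressWarnings(IRanges::trim(out))
}
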