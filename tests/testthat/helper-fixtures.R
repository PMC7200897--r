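suppressPackageStartupMessages({
    library(GenomicRanges)
    library(GenomeInfoDb)
    library(IRanges)
    library(S4Vectors)
})

# small genomes used across tests
tinyLayout <- function(lens = c(chrA = 10000L, chrB = 8000L)) {
    Seqinfo(seqnames = names(lens), seqlengths = unname(lens))
}

# hand-build an ExoPairs from parallel vectors of read_1 5' ends
makePairs <- function(layout, chrom, strand, r1five, r2five, mapq = 42L,
                      readLen = 5L) {
    n <- length(r1five)
    strand <- rep_len(strand, n); chrom <- rep_len(chrom, n)
    mapq <- rep_len(mapq, n)
    start <- ifelse(strand == "+", r1five, r1five - readLen + 1L)
    gr <- GRanges(chrom, IRanges(as.integer(start), width = readLen),
                  strand = strand, seqinfo = layout)
    ExoPairs(gr, mapq = as.integer(mapq), r2five = as.integer(r2five))
}

# random pair multiset on a small genome, with duplicates likely
randomPairs <- function(n, layout = tinyLayout(), seed = 1L, readLen = 5L,
                        posRange = 200L) {
    set.seed(seed)
    chrom <- sample(seqlevels(layout), n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    r1 <- sample(seq(readLen + 1L, readLen + posRange), n, replace = TRUE)
    r2 <- r1 + sample(50:80, n, replace = TRUE)
    makePairs(layout, chrom, strand, r1, r2, readLen = readLen)
}

# O(n^2) duplicate-marking oracle: pair i is a duplicate iff some j < i has
# an identical (chrom, strand, r1five, r2five) key
oracleDedupKeep <- function(pairs) {
    gr <- pairRanges(pairs)
    ch <- as.character(seqnames(gr)); st <- as.character(strand(gr))
    f1 <- r1FivePrime(pairs); f2 <- r2FivePrime(pairs)
    n <- length(gr)
    keep <- logical(n)
    for (i in seq_len(n)) {
        isdup <- FALSE
        for (j in seq_len(i - 1L)) {
            if (ch[i] == ch[j] && st[i] == st[j] &&
                f1[i] == f1[j] && f2[i] == f2[j]) { isdup <- TRUE; break }
        }
        keep[i] <- !isdup
    }
    keep
}

# per-base membership-count coverage oracle on one chromosome
oracleCoverage <- function(starts, ends, chromLen) {
    v <- integer(chromLen)
    for (k in seq_along(starts))
        for (p in seq(max(1L, starts[k]), min(chromLen, ends[k])))
            v[p] <- v[p] + 1L
    v
}

# all-pairs peak-to-TSS assignment oracle (strict |d| < maxDist)
oracleAssign <- function(peakChrom, peakPos, tssChrom, tssPos, tssStrand,
                         maxDist = 1000L) {
    out <- data.frame(peak = integer(), gene = integer(), distance = integer())
    for (i in seq_along(peakPos)) for (j in seq_along(tssPos)) {
        if (peakChrom[i] != tssChrom[j]) next
        d <- peakPos[i] - tssPos[j]
        if (abs(d) < maxDist) {
            if (tssStrand[j] == "-") d <- -d
            out <- rbind(out, data.frame(peak = i, gene = j, distance = d))
        }
    }
    out
}

# signature of a pair multiset, independent of order
pairKeys <- function(pairs) {
    gr <- pairRanges(pairs)
    sort(paste(seqnames(gr), strand(gr), r1FivePrime(pairs),
               r2FivePrime(pairs)))
}

# a small GEM events fixture; returns path and the data frame written
writeGemFixture <- function(path, n = 10L, seed = 7L) {
    set.seed(seed)
    df <- data.frame(
        Position = sprintf("chr%s:%d", sample(c("A", "B"), n, TRUE),
                           sample(1000:9000, n)),
        IP = round(runif(n, 5, 120), 1),
        Fold = round(runif(n, 1, 20), 1),
        expectd = round(runif(n, 0, 30), 1),
        Q_.lg10 = round(runif(n, 2, 40), 2))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    df
}
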