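test_that("read binning assigns 5' ends to 1-kb bins and conserves counts", {
    lay <- Seqinfo("chrT", 3500L)
    r1 <- GRanges("chrT", IRanges(c(1, 1000, 1001), width = 10),
                  strand = "+", seqinfo = lay)
    b <- binReads(r1, lay, 1000L)
    expect_equal(width(b), c(1000L, 1000L, 1000L, 500L))  # short last bin
    expect_equal(mcols(b)$count, c(2L, 1L, 0L, 0L))
    # minus-strand read binned by its 5' end (the alignment end)
    rm1 <- GRanges("chrT", IRanges(995, 1004), strand = "-", seqinfo = lay)
    expect_equal(mcols(binReads(rm1, lay, 1000L))$count, c(0L, 1L, 0L, 0L))
    # empty input -> all-zero counts
    expect_equal(sum(mcols(binReads(GRanges(seqinfo = lay), lay))$count), 0L)
    # conservation on a simulated sample
    lay2 <- tinyLayout()
    sim <- simulateSignal(simConfig(layout = lay2,
        tss = toyTss(lay2, 1500, margin = 1000), nSites = 4L,
        readsPerSite = 50L, seed = 8L))
    r <- extractRead1(sim$pairs)
    expect_equal(sum(mcols(binReads(r, lay2))$count), length(r))
})

test_that("sample correlation is 1 against itself and ~0 for independent noise", {
    lay <- toyLayout(4, 500000)  # 2 Mb toy genome
    n1 <- extractRead1(simulateNoise(20000, lay, seed = 1))
    n2 <- extractRead1(simulateNoise(20000, lay, seed = 2))
    b1 <- binReads(n1, lay); b2 <- binReads(n2, lay)
    same <- correlateSamples(list(a = b1, b = b1))
    expect_equal(unname(same$correlation["a", "b"]), 1, tolerance = 1e-12)
    indep <- correlateSamples(list(a = b1, b = b2))
    expect_lt(abs(indep$correlation["a", "b"]), 0.08)
    expect_true(isSymmetric(indep$correlation))
    expect_equal(unname(diag(indep$correlation)), c(1, 1))
    expect_error(correlateSamples(list(a = b1)), "at least 2")
})

test_that("all-zero bins are removed and the log2 pseudocount is applied", {
    m <- cbind(a = c(0, 4, 0, 8), b = c(0, 2, 1, 6))
    res <- correlateSamples(m)
    expect_equal(res$nBinsUsed, 3L)  # bin 1 zero in all samples
    expect_equal(unname(res$log2Counts[, "a"]), log2(c(4, 0, 8) + 1))
    expect_equal(unname(res$correlation["a", "b"]),
                 cor(log2(c(4, 0, 8) + 1), log2(c(2, 1, 6) + 1)))
})

test_that("TSS meta-profile is flat on uniform signal and peaks where planted", {
    lay <- Seqinfo("chrT", 50000L)
    flat <- new("BindingProfile",
                signal = RleList(chrT = Rle(1, 50000), compress = FALSE),
                seqinfo = lay, backgroundMean = 1, normalized = TRUE)
    tss <- GRanges("chrT", IRanges(c(10000, 30000), width = 1),
                   strand = c("+", "-"), gene_id = c("g1", "g2"),
                   seqinfo = lay)
    mp <- tssMetaprofile(flat, tss, flank = 500L)
    expect_equal(mp$values, rep(1, 1001))
    expect_equal(mp$nAnchors, 2L)
    # planted upstream signal at -200 appears at index flank - 200
    v <- numeric(50000); v[10000 - 200] <- 60
    planted <- new("BindingProfile",
                   signal = RleList(chrT = Rle(v), compress = FALSE),
                   seqinfo = lay, backgroundMean = 1, normalized = TRUE)
    mp2 <- tssMetaprofile(planted, tss[1], flank = 500L)
    expect_equal(which.max(mp2$values), 500L + 1L - 200L)
    expect_error(tssMetaprofile(flat, tss[0]), "empty")
})

test_that("meta-profile of a mirrored, strand-flipped genome is the reverse", {
    L <- 20000L
    lay <- Seqinfo("chrT", L)
    set.seed(21)
    v <- numeric(L); idx <- sample(2000:18000, 200)
    v[idx] <- runif(200, 0, 12)
    tssPos <- c(5000L, 9000L, 15000L)
    fwd <- new("BindingProfile", signal = RleList(chrT = Rle(v), compress = FALSE),
               seqinfo = lay, backgroundMean = 1, normalized = TRUE)
    tssF <- GRanges("chrT", IRanges(tssPos, width = 1), strand = "+",
                    gene_id = paste0("g", 1:3), seqinfo = lay)
    rev <- new("BindingProfile",
               signal = RleList(chrT = Rle(base::rev(v)), compress = FALSE),
               seqinfo = lay, backgroundMean = 1, normalized = TRUE)
    tssR <- GRanges("chrT", IRanges(L + 1L - tssPos, width = 1), strand = "-",
                    gene_id = paste0("g", 1:3), seqinfo = lay)
    a <- tssMetaprofile(fwd, tssF, flank = 300L)
    b <- tssMetaprofile(rev, tssR, flank = 300L)
    expect_equal(b$values, a$values)
})

test_that("promoter enrichment is strand-aware and ~1 on flat signal", {
    lay <- Seqinfo("chrT", 30000L)
    flat <- new("BindingProfile",
                signal = RleList(chrT = Rle(1, 30000), compress = FALSE),
                seqinfo = lay, backgroundMean = 1, normalized = TRUE)
    tss <- GRanges("chrT", IRanges(c(10000, 20000), width = 1),
                   strand = c("+", "-"), gene_id = c("g1", "g2"),
                   seqinfo = lay)
    expect_equal(tssEnrichment(flat, tss), 1)
    # signal only upstream of the minus-strand gene (genomic right)
    v <- numeric(30000); v[20001:21000] <- 5
    p <- new("BindingProfile", signal = RleList(chrT = Rle(v), compress = FALSE),
             seqinfo = lay, backgroundMean = 1, normalized = TRUE)
    upOnly <- tssEnrichment(p, tss[2])
    expect_equal(upOnly, 5)
    expect_equal(tssEnrichment(p, tss[1]), 0)  # not upstream of the + gene
})

test_that("peak-shape profiles count 5' ends at signed offsets by strand", {
    lay <- Seqinfo("chrT", 10000L)
    peaks <- GRanges("chrT", IRanges(501, width = 1), seqinfo = lay)
    # five plus reads with 5' at 489 -> relative position -12
    r1 <- GRanges("chrT", IRanges(rep(489, 5), width = 20), strand = "+",
                  seqinfo = lay)
    ps <- peakShapeProfiles(r1, peaks, flank = 30L)
    expect_equal(ps$plusMatrix[1, which(ps$position == -12)], 5L)
    expect_equal(sum(ps$plusMatrix), 5L)
    expect_equal(sum(ps$minusMatrix), 0L)
    # minus-strand read 5' (alignment end) at +7
    rm1 <- GRanges("chrT", IRanges(489, 508), strand = "-", seqinfo = lay)
    ps2 <- peakShapeProfiles(rm1, peaks, flank = 30L)
    expect_equal(ps2$minusMatrix[1, which(ps2$position == 7)], 1L)
    # no reads near peaks -> zero matrices
    far <- GRanges("chrT", IRanges(5000, width = 20), strand = "+",
                   seqinfo = lay)
    expect_equal(sum(peakShapeProfiles(far, peaks, 30L)$plusMatrix), 0L)
})

test_that("averaged peak shape recovers the planted border offsets", {
    cfg <- simConfig(nSites = 60L, readsPerSite = 80L, borderJitterSd = 1.5,
                     layout = toyLayout(2, 200000),
                     tss = toyTss(toyLayout(2, 200000), 2000), seed = 12L)
    sim <- simulateSignal(cfg)
    dd <- deduplicate(filterQuality(sim$pairs))
    r1 <- extractRead1(dd$pairs)
    centers <- GRanges(sim$truth$sites$chrom,
                       IRanges(sim$truth$sites$center, width = 1),
                       seqinfo = cfg$layout)
    ps <- peakShapeProfiles(r1, centers, flank = 30L)
    b <- sim$truth$sites$borderOffset[1]  # floor(19/2) = 9
    expect_equal(b, 9L)
    expect_lte(abs(ps$position[which.max(ps$plusMean)] - (-b)), 2L)
    expect_lte(abs(ps$position[which.max(ps$minusMean)] - b), 2L)
})

test_that("TSS table reader validates columns and builds stranded anchors", {
    lay <- tinyLayout()
    f <- tempfile(fileext = ".tsv")
    writeLines(c("gene_id\tchrom\ttss_position\tstrand",
                 "g1\tchrA\t1200\t+", "g2\tchrB\t800\t-"), f)
    tss <- readTssTable(f, lay)
    expect_equal(mcols(tss)$gene_id, c("g1", "g2"))
    expect_equal(start(tss), c(1200L, 800L))
    expect_equal(as.character(strand(tss)), c("+", "-"))
    bad <- tempfile(fileext = ".tsv")
    writeLines(c("gene\tchrom\tpos\tstrand", "g1\tchrA\t1200\t+"), bad)
    expect_error(readTssTable(bad, lay), "missing columns")
    dup <- tempfile(fileext = ".tsv")
    writeLines(c("gene_id\tchrom\ttss_position\tstrand",
                 "g1\tchrA\t1200\t+", "g1\tchrA\t1300\t+"), dup)
    expect_error(readTssTable(dup, lay), "duplicate")
})
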