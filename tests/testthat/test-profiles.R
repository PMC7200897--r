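test_that("strand coverage counts per-base read membership", {
    lay <- Seqinfo("chrT", 200L)
    tr <- GRanges("chrT", IRanges(c(101, 111), width = 19),
                  strand = c("+", "+"), seqinfo = lay)
    cov <- coverageByStrand(tr, lay)
    v <- as.integer(cov$plus[["chrT"]])
    expect_equal(sum(v), 2L * 19L)
    expect_true(all(v[111:119] == 2L))
    expect_true(all(v[101:110] == 1L))
    expect_true(all(as.integer(cov$minus[["chrT"]]) == 0L))
})

test_that("strand coverage equals the brute-force per-base oracle", {
    lay <- Seqinfo("chrT", 10000L)
    for (seed in c(4, 8)) {
        set.seed(seed)
        n <- 1000
        st <- sample(c("+", "-"), n, replace = TRUE)
        five <- sample(30:9970, n, replace = TRUE)
        r1 <- GRanges("chrT",
                      IRanges(ifelse(st == "+", five, five - 18L), width = 19),
                      strand = st, seqinfo = lay)
        cov <- coverageByStrand(r1, lay)
        for (s in c("+", "-")) {
            sel <- st == s
            want <- oracleCoverage(start(r1)[sel], end(r1)[sel], 10000L)
            got <- as.integer((if (s == "+") cov$plus else cov$minus)[["chrT"]])
            expect_identical(got, want)
        }
    }
})

test_that("both-strand-overlap combination zeroes single-strand positions", {
    lay <- Seqinfo("chrT", 3L)
    f <- RleList(chrT = Rle(c(0, 2, 3)), compress = FALSE)
    r <- RleList(chrT = Rle(c(1, 0, 3)), compress = FALSE)
    prof <- combineStrands(f, r, lay)
    expect_equal(as.numeric(profileSignal(prof)[["chrT"]]), c(0, 0, 6))
    expect_false(isNormalized(prof))
    # alternative combination operators
    expect_equal(as.numeric(profileSignal(
        combineStrands(f, r, lay, combine = "min"))[["chrT"]]), c(0, 0, 3))
    expect_equal(as.numeric(profileSignal(
        combineStrands(f, r, lay, combine = "mean"))[["chrT"]]), c(0, 0, 3))
    # all-zero forward strand -> all-zero profile
    z <- RleList(chrT = Rle(0, 3), compress = FALSE)
    expect_equal(sum(as.numeric(profileSignal(
        combineStrands(z, r, lay))[["chrT"]])), 0)
    expect_error(combineStrands(f, RleList(chrX = Rle(0, 3), compress = FALSE),
                                lay), "layout")
})

test_that("combined profile is bounded by the strand sum and their support", {
    lay <- Seqinfo("chrT", 500L)
    set.seed(2)
    mk <- function() {
        st <- sample(c("+", "-"), 80, replace = TRUE)
        five <- sample(20:480, 80, replace = TRUE)
        GRanges("chrT", IRanges(ifelse(st == "+", five, five - 10L),
                                width = 11), strand = st, seqinfo = lay)
    }
    tr <- mk()
    cov <- coverageByStrand(tr, lay)
    prof <- combineStrands(cov$plus, cov$minus, lay)
    v <- as.numeric(profileSignal(prof)[["chrT"]])
    f <- as.numeric(cov$plus[["chrT"]]); r <- as.numeric(cov$minus[["chrT"]])
    expect_true(all(v <= f + r))
    expect_true(all(v[f == 0] == 0))
    expect_true(all(v[r == 0] == 0))
    expect_true(all(v[f > 0 & r > 0] == (f + r)[f > 0 & r > 0]))
})

test_that("background normalization scales to genome-wide mean 1", {
    lay <- Seqinfo("chrT", 100L)
    mkProf <- function(vals)
        combineStrands(RleList(chrT = Rle(vals), compress = FALSE),
                       RleList(chrT = Rle(rep(1, 100)), compress = FALSE), lay)
    p <- mkProf(c(rep(0, 90), rep(40, 10)))
    np <- backgroundNormalize(p)
    expect_true(isNormalized(np))
    expect_equal(mean(as.numeric(profileSignal(np)[["chrT"]])), 1, tolerance = 1e-9)
    expect_equal(backgroundMean(np), mean(c(rep(0, 90), rep(41, 10))))
    expect_error(backgroundNormalize(np), "already")
    # degenerate all-zero profile: unchanged, with a warning
    z <- combineStrands(RleList(chrT = Rle(0, 100), compress = FALSE),
                        RleList(chrT = Rle(0, 100), compress = FALSE), lay)
    expect_warning(nz <- backgroundNormalize(z), "no signal")
    expect_equal(sum(as.numeric(profileSignal(nz)[["chrT"]])), 0)
})

test_that("normalization is exactly scale invariant on raw signal", {
    lay <- Seqinfo("chrT", 60L)
    vals <- c(rep(0, 40), runif(20, 0, 9))
    mk <- function(v) new("BindingProfile",
                          signal = RleList(chrT = Rle(v), compress = FALSE),
                          seqinfo = lay, backgroundMean = NA_real_,
                          normalized = FALSE)
    a <- backgroundNormalize(mk(vals))
    b <- backgroundNormalize(mk(vals * 7.3))
    expect_equal(as.numeric(profileSignal(a)[["chrT"]]),
                 as.numeric(profileSignal(b)[["chrT"]]), tolerance = 1e-12)
})

test_that("replicate merging averages per base and ignores argument order", {
    lay <- Seqinfo("chrT", 3L)
    mk <- function(v) new("BindingProfile",
                          signal = RleList(chrT = Rle(v), compress = FALSE),
                          seqinfo = lay, backgroundMean = 1,
                          normalized = TRUE)
    a <- mk(c(0, 2, 4)); b <- mk(c(2, 2, 0))
    m <- mergeReplicates(list(a, b))
    expect_equal(as.numeric(profileSignal(m)[["chrT"]]), c(1, 2, 2))
    m2 <- mergeReplicates(list(b, a))
    expect_equal(as.numeric(profileSignal(m2)[["chrT"]]),
                 as.numeric(profileSignal(m)[["chrT"]]))
    # single replicate and k identical replicates are identities
    expect_equal(as.numeric(profileSignal(mergeReplicates(list(a)))[["chrT"]]),
                 c(0, 2, 4))
    expect_equal(as.numeric(profileSignal(
        mergeReplicates(list(a, a, a)))[["chrT"]]), c(0, 2, 4))
    # refuses unnormalized input
    raw <- new("BindingProfile", signal = RleList(chrT = Rle(c(0, 1, 2)),
                                                  compress = FALSE),
               seqinfo = lay, backgroundMean = NA_real_, normalized = FALSE)
    expect_error(mergeReplicates(list(a, raw)), "normalized")
})

test_that("wiggle round-trip preserves nonzero values at 1-based positions", {
    lay <- Seqinfo("chrT", 500L)
    v <- numeric(500); v[c(102, 103, 200, 499)] <- c(2.5, 1 / 3, 7, 0.125)
    p <- new("BindingProfile", signal = RleList(chrT = Rle(v), compress = FALSE),
             seqinfo = lay, backgroundMean = 1, normalized = TRUE)
    wig <- tempfile(fileext = ".wig")
    writeWig(p, wig)
    lines <- readLines(wig)
    expect_true(any(grepl("variableStep", lines)))
    expect_true(any(grepl("^102\\s", lines)))   # 1-based position
    expect_false(any(grepl("^101\\s", lines)))  # zero positions omitted
    p2 <- readWig(wig, lay)
    expect_equal(as.numeric(profileSignal(p2)[["chrT"]]), v, tolerance = 1e-6)

    # random sparse profile round-trip
    set.seed(9)
    v2 <- numeric(500); idx <- sample(500, 50)
    v2[idx] <- round(runif(50, 0.01, 99), 4)
    p3 <- new("BindingProfile", signal = RleList(chrT = Rle(v2), compress = FALSE),
              seqinfo = lay, backgroundMean = 1, normalized = TRUE)
    writeWig(p3, wig)
    expect_equal(as.numeric(profileSignal(readWig(wig, lay))[["chrT"]]), v2,
                 tolerance = 1e-6)
    # malformed wiggle is a format error naming the file
    bad <- tempfile(fileext = ".wig")
    writeLines(c("variableStep chrom=chrT", "not-a-position\t1.0"), bad)
    suppressWarnings(expect_error(readWig(bad, lay),
                                  "malformed|parse|invalid"))
})

test_that("profile argmax sits at the planted site centre without noise", {
    lay <- Seqinfo("chrT", 20000L)
    tssOne <- GRanges("chrT", IRanges(10200, width = 1), strand = "+",
                      gene_id = "g1", seqinfo = lay)
    cfg <- simConfig(layout = lay, tss = tssOne, nSites = 1L,
                     readsPerSite = 60L, borderJitterSd = 0,
                     backgroundFraction = 0, footprintBp = 19L, seed = 2L)
    sim <- simulateSignal(cfg)
    # degenerate jitter: all plus-strand read_1 5' ends exactly at c - 9
    r1 <- extractRead1(sim$pairs)
    plus5 <- start(r1)[as.character(strand(r1)) == "+"]
    expect_true(all(plus5 == 10000 - 9))
    tr <- trimReads(r1, 19L)
    cov <- coverageByStrand(tr, lay)
    prof <- combineStrands(cov$plus, cov$minus, lay)
    v <- as.numeric(profileSignal(prof)[["chrT"]])
    # site centre is 200 bp upstream of the plus-strand TSS at 10200; with
    # zero jitter the profile is a plateau over the footprint, so the centre
    # estimate is the midpoint of the maximal positions
    expect_lte(abs(mean(which(v == max(v))) - 10000), 2)
})
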