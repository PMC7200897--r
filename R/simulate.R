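#' Toy genome layout and gene annotation
#'
#' Helpers for building yeast-scale synthetic genomes: `toyLayout` makes a
#' [GenomeInfoDb::Seqinfo] of equally sized chromosomes (default 12 x 1 Mb,
#' matching the ~12 Mb S. cerevisiae genome), and `toyTss` places a TSS
#' every `spacing` bp with alternating strand (default 2 kb, approximating
#' yeast gene density).
#'
#' @param nChrom Number of chromosomes.
#' @param chromLen Length of each chromosome (bp).
#' @return `toyLayout`: a `Seqinfo`; `toyTss`: a width-1 stranded `GRanges`
#'   with `gene_id`.
#' @export
toyLayout <- function(nChrom = 12L, chromLen = 1e6) {
    rn <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX", "X",
            "XI", "XII", "XIII", "XIV", "XV", "XVI")
    nm <- if (nChrom <= length(rn)) paste0("chr", rn[seq_len(nChrom)]) else
        paste0("chr", seq_len(nChrom))
    Seqinfo(seqnames = nm, seqlengths = rep(as.integer(chromLen), nChrom))
}

#' @rdname toyLayout
#' @param layout Genome `Seqinfo`.
#' @param spacing Distance between consecutive TSSs (bp).
#' @param margin Distance kept free of TSSs at each chromosome end.
#' @export
toyTss <- function(layout, spacing = 2000L, margin = 3000L) {
    sl <- seqlengths(layout)
    pos <- lapply(sl, function(L) seq(margin, L - margin, by = spacing))
    n <- lengths(pos)
    gr <- GRanges(rep(names(sl), n), IRanges(unlist(pos), width = 1L),
                  strand = rep_len(c("+", "-"), sum(n)), seqinfo = layout)
    mcols(gr)$gene_id <- sprintf("gene%05d", seq_along(gr))
    gr
}

#' Synthetic ChIP-exo experiment configuration
#'
#' Bundles the parameters of the read simulator.  The defaults describe the
#' experiment the simulator is meant to emulate: a yeast-scale genome,
#' 75 bp paired-end reads with insert length 225 +- 75 bp, binding sites
#' 200 bp upstream of TSSs, exonuclease border reads whose read_1 5' ends
#' sit half a footprint from the site centre with ~1.5 bp jitter, a 20%
#' uniform background, and optional PCR duplication.
#'
#' @param layout Genome [GenomeInfoDb::Seqinfo] (default [toyLayout()]).
#' @param tss TSS annotation (default [toyTss()] on `layout`).
#' @param nSites Number of binding sites planted (each upstream of a
#'   distinct randomly chosen gene).
#' @param sitePositions Optional explicit site centres (width-1 `GRanges`),
#'   overriding `nSites`/`upstreamOffset`.
#' @param footprintBp Planted footprint size; border reads start
#'   `floor(footprintBp/2)` bp from the site centre.
#' @param readsPerSite Border read pairs per site.
#' @param borderJitterSd Gaussian jitter (sd, bp, rounded to integers) on
#'   border positions; emulates imperfect exonuclease stops.
#' @param backgroundFraction Fraction of all signal-sample reads placed
#'   uniformly over the genome.
#' @param readLength,insertMean,insertSd Read geometry (bp).
#' @param pcrDuplicateRate Fraction of pairs duplicated by copying.
#' @param lowMapqFraction Fraction of pairs given mapq drawn from 0..19
#'   (the rest get 42).
#' @param upstreamOffset Distance from TSS to planted site centre (bp,
#'   upstream in gene orientation).
#' @param seed Integer seed; every simulator operation is a pure function
#'   of (config, seed).
#' @return A `SimConfig` (list) for [simulateSignal()].
#' @export
simConfig <- function(layout = toyLayout(), tss = toyTss(layout),
                      nSites = 200L, sitePositions = NULL, footprintBp = 19L,
                      readsPerSite = 100L, borderJitterSd = 1.5,
                      backgroundFraction = 0.2, readLength = 75L,
                      insertMean = 225, insertSd = 75,
                      pcrDuplicateRate = 0, lowMapqFraction = 0,
                      upstreamOffset = 200L, seed = 1L) {
    stopifnot(nSites >= 0, readsPerSite >= 0,
              backgroundFraction >= 0, backgroundFraction <= 1,
              pcrDuplicateRate >= 0, pcrDuplicateRate <= 1,
              lowMapqFraction >= 0, lowMapqFraction <= 1,
              footprintBp >= 1, readLength >= 1)
    if (footprintBp > min(seqlengths(layout)))
        stop("footprint larger than a chromosome: infeasible geometry")
    structure(list(layout = layout, tss = tss, nSites = as.integer(nSites),
                   sitePositions = sitePositions,
                   footprintBp = as.integer(footprintBp),
                   readsPerSite = as.integer(readsPerSite),
                   borderJitterSd = borderJitterSd,
                   backgroundFraction = backgroundFraction,
                   readLength = as.integer(readLength),
                   insertMean = insertMean, insertSd = insertSd,
                   pcrDuplicateRate = pcrDuplicateRate,
                   lowMapqFraction = lowMapqFraction,
                   upstreamOffset = as.integer(upstreamOffset),
                   seed = as.integer(seed)),
              class = "SimConfig")
}

# clamp read_1/read_2 5' ends so both alignment spans fit the chromosome
.clampFive <- function(five, plus, len, w) {
    lo <- ifelse(plus, 1L, w)
    hi <- ifelse(plus, len - w + 1L, len)
    pmin(pmax(five, lo), hi)
}

# vectorized fragment-pair builder shared by signal and noise simulators:
# given read_1 5' ends and strands, draws inserts and mates
.buildPairs <- function(chrom, plus, r1five, cfg, nameStem) {
    n <- length(r1five)
    sl <- seqlengths(cfg$layout)
    len <- unname(sl[chrom])
    w <- cfg$readLength
    r1five <- .clampFive(r1five, plus, len, w)
    insert <- pmax(round(stats::rnorm(n, cfg$insertMean, cfg$insertSd)), w)
    r2five <- ifelse(plus, r1five + insert - 1, r1five - insert + 1)
    # read_2 is on the opposite strand; clamp its span too
    r2five <- .clampFive(r2five, !plus, len, w)
    start1 <- ifelse(plus, r1five, r1five - w + 1L)
    mapq <- rep(42L, n)
    if (cfg$lowMapqFraction > 0 && n > 0) {
        nlow <- round(cfg$lowMapqFraction * n)
        if (nlow > 0) {
            idx <- sample.int(n, nlow)
            mapq[idx] <- sample(0:19, nlow, replace = TRUE)
        }
    }
    gr <- GRanges(chrom, IRanges(as.integer(start1), width = w),
                  strand = ifelse(plus, "+", "-"), seqinfo = cfg$layout)
    names(gr) <- sprintf("%s%07d", nameStem, seq_len(n))
    ExoPairs(gr, mapq = mapq, r2five = as.integer(r2five))
}

#' Simulate exonuclease border reads around planted binding sites
#'
#' Generates aligned paired-end fragments emulating a ChIP-exo experiment:
#' for each planted site at centre `c` with footprint `f`, plus-strand
#' read_1 5' ends are drawn at `c - floor(f/2) + N(0, jitter)` and
#' minus-strand 5' ends at `c + floor(f/2) + N(0, jitter)`; read_2 lies at
#' sonication-insert distance (`N(insertMean, insertSd)`, floored at the
#' read length) outward from the site.  A configurable fraction of reads is
#' uniform background, and PCR duplicates are injected by copying existing
#' pairs.  Fully reproducible from `config$seed`.
#'
#' @param config A [simConfig()].
#' @return A list: `pairs` (an [ExoPairs-class], originals first,
#'   duplicate copies appended), and `truth` — a list with `sites`
#'   (data.frame: `site`, `chrom`, `center`, `geneStrand`, `gene_id`,
#'   `borderOffset`, `nReads`), `isDuplicate` (logical per pair),
#'   `isBackground` (logical per pair) and `r1five` (the planted 5' ends).
#' @export
simulateSignal <- function(config) {
    cfg <- config
    set.seed(cfg$seed)
    if (!is.null(cfg$sitePositions)) {
        sites <- cfg$sitePositions
        geneStrand <- rep("+", length(sites))
        geneId <- rep(NA_character_, length(sites))
    } else {
        pick <- sort(sample.int(length(cfg$tss), cfg$nSites))
        anchor <- cfg$tss[pick]
        minus <- as.character(strand(anchor)) == "-"
        centers <- ifelse(minus, start(anchor) + cfg$upstreamOffset,
                          start(anchor) - cfg$upstreamOffset)
        sites <- GRanges(seqnames(anchor), IRanges(centers, width = 1L),
                         seqinfo = cfg$layout)
        geneStrand <- as.character(strand(anchor))
        geneId <- mcols(anchor)$gene_id
    }
    f2 <- cfg$footprintBp %/% 2L
    ns <- length(sites)
    nSig <- ns * cfg$readsPerSite
    siteIdx <- rep(seq_len(ns), each = cfg$readsPerSite)
    plus <- stats::runif(nSig) < 0.5
    jit <- if (cfg$borderJitterSd > 0)
        as.integer(round(stats::rnorm(nSig, 0, cfg$borderJitterSd))) else 0L
    center <- start(sites)[siteIdx]
    r1five <- ifelse(plus, center - f2, center + f2) + jit
    chrom <- as.character(seqnames(sites))[siteIdx]
    nBg <- if (cfg$backgroundFraction > 0 && cfg$backgroundFraction < 1)
        round(nSig * cfg$backgroundFraction / (1 - cfg$backgroundFraction))
    else 0L
    if (nBg > 0) {
        sl <- seqlengths(cfg$layout)
        bgChrom <- sample(names(sl), nBg, replace = TRUE,
                          prob = sl / sum(as.numeric(sl)))
        bgFive <- as.integer(1 + floor(stats::runif(nBg) * sl[bgChrom]))
        bgPlus <- stats::runif(nBg) < 0.5
        chrom <- c(chrom, bgChrom)
        plus <- c(plus, bgPlus)
        r1five <- c(r1five, bgFive)
    }
    pairs <- .buildPairs(chrom, plus, r1five, cfg, "frag")
    n <- length(pairs)
    nDup <- round(cfg$pcrDuplicateRate * n)
    isDup <- rep(FALSE, n)
    if (nDup > 0) {
        src <- sample.int(n, nDup, replace = TRUE)
        dup <- pairs[src]
        gr <- pairRanges(dup)
        names(gr) <- sprintf("dup%07d", seq_len(nDup))
        pairs <- c(pairs, ExoPairs(gr))
        isDup <- c(isDup, rep(TRUE, nDup))
    }
    truth <- list(sites = data.frame(site = seq_len(ns),
                      chrom = as.character(seqnames(sites)),
                      center = start(sites), geneStrand = geneStrand,
                      gene_id = geneId, borderOffset = f2,
                      nReads = as.integer(table(factor(siteIdx,
                          levels = seq_len(ns))))),
                  isDuplicate = isDup,
                  isBackground = c(rep(FALSE, nSig),
                                   rep(TRUE, max(nBg, 0)),
                                   rep(NA, nDup)),
                  r1five = r1FivePrime(pairs))
    list(pairs = pairs, truth = truth)
}

#' Simulate uniformly distributed noise reads
#'
#' Emulates a mapped sample of random (unenriched) paired-end reads:
#' read_1 5' positions uniform over the genome, fair-coin strand, read_2
#' at the standard insert distance.
#'
#' @param nReads Number of fragment pairs.
#' @param layout Genome [GenomeInfoDb::Seqinfo].
#' @param seed Integer seed.
#' @param readLength,insertMean,insertSd Read geometry (bp).
#' @return An [ExoPairs-class] of `nReads` pairs.
#' @export
simulateNoise <- function(nReads, layout, seed = 1L, readLength = 75L,
                          insertMean = 225, insertSd = 75) {
    cfg <- list(layout = layout, readLength = as.integer(readLength),
                insertMean = insertMean, insertSd = insertSd,
                lowMapqFraction = 0)
    set.seed(seed)
    if (nReads == 0L)
        return(ExoPairs(GRanges(seqinfo = layout)))
    sl <- seqlengths(layout)
    chrom <- sample(names(sl), nReads, replace = TRUE,
                    prob = sl / sum(as.numeric(sl)))
    five <- as.integer(1 + floor(stats::runif(nReads) * sl[chrom]))
    plus <- stats::runif(nReads) < 0.5
    .buildPairs(chrom, plus, five, cfg, "noise")
}

#' Mix signal and noise read pools at a defined noise fraction
#'
#' Implements the artificial-noise validation design: from a pure signal
#' pool and a pure noise pool, draw
#' `nSignal = round(total * (1 - noiseFraction))` and
#' `nNoise = total - nSignal` pairs without replacement (each call with its
#' own seed, mirroring independently seeded subsampling) and shuffle.
#' For the default 100,000-read total the five canonical noise levels give
#' signal/noise counts 100000/0, 75000/25000, 50000/50000, 25000/75000 and
#' 0/100000.
#'
#' @param signal,noise [ExoPairs-class] pools on the same genome.
#' @param noiseFraction Fraction of the mixed sample drawn from the noise
#'   pool (0..1).
#' @param totalReads Total pairs in the mixed sample (default 100000).
#' @param seed Integer seed for this subsample.
#' @return A list: `pairs` (shuffled mixed `ExoPairs`), `nSignal`,
#'   `nNoise`.
#' @export
mixDatasets <- function(signal, noise, noiseFraction, totalReads = 100000L,
                        seed = 1L) {
    stopifnot(noiseFraction >= 0, noiseFraction <= 1)
    nSignal <- round(totalReads * (1 - noiseFraction))
    nNoise <- totalReads - nSignal
    if (length(signal) < nSignal)
        stop("signal pool too small: need ", nSignal, ", have ",
             length(signal), " (shortfall ", nSignal - length(signal), ")")
    if (length(noise) < nNoise)
        stop("noise pool too small: need ", nNoise, ", have ",
             length(noise), " (shortfall ", nNoise - length(noise), ")")
    set.seed(seed)
    take <- list()
    if (nSignal > 0) take <- c(take, list(signal[sample.int(length(signal), nSignal)]))
    if (nNoise > 0) take <- c(take, list(noise[sample.int(length(noise), nNoise)]))
    mixed <- if (length(take) == 1L) take[[1]] else do.call(c, take)
    mixed <- mixed[sample.int(length(mixed))]
    list(pairs = mixed, nSignal = as.integer(nSignal),
         nNoise = as.integer(nNoise))
}

#' Run the artificial-noise validation design
#'
#' Builds a signal pool (planted sites upstream of TSSs) and a uniform
#' noise pool, mixes them at each requested noise fraction into
#' independently seeded pseudo-replicates, runs each sample through the
#' standard pipeline defaults (quality filter, deduplication, 1-kb
#' binning; optionally trim/overlap/normalize for profile enrichment) and
#' tabulates per-fraction replicate correlation and promoter enrichment.
#' Replicate correlation should fall with the noise fraction — reaching
#' ~0 at 100% noise — and promoter enrichment should fall towards 1.
#'
#' The signal pool is shared between the two replicates of a fraction
#' (they emulate subsamples of one merged real dataset); each replicate's
#' noise reads are generated from an independent seed, the limit of
#' subsampling a noise pool much larger than the sample.
#'
#' @param config A [simConfig()]; the default pool is sized (500 sites x
#'   400 reads + 20% background, ~250k pairs) so that two 100k subsamples
#'   are far from identical.
#' @param fractions Noise fractions to test.
#' @param totalReads Reads per mixed sample.
#' @param seed Master seed; per-sample seeds are derived from it.
#' @param computeEnrichment If `FALSE`, skip the profile build and report
#'   only replicate correlation (faster).
#' @return A data.frame with one row per fraction: `noiseFraction`, `pcc`
#'   (log2 1-kb-bin Pearson correlation between the two replicates),
#'   `enrichment` (promoter fold-over-background of the merged profile; NA
#'   when skipped), `nSignal`, `nNoise`.
#' @export
runNoiseValidation <- function(config = simConfig(nSites = 500L,
                                   readsPerSite = 400L, seed = seed),
                               fractions = c(0, 0.25, 0.5, 0.75, 1),
                               totalReads = 100000L, seed = 1L,
                               computeEnrichment = TRUE) {
    sig <- simulateSignal(config)
    out <- data.frame()
    for (i in seq_along(fractions)) {
        fr <- fractions[i]
        reps <- lapply(1:2, function(j) {
            nNoise <- totalReads - round(totalReads * (1 - fr))
            noise <- simulateNoise(nNoise, config$layout,
                                   seed = seed + 1000L * i + 10L * j)
            mx <- mixDatasets(sig$pairs, noise, fr, totalReads,
                              seed = seed + 100L * i + j)
            dd <- deduplicate(filterQuality(mx$pairs))
            list(read1 = extractRead1(dd$pairs), mix = mx)
        })
        bins <- lapply(reps, function(r)
            binReads(r$read1, config$layout, 1000L))
        pcc <- correlateSamples(bins)$correlation[1, 2]
        enr <- NA_real_
        if (computeEnrichment) {
            profs <- lapply(reps, function(r) {
                tr <- trimReads(r$read1, config$footprintBp)
                cov <- coverageByStrand(tr, config$layout)
                backgroundNormalize(combineStrands(cov$plus, cov$minus,
                                                   config$layout))
            })
            enr <- tssEnrichment(mergeReplicates(profs), config$tss)
        }
        out <- rbind(out, data.frame(noiseFraction = fr, pcc = pcc,
                                     enrichment = enr,
                                     nSignal = reps[[1]]$mix$nSignal,
                                     nNoise = reps[[1]]$mix$nNoise))
    }
    out
}

#' Write a random toy genome FASTA
#'
#' Uniform-random DNA matching a layout, for exercising sequence
#' extraction and motif-input generation on synthetic data.
#'
#' @param layout Genome [GenomeInfoDb::Seqinfo].
#' @param file FASTA output path.
#' @param seed Integer seed.
#' @return The `DNAStringSet`, invisibly.
#' @export
writeToyGenome <- function(layout, file, seed = 1L) {
    set.seed(seed)
    sl <- seqlengths(layout)
    seqs <- Biostrings::DNAStringSet(vapply(sl, function(L)
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
              collapse = ""), character(1)))
    names(seqs) <- names(sl)
    Biostrings::writeXStringSet(seqs, file)
    invisible(seqs)
}
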