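#' @import methods
#' @importFrom S4Vectors mcols mcols<- metadata metadata<- DataFrame Rle runValue
#' @importFrom IRanges IRanges RleList Views viewSums
#' @importFrom GenomeInfoDb Seqinfo seqinfo seqnames seqlengths seqlevels
#' @importFrom GenomicRanges GRanges granges coverage resize shift strand
#'   strand<- start end width seqnames
#' @importFrom BiocGenerics sort
NULL

#' Aligned paired-end ChIP-exo fragments
#'
#' `ExoPairs` holds one record per properly mapped paired-end fragment.  The
#' read_1 alignment span is stored as a [GenomicRanges::GRanges] (1-based,
#' closed intervals; the strand is read_1's strand) and carries two required
#' metadata columns:
#'
#' * `mapq` — pair-level mapping quality (minimum over the mates where both
#'   are available),
#' * `r2five` — the 1-based genomic coordinate of read_2's 5' end.
#'
#' Read_1's 5' end is `start` on the plus strand and `end` on the minus
#' strand, the convention used throughout: in ChIP-exo the lambda exonuclease
#' stops at the protein-DNA crosslink, so read_1 5' ends mark binding-site
#' borders, while read_2 positions come from random sonication breakpoints.
#'
#' @slot ranges A `GRanges` of read_1 spans with `mapq` and `r2five` columns
#'   and a complete [GenomeInfoDb::Seqinfo].
#' @seealso [readAlignedPairs()], [deduplicate()], [extractRead1()]
#' @export
setClass("ExoPairs", representation(ranges = "GRanges"))

setValidity("ExoPairs", function(object) {
    gr <- object@ranges
    msg <- character()
    need <- c("mapq", "r2five")
    miss <- setdiff(need, colnames(mcols(gr)))
    if (length(miss))
        msg <- c(msg, paste0("missing mcols: ", paste(miss, collapse = ", ")))
    if (any(is.na(GenomeInfoDb::seqlengths(gr))))
        msg <- c(msg, "seqinfo must carry chromosome lengths")
    if (length(gr) && !all(as.character(strand(gr)) %in% c("+", "-")))
        msg <- c(msg, "read_1 strand must be + or -")
    if (length(gr) && "r2five" %in% colnames(mcols(gr))) {
        len <- GenomeInfoDb::seqlengths(gr)[as.character(seqnames(gr))]
        r2 <- mcols(gr)$r2five
        if (any(r2 < 1L | r2 > len))
            msg <- c(msg, "r2five outside chromosome bounds")
        if (any(start(gr) < 1L) || any(end(gr) > len))
            msg <- c(msg, "read_1 span outside chromosome bounds")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an ExoPairs object
#'
#' @param r1 `GRanges` of read_1 alignment spans (strand = read_1 strand),
#'   with seqlengths set.
#' @param mapq Integer vector of pair-level mapping qualities.
#' @param r2five Integer vector, 1-based 5' coordinate of each read_2.
#' @return An [ExoPairs-class] object.
#' @examples
#' si <- GenomeInfoDb::Seqinfo("chrI", 10000)
#' r1 <- GenomicRanges::GRanges("chrI", IRanges::IRanges(101, 175),
#'                              strand = "+", seqinfo = si)
#' ExoPairs(r1, mapq = 42L, r2five = 325L)
#' @export
ExoPairs <- function(r1, mapq = integer(), r2five = integer()) {
    if (length(mapq)) mcols(r1)$mapq <- as.integer(mapq)
    if (length(r2five)) mcols(r1)$r2five <- as.integer(r2five)
    if (!length(r1)) {
        mcols(r1)$mapq <- integer()
        mcols(r1)$r2five <- integer()
    }
    new("ExoPairs", ranges = r1)
}

#' @describeIn ExoPairs Number of fragments.
#' @param x,object An `ExoPairs` object.
#' @export
setMethod("length", "ExoPairs", function(x) length(x@ranges))

#' @describeIn ExoPairs Subset fragments.
#' @param i Index vector.
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "ExoPairs", function(x, i, j, ..., drop = FALSE) {
    initialize(x, ranges = x@ranges[i])
})

#' @describeIn ExoPairs Concatenate `ExoPairs` objects (same genome).
#' @export
setMethod("c", "ExoPairs", function(x, ...) {
    args <- list(x, ...)
    grl <- lapply(args, function(p) p@ranges)
    initialize(x, ranges = do.call(c, grl))
})

#' @describeIn ExoPairs Genome description of the pairs.
#' @export
setMethod("seqinfo", "ExoPairs", function(x) seqinfo(x@ranges))

setMethod("show", "ExoPairs", function(object) {
    cat("ExoPairs with", length(object), "fragment pairs on",
        length(seqlevels(object@ranges)), "sequences\n")
    if (length(object)) {
        tab <- table(strand(object@ranges))
        cat("  read_1 strand: +", tab[["+"]], " -", tab[["-"]], "\n")
        cat("  mapq range:", paste(range(mcols(object@ranges)$mapq),
                                   collapse = "-"), "\n")
    }
})

#' @describeIn ExoPairs The underlying read_1 `GRanges` (with `mapq`,
#'   `r2five` metadata columns).
#' @export
pairRanges <- function(x) x@ranges

#' 5' end coordinates of read_1 / read_2
#'
#' Read_1's 5' end is the alignment start on `+` and the alignment end on
#' `-`; read_2's 5' end is stored directly.
#' @param x An `ExoPairs` object (or, for `fivePrime`, any stranded
#'   `GRanges`).
#' @return Integer vector of 1-based coordinates.
#' @export
r1FivePrime <- function(x) {
    gr <- if (is(x, "ExoPairs")) x@ranges else x
    ifelse(as.character(strand(gr)) == "+", start(gr), end(gr))
}

#' @rdname r1FivePrime
#' @export
r2FivePrime <- function(x) mcols(x@ranges)$r2five

#' @rdname r1FivePrime
#' @export
pairMapq <- function(x) mcols(x@ranges)$mapq

#' Per-base TF binding profile
#'
#' A `BindingProfile` is the per-chromosome, base-resolution ChIP-exo signal
#' after the two strand coverages have been combined under the
#' both-strand-overlap rule: a position carries signal only where trimmed
#' reads cover it on both strands, because a credible binding event needs an
#' exonuclease border on each side of the factor.  After
#' [backgroundNormalize()] the values are fold-over-background (genome-wide
#' mean 1).
#'
#' @slot signal An [IRanges::RleList], one run-length-encoded numeric vector
#'   per chromosome, each of full chromosome length.
#' @slot seqinfo The genome layout ([GenomeInfoDb::Seqinfo]).
#' @slot backgroundMean Genome-wide mean used for normalization (`NA_real_`
#'   until normalized).
#' @slot normalized Logical; `TRUE` once values are fold-over-background.
#' @seealso [combineStrands()], [backgroundNormalize()], [mergeReplicates()]
#' @export
setClass("BindingProfile",
    representation(signal = "RleList", seqinfo = "Seqinfo",
                   backgroundMean = "numeric", normalized = "logical"))

setValidity("BindingProfile", function(object) {
    msg <- character()
    sl <- seqlengths(object@seqinfo)
    if (!identical(names(object@signal), names(sl)))
        msg <- c(msg, "signal chromosomes must match seqinfo order")
    else if (!all(lengths(object@signal) == unname(sl)))
        msg <- c(msg, "signal vectors must span whole chromosomes")
    if (length(object@normalized) != 1L)
        msg <- c(msg, "normalized must be a single logical")
    if (length(msg)) msg else TRUE
})

#' @describeIn BindingProfile Per-chromosome signal as an `RleList`.
#' @param x,object A `BindingProfile`.
#' @export
profileSignal <- function(x) x@signal

#' @describeIn BindingProfile Genome layout.
#' @export
setMethod("seqinfo", "BindingProfile", function(x) x@seqinfo)

#' @describeIn BindingProfile Background mean (NA before normalization).
#' @export
backgroundMean <- function(x) x@backgroundMean

#' @describeIn BindingProfile Whether values are fold-over-background.
#' @export
isNormalized <- function(x) x@normalized

setMethod("show", "BindingProfile", function(object) {
    tot <- sum(vapply(object@signal, function(r) sum(as.numeric(runValue(r) > 0) *
                  S4Vectors::runLength(r)), numeric(1)))
    cat("BindingProfile over", length(object@signal), "chromosomes (",
        sum(as.numeric(seqlengths(object@seqinfo))), "bp )\n")
    cat("  nonzero positions:", tot, "\n")
    cat("  normalized:", object@normalized,
        if (object@normalized) paste0("(background mean ",
            signif(object@backgroundMean, 4), ")") else "", "\n")
})

#' Footprint / trim-length calculation record
#'
#' Holds the inputs, intermediates and result of the protein-size-based
#' footprint estimate used to pick the read trim length.  See
#' [computeFootprint()] for the model.
#'
#' @slot sequenceLengthNt Coding-sequence length (nucleotides).
#' @slot tfWeightDa Estimated protein weight (daltons).
#' @slot tfRadiusNm Estimated spherical radius (nanometres).
#' @slot tfFootprintBp Rounded footprint, i.e. the trim length (bp).
#' @slot radiusMultiplier Multiplier on the radius (3 under the
#'   half-overlapping-dimer assumption).
#' @export
setClass("FootprintParams",
    representation(sequenceLengthNt = "numeric", tfWeightDa = "numeric",
                   tfRadiusNm = "numeric", tfFootprintBp = "integer",
                   radiusMultiplier = "numeric"))

setValidity("FootprintParams", function(object) {
    if (object@tfFootprintBp < 1L) "footprint must be a positive integer"
    else TRUE
})

setMethod("show", "FootprintParams", function(object) {
    cat("FootprintParams\n")
    cat(sprintf("  coding sequence : %g nt (%g codons)\n",
                object@sequenceLengthNt, object@sequenceLengthNt / 3))
    cat(sprintf("  TF weight       : %g Da\n", object@tfWeightDa))
    cat(sprintf("  TF radius       : %.4g nm\n", object@tfRadiusNm))
    cat(sprintf("  footprint (trim): %d bp  [%g x radius]\n",
                object@tfFootprintBp, object@radiusMultiplier))
})

#' @describeIn FootprintParams The rounded footprint (= trim length) in bp.
#' @param x,object A `FootprintParams` object.
#' @export
tfFootprint <- function(x) x@tfFootprintBp
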