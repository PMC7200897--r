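#' Strand-specific base coverage of trimmed reads
#'
#' Computes per-base read coverage separately for the two strands, the
#' precursor of the both-strand-overlap filter.
#'
#' @param trimmed A stranded `GRanges` of trimmed reads ([trimReads()]),
#'   clipped to the genome.
#' @param layout Optional [GenomeInfoDb::Seqinfo]; defaults to the reads'
#'   own seqinfo (which must carry lengths).
#' @return A list with elements `plus` and `minus`, each an
#'   [IRanges::RleList] of per-base counts spanning every chromosome.
#' @export
coverageByStrand <- function(trimmed, layout = seqinfo(trimmed)) {
    sl <- seqlengths(layout)
    if (any(is.na(sl))) stop("layout must carry chromosome lengths")
    if (length(trimmed)) {
        len <- sl[as.character(seqnames(trimmed))]
        if (any(start(trimmed) < 1L) || any(end(trimmed) > len))
            stop("trimmed reads extend outside the genome layout")
    }
    st <- as.character(strand(trimmed))
    list(plus = coverage(trimmed[st == "+"], width = sl),
         minus = coverage(trimmed[st == "-"], width = sl))
}

#' Combine strand coverages under the both-strand-overlap rule
#'
#' ChIP-exo defines both borders of a bound factor: one set of read 5' ends
#' on the forward strand, one on the reverse strand, with the factor in
#' between.  Presence of a factor is only credible where trimmed reads from
#' *both* strands overlap, so the combined profile is the sum of the two
#' strand coverages at positions where both are positive, and zero
#' elsewhere.
#'
#' @param fwd,rev Per-base coverage `RleList`s from [coverageByStrand()]
#'   (same genome).
#' @param layout The genome [GenomeInfoDb::Seqinfo].
#' @param combine How to combine the two coverages at overlap positions:
#'   `"sum"` (default; preserves total read support), `"min"` or `"mean"`.
#' @return An un-normalized [BindingProfile-class].
#' @export
combineStrands <- function(fwd, rev, layout, combine = c("sum", "min", "mean")) {
    combine <- match.arg(combine)
    if (missing(layout)) {
        layout <- Seqinfo(seqnames = names(fwd), seqlengths = lengths(fwd))
    }
    if (!identical(names(fwd), names(rev)) ||
        !identical(unname(lengths(fwd)), unname(lengths(rev))))
        stop("strand coverages disagree on genome layout")
    both <- (fwd > 0L) & (rev > 0L)
    vals <- switch(combine,
        sum  = (fwd + rev) * both,
        min  = IRanges::pmin(fwd, rev) * both,
        mean = (fwd + rev) / 2 * both)
    vals <- methods::as(vals, "RleList")
    new("BindingProfile", signal = vals, seqinfo = layout,
        backgroundMean = NA_real_, normalized = FALSE)
}

#' Normalize a profile by its average background read count
#'
#' Divides the profile by its genome-wide mean (computed over all
#' positions, zeros included), so replicates of different sequencing depth
#' become comparable and profile units read as fold-over-background.
#'
#' @param profile An un-normalized [BindingProfile-class].
#' @return The normalized profile (genome-wide mean 1).  An all-zero
#'   profile is returned unchanged with a warning.
#' @export
backgroundNormalize <- function(profile) {
    if (isNormalized(profile))
        stop("profile is already normalized")
    sig <- profileSignal(profile)
    total <- sum(vapply(sig, function(r) sum(as.numeric(r)), numeric(1)))
    glen <- sum(as.numeric(seqlengths(seqinfo(profile))))
    bg <- total / glen
    if (bg == 0) {
        warning("profile has no signal; background mean is 0, values unchanged")
        return(new("BindingProfile", signal = sig, seqinfo = seqinfo(profile),
                   backgroundMean = 0, normalized = TRUE))
    }
    new("BindingProfile", signal = methods::as(sig / bg, "RleList"),
        seqinfo = seqinfo(profile), backgroundMean = bg, normalized = TRUE)
}

#' Average normalized replicate profiles
#'
#' Combines replicates by their arithmetic mean per base position.  All
#' inputs must already be fold-over-background ([backgroundNormalize()]),
#' so each replicate contributes equally regardless of sequencing depth.
#'
#' @param profiles A list of normalized [BindingProfile-class] objects on
#'   the same genome (a single profile is returned as-is).
#' @return The merged `BindingProfile`.
#' @export
mergeReplicates <- function(profiles) {
    if (is(profiles, "BindingProfile")) profiles <- list(profiles)
    if (!length(profiles)) stop("no profiles supplied")
    norm <- vapply(profiles, isNormalized, logical(1))
    if (!all(norm))
        stop("all profiles must be normalized before merging")
    si <- seqinfo(profiles[[1]])
    for (p in profiles[-1])
        if (!identical(seqlengths(seqinfo(p)), seqlengths(si)))
            stop("profiles disagree on genome layout")
    sig <- Reduce(`+`, lapply(profiles, profileSignal)) / length(profiles)
    new("BindingProfile", signal = methods::as(sig, "RleList"), seqinfo = si,
        backgroundMean = mean(vapply(profiles, backgroundMean, numeric(1))),
        normalized = TRUE)
}

#' Write / read a binding profile as a wiggle track
#'
#' Profiles are serialized as `variableStep` wiggle (span 1, 1-based
#' positions, only nonzero positions emitted), the format of choice for
#' genome-browser inspection of ChIP-exo signal.
#'
#' @param profile A [BindingProfile-class].
#' @param path Output/input `.wig` path.
#' @return `writeWig`: the path, invisibly.  `readWig`: the reconstructed
#'   `BindingProfile` (normalization state is taken from `normalized`).
#' @export
writeWig <- function(profile, path) {
    sig <- profileSignal(profile)
    grl <- lapply(names(sig), function(ch) {
        r <- sig[[ch]]
        pos <- which(as.logical(r > 0))
        if (!length(pos)) return(GRanges(seqinfo = seqinfo(profile)))
        GRanges(ch, IRanges(pos, width = 1L),
                score = as.numeric(r[pos]), seqinfo = seqinfo(profile))
    })
    gr <- do.call(c, grl)
    rtracklayer::export.wig(gr, path)
    invisible(path)
}

#' @rdname writeWig
#' @param layout The genome [GenomeInfoDb::Seqinfo] for the track.
#' @param normalized Logical; whether the stored values are
#'   fold-over-background (default `TRUE`, the state in which profiles are
#'   written by the pipeline).
#' @export
readWig <- function(path, layout, normalized = TRUE) {
    gr <- tryCatch(rtracklayer::import.wig(path),
                   error = function(e) stop("malformed wiggle file '", path,
                                            "': ", conditionMessage(e)))
    unknown <- setdiff(unique(as.character(seqnames(gr))), seqlevels(layout))
    if (length(unknown))
        stop("wiggle chromosome not in layout: ", paste(unknown, collapse = ", "))
    sl <- seqlengths(layout)
    sig <- RleList(lapply(seqlevels(layout), function(ch) {
        sub <- gr[seqnames(gr) == ch]
        v <- Rle(0, sl[[ch]])
        if (length(sub)) {
            # expand any spans > 1 the parser may have merged
            pos <- unlist(lapply(seq_along(sub), function(i)
                start(sub)[i]:end(sub)[i]))
            val <- rep(mcols(sub)$score, width(sub))
            v[pos] <- val
        }
        v
    }), compress = FALSE)
    names(sig) <- seqlevels(layout)
    new("BindingProfile", signal = sig, seqinfo = layout,
        backgroundMean = NA_real_, normalized = normalized)
}
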