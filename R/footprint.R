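#' Estimate a transcription factor's DNA footprint from its sequence length
#'
#' ChIP-exo read 5' ends mark the borders of the protein-DNA footprint, so
#' the read trim length should match the footprint size.  The estimate
#' proceeds in three steps from the coding-sequence length \eqn{L} (nt):
#'
#' \deqn{W = L \times \tfrac{1}{3} \times 110 \;\mathrm{Da}}
#' \deqn{r = 0.066 \times W^{1/3} \;\mathrm{nm}}
#' \deqn{F = \mathrm{round}(m \times r \times 3.03) \;\mathrm{bp}}
#'
#' i.e. the protein weight from the mean amino-acid mass (110 Da), the
#' radius of an equivalent sphere of that mass, and the diameter-scale
#' contact length converted at 3.03 bp/nm.  Most factors bind as dimers
#' assumed to overlap for half their size, hence the default multiplier
#' \eqn{m = 3} (three radii, i.e. 1.5 sphere diameters).  Rounding is
#' half-up to the nearest integer.
#'
#' For the S. cerevisiae factor Ino2 (304 codons, 912 nt) this yields a
#' 19 bp footprint.
#'
#' @param sequenceLengthNt Coding-sequence length in nucleotides (>= 3;
#'   a warning is issued when not divisible by 3).
#' @param radiusMultiplier Multiplier on the sphere radius; 3 encodes the
#'   half-overlapping-dimer assumption and should only be changed for
#'   factors known to bind as monomers or higher-order complexes.
#' @return A [FootprintParams-class] object; extract the trim length with
#'   [tfFootprint()].
#' @examples
#' tfFootprint(computeFootprint(912))   # Ino2 -> 19 bp
#' computeFootprintAa(304)              # same, from amino-acid count
#' @export
computeFootprint <- function(sequenceLengthNt, radiusMultiplier = 3) {
    if (!is.numeric(sequenceLengthNt) || length(sequenceLengthNt) != 1L ||
        is.na(sequenceLengthNt) || sequenceLengthNt <= 0)
        stop("sequenceLengthNt must be a single positive number")
    if (sequenceLengthNt < 3 || sequenceLengthNt %% 3 != 0)
        warning("sequenceLengthNt (", sequenceLengthNt,
                ") is not a positive multiple of 3; ",
                "is it really a coding-sequence length in nucleotides?")
    weight <- sequenceLengthNt / 3 * 110
    radius <- 0.066 * weight^(1 / 3)
    fp <- as.integer(floor(radiusMultiplier * radius * 3.03 + 0.5))
    new("FootprintParams", sequenceLengthNt = sequenceLengthNt,
        tfWeightDa = weight, tfRadiusNm = radius, tfFootprintBp = fp,
        radiusMultiplier = radiusMultiplier)
}

#' @rdname computeFootprint
#' @param lengthAa Protein length in amino acids; converted as
#'   `3 * lengthAa` nucleotides.  Supply exactly one of the two lengths.
#' @export
computeFootprintAa <- function(lengthAa, radiusMultiplier = 3) {
    computeFootprint(3 * lengthAa, radiusMultiplier = radiusMultiplier)
}
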