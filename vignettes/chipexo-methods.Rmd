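---
title: "ChIP-exo binding-profile analysis with exoPipe: models and methods"
author: "exoPipe authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ChIP-exo binding-profile analysis with exoPipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(exoPipe))
suppressPackageStartupMessages(library(GenomicRanges))
```

## The measurement model

ChIP-exo couples chromatin immunoprecipitation with a lambda exonuclease
digestion.  The exonuclease degrades DNA 5'→3' until it reaches the
protein–DNA crosslink, so after paired-end sequencing the 5' end of read_1
marks a *border* of the bound factor's footprint: plus-strand read_1 5'
ends accumulate at the left border, minus-strand 5' ends at the right
border, and the factor sits in between.  Read_2, in contrast, starts at a
random sonication breakpoint and carries no positional information about
the binding site.  Everything in exoPipe follows from this asymmetry:

* **PCR duplicates** cannot be identified from read_1 alone (many genuine
  fragments share a border position).  A duplicate is a pair with an
  identical read_1 *and* an identical read_2 — agreement at the random
  sonication end is what betrays an amplification copy.  `deduplicate()`
  keys on `(chrom, read_1 strand, read_1 5', read_2 5')`, keeps the first
  pair of each group, and is idempotent.  Strand is part of the key: two
  fragments on opposite strands at mirrored coordinates are distinct
  biological events.
* **Trimming**: each read_1 is re-anchored at its 5' end and extended the
  footprint length in the read direction (`trimReads()`), so border reads
  from the two strands overlap across the site.  Reads running past a
  chromosome end are clipped rather than dropped, preserving signal near
  telomeric genes.
* **The both-strand-overlap filter**: a position belongs to the binding
  profile only if trimmed coverage is positive on *both* strands there
  (`combineStrands()`).  One border alone is not evidence of a bound
  factor.  At positions passing the filter the two strand coverages are
  summed; summation preserves total read support, and `combine = "min"` or
  `"mean"` are available for users who prefer a conservative or averaged
  statistic.

## The footprint estimate

The trim length should match the protein's DNA footprint.  exoPipe
estimates it from the coding-sequence length $L$ (nt) in three steps
(`computeFootprint()`):

$$W = L \cdot \tfrac{1}{3} \cdot 110 \text{ Da}, \qquad
  r = 0.066 \cdot W^{1/3} \text{ nm}, \qquad
  F = \operatorname{round}(3 \cdot r \cdot 3.03 \text{ bp/nm})$$

i.e. protein mass from the mean amino-acid weight, the radius of an
equivalent sphere of that mass, and a contact length of three radii
converted to base pairs.  The factor 3 encodes the assumption that most
factors bind as dimers whose spheres overlap for half their size; it is
exposed (`radiusMultiplier`) for factors known to bind as monomers.
Rounding is half-up — the conventional reading where the rounding mode is
not otherwise fixed.  For the S. cerevisiae factor Ino2 (304 codons):

```{r}
computeFootprint(912)
```

Whether the 912 nt include the stop codon is immaterial: 912 and 915 nt
both round to 19 bp, so the anchor is robust to that ambiguity.  The
estimate grows as $L^{1/3}$, so it is insensitive to moderate annotation
errors in either direction.

## Normalization and replicate merging

`backgroundNormalize()` divides a profile by its genome-wide mean computed
over **all** positions, zeros included.  An alternative would exclude
peak regions from the background; we use the all-positions mean because it
is parameter-free, robust (peaks occupy a vanishing fraction of the
genome), and makes profile units directly interpretable as
fold-over-background with genome-wide mean 1.  Replicates are then
averaged per base (`mergeReplicates()`), so each contributes equally
regardless of sequencing depth.  Normalization is exactly scale-invariant,
and merging is invariant to replicate order.

## Quality control

Three QC statistics summarise an experiment:

1. **Replicate correlation** (`binReads()`, `correlateSamples()`): read_1
   5' ends are counted in 1-kb bins, bins that are zero in every sample
   are removed, counts are transformed as $\log_2(x + 1)$ and Pearson
   correlation is computed pairwise.  The pseudocount keeps bins that are
   zero in only some samples finite, which matters exactly in the noisy
   samples this plot is meant to flag.  Binning uses deduplicated,
   *untrimmed* reads, so the QC verdict does not depend on the chosen trim
   length.  Clean replicates correlate at $r \ge 0.85$; good ones at
   $\ge 0.9$.
2. **TSS meta-profile** (`tssMetaprofile()`, `tssEnrichment()`): the
   normalized profile is averaged over ±1000 bp windows around every TSS,
   flipped for minus-strand genes so upstream is always left.  Windows
   truncated at chromosome ends contribute only the positions they cover.
   Because most yeast factors bind upstream of the TSS, a clean experiment
   shows promoter enrichment left of the anchor; pure noise gives a flat
   profile at 1.
3. **Peak shape** (`peakShapeProfiles()`): read_1 5' ends per strand at
   signed offsets from each called peak centre.  The averaged plus- and
   minus-strand maxima should flank the centre at about half the
   footprint; a wide smear indicates failed peak calling or heterogeneous
   binding modes.

## Peak post-processing

GEM event files are parsed verbatim (`parseGemEvents()`), including GEM's
historical `expectd` header spelling; `expected` and `control` are
accepted as synonyms, and a file without any such column yields expected
strength 0 with a flag.  A peak's SNR is its IP strength over the expected
strength with a pseudocount-1 floor on the denominator
(`ip / max(expected, 1)`); peaks with SNR ≤ 2 are removed — the boundary
value 2.0 is excluded, following the strict reading of the filter.  Peaks
are assigned to every gene whose TSS lies strictly within 1000 bp of the
peak centre, upstream or downstream, so one peak may serve two divergent
genes; distances are signed negative-upstream in each gene's orientation.
The gene-target table rows cover the full TSS annotation, making absence
of binding explicit.  The recommended GEM invocation (q-value 0.01, k-mer
5–18, smoothing 3, minimum 5 events, at most 50 reads per base) is
documented here as provenance; GEM itself runs outside the package, as
does MEME — `extractPeakSequences()` prepares its 60-bp input windows.

## The synthetic-data generator

`simulateSignal()` emulates the border model directly: for a site at
centre $c$ with footprint $f$, plus-strand read_1 5' ends are drawn at
$c - \lfloor f/2 \rfloor + N(0, \sigma)$ and minus-strand ends at
$c + \lfloor f/2 \rfloor + N(0, \sigma)$, with read_2 at sonication-insert
distance $N(225, 75)$ bp (floored at the 75 bp read length) outward.
Defaults describe a yeast-scale study: a 12 × 1 Mb genome, one TSS every
2 kb with alternating strands (~6000 genes over 12 Mb, matching
S. cerevisiae gene density), sites planted 200 bp upstream of randomly
chosen TSSs, border jitter sd 1.5 bp (reproducing the 2–3 bp border smear
seen in real averaged peak shapes), 20% uniform background, and optional
PCR duplication by copying existing pairs.  The generator emits aligned
pairs rather than FASTQ: the pipeline's scope begins after mapping, and
this keeps the aligner out of the test loop.  Every operation is a pure
function of its configuration and seed.

The noise-robustness design mirrors the published validation: mixed
samples of 100,000 reads at noise fractions 0/25/50/75/100% are drawn
without replacement from a signal pool and a noise source, two
independently seeded pseudo-replicates per fraction
(`mixDatasets()`, `runNoiseValidation()`).  The signal pool (500 sites ×
400 reads + 20% background, ~250k pairs) is shared between replicates —
they emulate subsamples of one merged real dataset — while each
replicate's noise reads come from an independent seed, the limit of
subsampling a noise pool much larger than the sample.  A small shared
noise pool would leave "independent" 100%-noise replicates correlated at
roughly the inclusion probability, an artifact of pool size rather than
of the design.

**What the simulation does and does not show.**  The generator reproduces
the geometry of ChIP-exo signal (borders, inserts, background, duplicates,
promoter bias) but deliberately omits several features of real libraries:
site strengths are uniform across sites (real binding strengths vary over
orders of magnitude, which *raises* replicate bin correlation by adding
shared between-site variance — our 0%-noise replicate PCC of ~0.82 is
therefore conservative relative to the ≥0.9 of good real replicates),
background is uniform (real chromatin background has shared structure),
and there are no sequence-dependent biases.  Passing tests demonstrate
that the pipeline's operations are correct and that its QC statistics
respond to noise as designed — not that any particular real library will
reach a given correlation.  Promoter enrichment in the toy genome is
bounded near 2 even for noise-free signal, because ±1 kb promoter windows
tile about half of a genome with one gene per 2 kb and normalization fixes
the genome-wide mean at 1; the informative quantity is its decline to 1
as noise is added.

## Numerical and design choices

* **Coordinates** are 1-based, closed intervals throughout, the native
  convention of the GRanges/IRanges/Rle containers the package is built
  on; wiggle output is 1-based as the format requires, and BED output is
  converted to 0-based half-open at the boundary.
* **Pair-level mapping quality** is the minimum over the two mates: a
  fragment is only as trustworthy as its worse alignment.
* **Duplicate representative**: the first pair in input order survives;
  since all key coordinates are identical within a group, the choice is
  invisible downstream.
* **Centre estimation on plateaus**: with little jitter the combined
  profile is flat across the footprint; site-centre recovery therefore
  uses the midpoint of the maximal positions, which is exact for a
  symmetric plateau.
* **Degenerate inputs**: an all-zero profile normalizes to itself with a
  warning (background 0); empty TSS lists, single samples in correlation
  QC, and sub-3-bin correlations are errors, not silent results.
* **Problem sizes**: tests and the acceptance analysis run the full
  100,000-read mixing design on the 12-Mb toy genome — the same sample
  size as the published validation — with oracle comparisons on small
  randomized instances (hundreds of elements, 100 seeds) where exhaustive
  checks are feasible.

## Known limitations

* GEM and MEME are external: the package consumes GEM's events file and
  produces MEME's input, but neither tool is reimplemented or invoked.
* The SNR denominator is read from GEM's expected/control column; if GEM's
  internal noise model differs from that column, SNR values differ
  accordingly.
* BAM writing serialises positions only (no sequences or qualities),
  sufficient for every downstream operation in this pipeline but not a
  general-purpose BAM round-trip.
* The simulator's uniform site strengths and uniform background make its
  absolute correlation levels conservative, as discussed above.
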