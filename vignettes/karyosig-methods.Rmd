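---
title: "Copy-number rearrangement signatures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number rearrangement signatures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyosig)
library(dplyr)
```

# Scope and data model

`karyosig` analyses tumor copy-number profiles of the kind produced by
two-color array CGH: per-probe log2 ratios of tumor versus matched
control DNA, ordered along a genome build. Everything downstream —
threshold calibration, segmentation, aneuploidy calling, chromothripsis
and breakage-fusion-bridge (BFB) signature detection, loss-of-
heterozygosity (LOH) mechanism classification — operates on tabular
objects (tibbles), so results compose with ordinary dplyr verbs.

Coordinates are 0-based half-open throughout, as in BED; interval
arithmetic (arm fractions, gene overlaps) then needs no off-by-one
corrections. Sex chromosomes are excluded by default: against an
opposite-sex or pooled reference their log2 ratios are shifted for
reasons unrelated to somatic copy number. Chromosomes without a
recorded centromere are treated as single-armed — appropriate for the
largely acrocentric rat karyotype this package was designed around —
and an explicit centromere table switches any chromosome to p/q arms.

# Threshold calibration

A self–self (control versus control) hybridization measures the null
spread of log2 ratios. `calibrate_thresholds()` discards the extreme 1%
of probes on each tail, computes the trimmed mean $m$ and standard
deviation $s$, and sets

$$\text{gain} = m + k\,s, \qquad \text{loss} = m - k\,s, \qquad
\text{amp} = c \cdot \text{gain},$$

with $k = 3$ (the three-sigma rule) and $c = 5$ by default. The
trimming guards the moments against the handful of outlier probes every
array carries; note that it also shrinks $s$ slightly below the raw
standard deviation (about 7% for Gaussian noise), so a three-sigma cut
on a sd-0.1 null sits near 0.28 rather than 0.30. Fewer than 100 probes
or a zero spread is a calibration error, not a silent default.

Where no control hybridization exists — noise-free simulations in
particular, whose null spread is exactly zero — `default_thresholds()`
provides cutoffs (−0.3, 0.3, 1.2) positioned between the expected means
of single-copy states on a diploid background: $\log_2(1/2) = -1$ for a
loss, $\log_2(3/2) \approx 0.58$ for a gain, 1.5 and up for
amplification tiers.

# Segmentation

`segment_profile()` finds, per chromosome, the breakpoints minimizing

$$\sum_{\text{segments}} \text{SSE} + \lambda \cdot \#\text{breakpoints},$$

subject to a minimum of `min_probes` probes per segment (default 5,
suppressing single-probe artifacts), by an exact dynamic programme over
all admissible breakpoint sets. Exactness is not cosmetic: it makes the
segmenter provably equal to brute-force enumeration (a property the
test suite verifies on small chromosomes) and penalty-deterministic —
the same input and penalty always give the same optimum, with no
dependence on a heuristic split order.

With `penalty = NULL` the per-chromosome penalty is
$\max(2\hat\sigma^2 \log n,\ 10^{-8})$, where $\hat\sigma$ is a robust
noise estimate from the median absolute successive probe difference.
The $10^{-8}$ floor matters for noise-free input: with
$\hat\sigma = 0$ any over-segmentation costs nothing in SSE, and the
floor makes the minimal exact segmentation the unique optimum.

`assign_states()` maps segment means to discrete states. Boundary
values classify into the altered state on the gain side
(mean ≥ cut ⇒ GAIN/AMP); losses are strict (mean < loss cut). Alongside
the four-state label an integer *copy-number level* is recorded:
LOSS = −1, NEUTRAL = 0, GAIN = 1, and amplification tiers 2, 3, …
spaced 0.5 log2 units apart above the amplification cutoff. Merging of
adjacent segments, switch counting, and stair detection all operate on
this level rather than the collapsed four-state label — otherwise
adjacent amplification tiers would merge and BFB stairs would be
invisible. Merged segments recompute bp-weighted means and summed probe
counts.

# Signature definitions

**Aneuploidy.** An arm-level event is a single alteration or an
aggregate of same-class alterations (losses versus gains-and-
amplifications) covering strictly more than 75% of an arm. At most one
call per arm; a tie between classes yields no call.

**Chromothripsis.** A chromosome is called when it shows at least 10
changes in segmental copy-number involving two or three distinct
copy-number states. "Changes" are adjacent-segment level switches after
same-level merging — on merged segments the switch count is simply the
segment count minus one — and the distinct-state count covers the whole
chromosome including the neutral baseline, since the oscillation
pattern includes it. The count is chromosome-wide; the criterion is
read literally and does not attempt to excise non-oscillating
stretches.

**BFB.** Breakage-fusion-bridge cycles leave a terminal stair: scanning
inward from each chromosome terminus, the detector collects the maximal
run of segments whose level strictly decreases moving away from the
terminus with every stair above NEUTRAL. A call requires at least 3
stairs and a sharp interior drop — the next segment at NEUTRAL or
below, or at least `drop_levels` (default 2) levels below the lowest
stair. The published description bounds neither the drop magnitude nor
the stair heights, so both are explicit parameters. Genes intersecting
any stair-run segment at amplification level (any overlap, half-open)
are reported as amplified.

**LOH mechanism.** Given LOH established independently (the study used
capillary sequencing; the pipeline takes the heterozygous genotype as
that assertion), the mechanism is classified with precedence:
chromothripsis on the locus chromosome → "affected by chromothripsis";
else a LOSS segment overlapping the locus → "deletion"; else
"gene conversion or copy-neutral SV". Chromothripsis outranks deletion
because a shattered chromosome contains losses that are part of the
shattering, not independent deletions. The three-way label is the
finest distinction copy-number data support; separating gene conversion
from copy-neutral rearrangement needs allele-level evidence the
profiles do not carry.

# Telomere length from shallow sequencing

Reads are classified as telomeric by repeat content: the fraction of
positions matching the periodic vertebrate repeat, maximised over the
six phases and both orientations (TTAGGG / CCCTAA), must reach 0.9.
The phase-and-orientation maximum emulates alignment against a tandem
TTAGGG reference while remaining a pure function of the read; the 0.9
default tolerates roughly 10% sequencing error without admitting
interstitial telomere-like sequence. Genome coverage is estimated from
the non-telomeric reads, and mean telomere length per end is

$$L = \frac{\text{telomeric bases}}{\text{coverage} \times n_{\text{ends}}},$$

the standard shallow-WGS estimator; $n_{\text{ends}}$ defaults to 84
(rat: 2n = 42 chromosomes, two telomeres each) and is configurable for
other karyotypes. The estimator is linear in true length and
independent of coverage in expectation, properties the test suite
checks by parameter recovery against the read simulator. TRAP
(telomerase) and C-circle (ALT) signals are normalized to their
positive controls; "activated" is a strict comparison against a
configurable threshold (default 0.1 × control) because the published
judgement was qualitative.

Group contrasts use the pooled-variance Student's t-test, matching the
method named in the source figure legends; Welch's correction is
available behind `var_equal = FALSE`.

# The synthetic-data generator

The generator is first-class, tested code: it produces probe profiles,
cohorts and read sets with exactly the statistical structure the
detectors assume, plus truth manifests for record-by-record comparison.

* Probe log2 ratios are segment true mean + Gaussian noise
  (default sd 0.15 log2 units, a typical aCGH probe scatter). The
  level-to-log2 map defaults to −1 / 0 / 0.58 / 1.5 + 0.5·k as above.
* Chromothripsis plans place breakpoints uniformly on the probe grid
  with a minimum segment width of 5 probe spacings — the segmenter's
  own minimum segment size, so injected plans are recoverable by
  construction — and draw adjacent-segment states from a 2- or 3-letter
  alphabet so that neighbours always differ; the switch count equals
  the breakpoint count exactly.
* BFB plans build strictly increasing terminal stairs with a NEUTRAL
  interior drop; stair widths are assigned terminus-outward so the
  start- and end-anchored plans are exact coordinate mirrors.
* Read sets mix background reads (uniform random sequence) with
  telomeric reads (phase-shifted repeat tandems, per-base substitution
  errors) in proportion telomere bases / (genome + telomere bases).
  Telomeric reads are pure repeat with no subtelomeric transition
  sequence, matching a tandem-repeat mapping target.
* Cohort simulation defaults encode the study contrast the package was
  built around: 16 heterozygous tumors with chromothripsis probability
  9/16, BFB probability 6/16, per-chromosome aneuploidy rate 0.2,
  focal CNV rate 0.1; 10 homozygous tumors with no complex events,
  aneuploidy rate 0.015 (a few gained/lost chromosomes per cohort) and
  focal rate 0.02. All randomness flows from one seed; identical seeds
  give byte-identical output.

What the generator does *not* emulate: microarray intensity artifacts
(GC waves, dye bias, spatial effects), probe-density variation,
subclonal mixtures and purity dilution, interstitial telomere-like
repeats, and indel or paired-end error models. Passing tests therefore
demonstrate correctness of the inference rules on data satisfying their
assumptions, not robustness to every artifact of real arrays or
sequencers.

# Numerical choices and degenerate inputs

* Amplification tiers are quantized as
  $2 + \lfloor (\text{mean} - \text{amp cut}) / 0.5 \rfloor$, i.e.
  anchored at the amplification cutoff. Stair detection therefore
  resolves amplification steps best when the cutoff sits just below the
  first amplification tier of the data (about 1.2 for a diploid
  background whose tiers start at 1.5); a cutoff placed mid-tier can
  put two neighbouring stair means into one tier and merge them. With
  the default `amp_multiplier = 5` and a noisy null this can happen —
  pass `amp_multiplier = 3` (or explicit thresholds) when amplification
  tiers matter.
* Segmentation ties (noise-free plateaus) resolve toward fewer
  segments via the penalty floor.
* A chromosome with fewer probes than `min_probes` becomes a single
  segment with a warning rather than an error.
* Empty read sets yield zero counts; zero non-telomeric reads make
  coverage (and hence length) an error rather than an infinity.
* An empty cohort table is a warning with an empty record list; a flag
  contradicting its affected-chromosome list is an error.
* Validation sizes: desk-scale simulations use 5 autosomes × 10 Mb at
  50 kb probe spacing (200 probes per chromosome), 100 noise-free
  genomes per event kind for closure, 200 null genomes for
  specificity, and a 3 × 3 × 20 grid (true lengths 20/50/100 kb —
  the reported rat telomere range — by coverages 0.1/0.5/1.3×) for
  telomere recovery with a 1 Mb genome and 8 ends. The telomere
  estimator is scale-free in genome size, so the scaled-down genome
  changes only the telomeric read fraction, not the estimand.

# Known limitations

* Detection is purely copy-number-signature based: no breakpoint-
  junction (split-read/discordant-pair) evidence, no statistical test
  of breakpoint randomness, no ploidy/purity estimation, and no
  allele-specific copy number — two-color ratio data carry no B-allele
  frequencies.
* The chromothripsis rule is the literal ≥10-switches/2–3-states
  criterion; it will miss events whose oscillation is diluted below 10
  detectable switches and cannot distinguish chromothripsis from other
  mechanisms producing oscillating profiles.
* Absolute telomere lengths depend on the configured end count and on
  the assumption that telomeric and genomic reads are sequenced with
  equal efficiency; between-group comparisons are the robust use.
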