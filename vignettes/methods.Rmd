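---
title: "Making cross-species microsatellite genotypes commensurable: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Making cross-species microsatellite genotypes commensurable: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthosat)
```

## The problem

Microsatellite genotypes are almost always recorded as PCR fragment lengths:
the length in base pairs of the product amplified by a locus-specific primer
pair. Within one species this is a serviceable proxy for the repeat count of
the embedded short tandem repeat (STR), because the flanking sequence between
the primers and the repeat array is effectively invariant. Between species it
is not: small insertions and deletions accumulate in the flanks, so a
chimpanzee fragment and a human fragment of the *same length* can carry
*different* numbers of repeats, and vice versa. Any statistic that matches
alleles by state — allele-sharing distance directly, and multi-allelic
F\_ST through its allele-frequency components — then misaligns orthologous
alleles in interspecies comparisons and overstates differentiation.

`orthosat` implements the full chain needed to detect, quantify and correct
this incommensurability for a panel of amplicon-typed microsatellites:

1. **In-silico PCR** (`scan_primer`, `demarcate_fragments`,
   `resolve_candidates`): locate each primer pair's target in a reference
   sequence and decide, per marker, whether the located fragment plausibly
   underlies the observed genotypes.
2. **STR detection** (`find_str_regions`, `harmonize_boundaries`): annotate
   the repeat structure embedded in each retained amplicon.
3. **Ortholog assessment** (`classify_ranges`, `assess_lengths`): compare the
   two species' observed fragment-length ranges and the placement of the two
   reference fragment lengths within them.
4. **Structure concordance and flank alignment** (`compare_structures`,
   `align_orthologs`): decide whether the two amplicons contain the same STR
   organization, and tabulate the non-STR nucleotides present in only one
   species — the quantity that breaks commensurability.
5. **Calibration** (`build_model`, `length_to_repeats`, `normalize_dataset`):
   convert fragment-length genotypes into repeat numbers against each
   species' own reference.
6. **Differentiation analysis** (`pairwise_fst`, `pairwise_dps`,
   `inflation_summary`): quantify how much the length representation inflates
   interspecies F\_ST and D\_PS relative to the repeat representation.

A synthetic-data generator (`make_ortholog_pair`, `simulate_genotypes`,
`make_study`) produces complete study bundles with known ground truth, so
every stage is testable end to end without external data.

## Models and rules, stage by stage

### Primer scanning

A primer hit is a local alignment of the primer against either reference
strand satisfying two acceptance thresholds: the alignment may be at most
10 nt shorter than the (genomic portion of the) primer, and at least 90% of
its columns must match. Identity is computed as matches divided by alignment
columns (gaps included). The alignment assessed on each diagonal is the
*score-optimal* window under match +1 / mismatch −1 — the window a local
aligner would report — not the longest window that happens to satisfy the
thresholds; otherwise padding a short exact match with mismatches could
manufacture acceptable "length".

By default a locus must also contain an exact-match run of at least 11 nt
(`min_seed = 11`), emulating the word-based seeding of the classic BLASTN
search that primer-mapping pipelines use in practice. Without seeding, a
reference of a few hundred kilobases scanned at the bare thresholds yields
occasional 10–12 nt chance windows at ≥90% identity; such phantom hits can
pair with a genuine reverse-primer hit and, through the overlap-resolution
rule below, displace the true amplicon and silently shift a locus'
calibration by whole repeat units. Setting `min_seed = 1` recovers the bare
two-threshold rule.

Non-genomic primer tails — the 7-bp "pig-tail" or the single extra adenine
used to stabilize product sizing — are excluded from the scan and from
alignment-length assessment; their lengths re-enter later as fragment-length
adjustments.

### Fragment demarcation and retention

A candidate amplicon runs from the 5′-terminal base of a forward hit to the
5′-terminal base of a reverse hit, counted inclusively, so the fragment
equals the standard PCR product spanning both primers. The inclusive (+1)
convention is isolated in `demarcate_fragments`; candidates longer than
2000 bp or in invalid orientation are discarded.

Retention follows a decision tree against the species' observed
fragment-length range `[g, G]` extended by 6 bp of slack on each side
(samples may not capture the full population range):

* no candidates → `rejected_no_hit`;
* exactly one candidate within the extended range → `retained`;
* several candidates within range that overlap and share the reverse-primer
  position → the smallest is chosen (`resolved_overlap`), on the assumption
  that the shortest template amplifies most efficiently;
* several in-range candidates without that structure → `rejected_multi_hit`;
* all candidates out of range → `rejected_length`, with the margin (bp
  outside the unextended range) reported.

The filter-then-resolve order matters: phantom fragments that fail the
length filter can never participate in overlap resolution.

The retention tree is applied to the species whose reference is being
screened (the chimpanzee side in the canonical study design); the other
species' fragment is taken as given — the candidate nearest its observed
range — and a marker is excluded only when no fragment exists at all.

### STR detection

An STR region is a run of at least `min_repeats` contiguous copies of a
2–6 nt motif. Detection enumerates every (start, unit size) candidate,
extends it maximally, discards motifs that are whole-number repetitions of a
shorter motif (so `ACAC` is always reported as `AC`, and homopolymers never
appear), and resolves overlapping candidates deterministically: longer span
first, then smaller unit size, then leftmost start. Any interruption of one
base pair or more terminates a region; flanking runs survive only if each
independently reaches `min_repeats`. Detection uses `min_repeats = 4` — the
empirical polymorphism threshold for 2–6 nt motifs — while interspecies
concordance scoring re-derives structures at `min_repeats = 2` so that
two- and three-repeat variants are visible.

Two abutting regions with different motifs (a compound repeat) are a legal
structure; spacers may therefore be zero, although the generator never
builds such loci.

Where two regions of one structure have rotationally equivalent motifs
(`ATCT`/`TCTA`), `harmonize_boundaries` re-phases later regions onto the
first region's motif when a phase shift supported by the sequence preserves
every repeat count — multiple regions frequently descend from one ancestral
array split by mutation, and a common motif is what lets repeat units pair
across species during alignment.

### Interspecies assessment

Markers whose two species' ranges are disjoint are excluded as possible
regressions or non-orthologs (their heterozygosities are still reported).
For overlapping ranges, a marker is accepted as orthologous when it meets
the first of three criteria: (i) both reference fragment lengths lie within
the intersection of the two ranges; (ii) a length lies outside its own
species' range but within the union; (iii) a length lies outside the union,
but the range overlap score is at least 0.289 and the offending length is at
most 6 bp outside the union. The ROS is implemented as intersection over
union of the closed bp intervals, counted inclusively (1 for identical
ranges, 0 for disjoint). The 0.289 default reproduces the data-driven rule —
the lowest ROS among criterion-(i) markers of the reference panel — and
`derive_ros_threshold` recomputes it for any panel.

### Flank alignment and the non-STR imbalance

`align_orthologs` aligns the two amplicons with the STR regions as anchors:
regions with identical (harmonized) motifs pair in order and align unit by
unit, surplus units of the longer array are gapped as whole units, and a
region split by a short (≤6 nt) interruption in one species pairs as a
single anchor group with the interruption bases aligned against gaps at
their genomic position. Flank segments between anchors are aligned globally
with affine gap penalties (match +1, mismatch −1, gap open −3, gap
extend −1 in `Biostrings::pairwiseAlignment` parameterization). Gaps stay
outside STR blocks by construction, and all indels are treated as insertions
in the fragment that carries them.

The **non-STR imbalance** — nucleotides outside either species' STR regions
present in only one fragment — is the alignment's headline number: it is
exactly the offset by which the length representation misaligns orthologous
alleles. The accounting identity
`length(chimp) − length(human) = chimp_only_total − human_only_total`
holds for every alignment and is asserted in the tests.

When anchor pairing fails (discordant motifs, unpairable region sets) the
aligner falls back to a plain global alignment and flags the marker
(`anchored = FALSE`); such markers are excluded from calibration anyway.

### Structure concordance classes

`compare_structures` classifies an amplicon pair as `identical` (same
regions, same motifs, all counts ≥ 4), `three_repeat_variant` or
`two_repeat_variant` (an order-paired region with exactly 3 or 2 copies in
one or both species), `disrupted_variant` (one region vs two separated by a
≤6 nt interruption — the footprint of a point or small indel mutation),
`discordant` (different motifs expanded at corresponding positions, or
unpairable region sets), or `no_str` (no regions at all in one species).
Only `identical` markers whose regions share a single repeat-unit size are
calibrated; three-repeat and disrupted variants are retained for diversity
analyses but not converted; two-repeat, discordant, no-STR and mixed-unit
markers are excluded from conversion.

### Calibration

For a marker with reference fragment length `L₀`, total reference repeats
`R₀` and unit size `u`, a genotype of length `L` converts to
`R = R₀ + (L − L₀)/u`, species by species — cross-species calibration is
refused, since species-specific flank differences are precisely what the
conversion corrects. When every converted value at a marker (pooled across
species) shares one non-zero decimal fraction — the signature of a small
constant inaccuracy in a reference sequence or in allele binning — all
values are rounded to the nearest integer (half away from zero; for unit
sizes ≥ 3 ties cannot occur, and at unit 2 only a 0.5 fraction ties).
Markers with several distinct fractions are left unadjusted and flagged.
Fractions are compared at a tolerance of 1e-9; the values are exact
rationals in floating point at these magnitudes.

Because the per-species map is affine and strictly increasing, every
within-species statistic that treats alleles as categorical states
(heterozygosity, allele counts, both pairwise statistics within a species)
is identical under the two representations. The interspecies statistics are
the only ones that can change — that is the entire point.

### Population-genetic statistics

Expected heterozygosity uses the sample-size-corrected estimator
`H_e = n/(n−1) · (1 − Σ pᵢ²)` over the `n` non-missing allele copies.
Pairwise F\_ST is the Weir–Cockerham (1984) θ with alleles as categorical
states: per pair of populations, the a/b/c variance components are computed
per allele per locus from allele frequencies, heterozygote proportions and
sample sizes, and combined across loci as a ratio of sums. Loci monomorphic
within a pair are skipped; negative estimates are reported as computed.
D\_PS is one minus the proportion of shared alleles: per locus the summed
minimum of the two populations' allele frequencies, averaged over loci with
data in both populations. Populations need at least 5 individuals.

`inflation_summary` reports, for every interspecies pair, the percent
reduction `100 (S_len − S_rep)/S_len` (pairs with `S_len ≤ 0` are skipped),
its maximum, mean and SD, the R² between matched entries of the two
matrices, a Wilcoxon signed-rank test on the interspecies entries, and —
when per-population distances are supplied — the Spearman correlation
between each human population's mean reduction and its distance from the
reference origin.

### Variability profiles and group comparisons

Nine per-marker, per-species measures: H\_e, number of distinct alleles,
variance, range and skewness (moment method, `m₃/m₂^{3/2}`) of the
repeat-number distribution, mean PCR fragment length, and mean, maximum and
minimum repeat counts. Distinct alleles and mean fragment length come from
the length representation, repeat measures from the repeat representation.
When one species has many more individuals, its measures are means over
1000 random draws matched to the smaller species' size (84 in the standing
conditions), removing the sample-size confound; draws are seeded and
bit-reproducible. Interspecies contrasts use the average relative difference
(ARD: mean of per-marker chimpanzee/human ratios) with Wilcoxon signed-rank
tests, within-species group contrasts the relative difference in means
(RDM: ratio of group means) with rank-sum tests, grouped by (number of STR
regions, unit size) with groups under 5 markers skipped. Outlier markers are
those whose `H_e(chimp) − H_e(human)` falls more than 2 SD (computed across
the full panel) below zero.

## The synthetic-data generator

The generator emulates the data-generating structure the analysis assumes:

* a **shared ancestral flank** on each side of the STR block, built
  base-by-base so that it contains no tandem of ≥2 copies of any 1–6 nt
  motif — detected STR structure is then exactly the constructed structure,
  which is what makes planted-truth recovery tests exact;
* **species-specific insertions** (1–32 bp, the scale of real flank
  divergence at such loci) planted in flank interiors, chimpanzee
  insertions in the left flank and human insertions in the right so that
  opposing insertions occupy different alignment segments and can never be
  paired away by the optimizer;
* **primer sites** as the exact flank ends (20 nt), mutable to exercise the
  scanning thresholds;
* optional **disruption** (a 1-nt interruption mid-array, using a base
  absent from the motif so no larger-unit tandem spans the junction) and
  **discordant motifs** per species;
* **multi-population diploid genotypes**: per species, base repeat-number
  frequencies follow a discretized double-geometric around the reference
  repeat count (decay 0.65 per repeat, support ±5) — the long-tailed,
  mostly-single-step allele spacing of stepwise-mutating loci; each
  population's frequencies are a Dirichlet draw around the species base
  with Balding–Nichols drift parameter F, and alleles are sampled i.i.d.
  Repeat numbers become fragment lengths through the species' own reference
  model, so planted flank insertions propagate into the length
  representation exactly as they would through a real sizing pipeline.

Genotypes are simulated at drift equilibrium rather than by forward-time
stepwise mutation: the analysis is agnostic to how population frequencies
arose, and equilibrium sampling gives closed-form recovery targets (the
Weir–Cockerham θ between populations drifted with parameter F estimates F,
which the tests verify at 100 loci and 10 populations of 50 diploids within
20% relative error).

### Standing study conditions

The default study (`study_config()`) mirrors the reference panel's shape:
138 concordant single-unit-size core loci — 31 trinucleotide and 86
tetranucleotide single-region loci plus 21 two-region tetranucleotide loci
(the panel's few three- and four-region loci are folded into the one-region
group; the generator builds one or two regions) — with a species
repeat-count offset of 2 (chimpanzee lower), a species-specific flank
insertion at about half the loci, 10 human populations on an
increasing-drift gradient (F from 0.02 in steps of 0.015) standing in for
distance from the expansion origin, and 5 chimpanzee populations at
F = 0.05, all of 20 diploids. A further 19 engineered markers exercise, one
each, every branch of the retention and assessment decision trees and every
concordance class, with their expected labels recorded in the bundle.

These sizes were chosen once as a desk-scale emulation of the study design;
they are also the problem sizes the test suite and the acceptance script
run at (the whole pipeline completes in a few minutes on one CPU).

## What passing tests do and do not show

The generator's flanks are repeat-free by construction and its indels are
clean insertions without flanking point mutations; real flanks contain
near-repeats, homoplasy and substitution noise that make hand or automatic
alignment genuinely ambiguous in places. Passing the planted-truth recovery
tests therefore shows the machinery is correct, not that alignment of real
amplicons is error-free. Similarly, equilibrium Dirichlet drift reproduces
the *mechanism* of length-based inflation — misaligned allele matching at
loci with flank offsets — but not the magnitude observed in real data:

* with insertions of 1–32 bp, most affected loci lose essentially *all*
  interspecies length-based allele sharing, so the simulated inflation
  (mean ≈ 30% for F\_ST) is far larger than the few-percent reductions seen
  in real panels where many offsets are small relative to allele ranges;
* the real positive correlation between a human population's distance from
  Africa and its F\_ST reduction rides on the accumulation of *private
  alleles* along the expansion; under equilibrium drift the absolute
  inflation is roughly constant across human populations while baseline
  interspecies F\_ST grows along the drift gradient, so the *relative*
  reduction decreases and the Spearman correlation comes out strongly
  negative. The sign of this correlation is a property of the demographic
  model, not of the correction machinery.

## Numerical choices and degenerate inputs

* Overlap resolution in STR detection, tie-breaking in primer-window
  assessment, and allele-pair ordering are all deterministic; identical
  inputs give identical outputs everywhere, and every source of randomness
  flows from an explicit seed.
* The identical-populations edge of the θ estimator sits at ≈ −1/(2n−1),
  not 0 (the among-population variance of literally identical samples is
  below its panmixia expectation); tests check the ≈0 property at n = 50.
* Wilcoxon tests follow `stats::wilcox.test` defaults — exact for small
  tie-free samples, normal approximation with continuity correction
  otherwise — with the paired variant forced to the approximation when
  zero differences are possible.
* Empty structures, monomorphic loci, missing genotypes (−9 or blank on
  read), and populations below the size threshold are all handled by
  explicit skips with the behavior asserted in tests.
* `run_study` aborts with the stage name and offending marker on any
  stage failure, and its disposition ledger conserves markers: every input
  marker appears exactly once with its fate and reason.

## Known limitations

* The inflation magnitudes and the distance trend are scenario properties
  (see above); only the mechanism and its zero-offset null (no indels →
  length- and repeat-based matrices identical entry-wise) are invariants.
* The generator does not plant substitutions in flanks, compound imperfect
  repeats, or allele-size homoplasy; mononucleotide runs and
  Tandem-Repeats-Finder-style scored imperfect repeats are out of scope.
* The ROS convention (inclusive bp intersection over union) is one of
  several in circulation; it is isolated in `range_overlap_score` and
  recorded in report metadata.
* θ is the Weir–Cockerham 1984 estimator; other F\_ST variants (AMOVA-style
  with haplotype distances, Nei's G\_ST family) would give numerically
  different inflation summaries. The estimator is a single function and can
  be swapped.
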