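---
title: "Probe-based microdiversity profiling along a pH gradient: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probe-based microdiversity profiling along a pH gradient: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limnodiv)
```

## The assay this package models

Reverse line blot hybridization (RLBH) resolves *microdiversity* — variation
below the genus or even species level — by hybridizing a labeled PCR
amplicon of the 16S–23S rRNA internal transcribed spacer (ITS) against a
membrane carrying many group-specific oligonucleotide probes at once. Each
probe targets a diagnostic ITS site of one genotype group; the read-out is a
per-probe signal strength scored ordinally: 0 (none), 1 (weak), 2 (normal),
3 (strong). Applied to environmental DNA from many habitats, the assay
yields a habitats × probes score matrix from which distribution patterns of
the probe-defined groups can be profiled along environmental gradients.

`limnodiv` implements the complete downstream analysis for such a survey of
the freshwater genus *Limnohabitans*: an 18-probe panel with its specific
ITS primer pair (forward Lim379F, biotinylated reverse LimCurvITS-R,
product ≈ 1,900 bp) and the universal outer pair (1406f/23Sr) for nested
amplification are shipped as packaged TSV resources.

## In-silico hybridization

`match_probe()` slides a probe over a target and reports every window with
at most `max_mismatches` mismatching positions. The degeneracy semantics
are asymmetric on purpose:

* a degenerate IUPAC letter in the **probe** (R, Y, M, K, …) matches any
  base of its set — panels are designed degenerate so one oligo covers
  several genotypes;
* an `N` in the **target** matches nothing by default — it is sequencing
  uncertainty, not a wildcard (set `target_n = "any"` to flip this).

Both strands are searched by default because the hybridized product is
denatured double-stranded DNA; antisense hits are reported in sense-strand
coordinates. All coordinates are 0-based, half-open. `in_silico_pcr()`
pairs forward sense sites with reverse antisense sites and keeps products
within a length window; nested PCR is expressed as composition (outer pair
first, inner pair applied to the outer product) rather than a special mode,
which keeps each step testable in isolation. `compute_coverage()`
aggregates matching into the panel-level summary (fraction of records hit
by ≥ 1 probe; mean targets per probe) at exact matching by default, the
appropriate setting for probe-design verification.

Melting temperatures are estimated either by the Wallace rule (useful for
analytic test cases) or, by default, a nearest-neighbor model with the
SantaLucia 1998 unified parameter set (0.25 µM oligo, 50 mM Na⁺, entropy
salt correction), averaging over all expansions of degenerate letters.
Reported panel Tm values were produced by an unspecified method, so the
package stores them but never asserts computed values against them.

## The gradient-profile algorithm

For one probe, `compute_profile()` turns scores plus habitat pH into a
normalized relative-intensity curve:

1. bin habitats into pH classes of width 0.2 (edges anchored at pH 0,
   half-open `[lo, hi)`, so 7.0 falls in `[7.0, 7.2)`);
2. sum the ordinal scores within each class (`raw_sums`);
3. divide by the probe's total score over all habitats (`fractions`, which
   sum to 1 across classes);
4. divide by the maximum fraction (`normalized`, so the best class reads
   exactly 1);
5. smooth with a centered 7-value gliding average (middle ± 3).

Design choices where the procedure is underdetermined:

* **Bin anchoring.** Edges are anchored at pH 0 so class boundaries are
  reproducible numbers (7.0, 7.2, …) rather than data-dependent.
* **Empty classes** between the observed pH extremes are kept with value 0;
  otherwise the gliding average would be undefined across gaps.
* **Edge handling.** The default `shrink` policy averages only the
  positions that exist near the series ends (a 4-value mean at the first
  class); mirror-padding is available as `edge_policy = "reflect"`.
  Profiles with fewer occupied classes than the window are smoothed with
  the widest legal odd window.
* **Order of operations.** The series is normalized first and smoothed
  second; the smoothed curve therefore lies within the range of the
  normalized one (an invariant the tests enforce).
* **No per-class habitat correction.** Class sums are not divided by the
  number of habitats per class; densely sampled pH regions therefore weigh
  more, matching how such surveys are conventionally summarized.

## Distribution-shape classification

Survey papers classify profile shapes by eye; `classify_distribution()`
makes the rule explicit and parameterized. Peaks are local maxima of the
smoothed series at or above `peak_threshold` (default 0.5) of its maximum;
peaks closer than `min_separation` (default 1.0 pH unit) are merged, the
higher surviving. Then:

* ≥ 2 peaks separated by a genuine valley (smoothed minimum between them
  below the peak threshold) → `bimodal`, the classic signature of hidden
  ecological heterogeneity within one probe-defined group;
* peaks without a separating valley over a widely occupied profile
  (> 60 % of classes at ≥ 0.25 of the maximum) → `broad` — a flat noisy
  curve should not be declared two-peaked;
* one peak → `broad` if occupancy exceeds 60 %, otherwise `acidic`
  (peak < 6.5), `alkaline` (peak > 7.5) or `circumneutral-narrow`;
* total score 0 → `undetected`.

The 0.5/1.0/60 %/0.25 constants are exposed arguments; defaults were fixed
once from the geometry of the archetypes (a valley between optima 5.5 and
8.5 drops essentially to zero; a σ = 2 generalist stays above a quarter of
its maximum across most of the 3.8–9.1 range) and are not tuned per
dataset.

## Richness and overlap statistics

Detection means score ≥ 1. `cooccurrence_histogram()` counts habitats by
number of groups detected; `richness_by_ph_class()` summarizes mean ± SD of
that count within explicit pH classes (default breakpoints 3.8, 4.8, 5.8,
6.8, 7.8, 9.1 — roughly one-unit classes; half-open, except the last class
closes at the top so the gradient maximum is kept; SD uses the n−1
denominator and is reported missing for single-habitat classes).
`richness_split()` gives the headline acid/alkaline contrast at pH 7, the
boundary habitat going to the upper class. Printed percentages use half-up
rounding to one decimal — `percentage(15, 161)` is 9.3 — because that is
how such tables are conventionally rounded; base R's round-half-even would
disagree on exact halves. `pairwise_overlap()` reports shared-habitat
counts, a Jaccard (or shared-count) index, and a complete-separation flag:
two groups each detected somewhere but never together.

## Distance matrices, Mantel, PCA, clustering

`community_similarity()` compares habitats on their 18-element 0/1
detection profiles. Simple matching (fraction of probes agreeing, absences
included) is the default; legacy workflows derived profile similarity with
sequence-alignment tooling applied to an encoding of the profiles, which is
not a well-defined matrix operation, so the simple-matching default is a
documented stand-in and Jaccard is available where shared absences should
not count. `geo_distance()` has two modes: `great-circle` (haversine,
radius 6,371,000 m) for general use, and `equator-1d`, which reproduces a
legacy transform that collapses each habitat to its distance from the
equator (latitude × 111,319.49 m/degree) and discards longitude — kept
because published distance-decay analyses used exactly this 1-D reduction,
and the package must be able to mirror it.

`mantel()` correlates lower triangles and permutes one matrix's labels
jointly over rows and columns. The sampled p-value uses the add-one
estimator (count + 1)/(N + 1), which can never be zero and makes the test
exactly calibrated at nominal level for continuous statistics; tails
two-sided (default), one-sided-positive, or one-sided-negative (the
distance-decay direction when testing community similarity against
distance). For n ≤ 8 an exhaustive mode evaluates all n! relabelings and
returns the exact permutation p. `pca_binary()` is a centered (optionally
scaled) PCA of the detection matrix with a deterministic sign convention
(largest-magnitude loading positive per axis). Redundancy analysis with
forward selection is deliberately out of scope; the PCA plus per-probe
covariate correlations cover the ordination needs of this pipeline.
`cluster_probes()` groups probes by occurrence similarity — average-linkage
hierarchical clustering on correlation distance, cut at k = 4 by default —
with lexicographic pre-ordering so ties break deterministically; probes
with zero occurrence variance cannot be placed and are returned separately.

## The synthetic-data generator

Because the survey's raw samples are not redistributable, every stage is
validated against seeded synthetic data with exported ground truth.

* `generate_habitats()` emulates a Central-European standing-freshwater
  survey: pH is a mixture of a uniform background over 3.8–9.1 (half the
  habitats) and two bumps at 4.8 ± 0.6 (humic/acidic ponds) and 8.0 ± 0.6
  (hardwater ponds), a quarter each; conductivity is log-normal increasing
  with pH; absorbance (a DOC proxy) decreases with pH and depresses oxygen;
  altitude and temperature are independent; coordinates sit in an
  Austria/Czech-like box with mild clustering of acidic vs alkaline
  habitats so that community similarity can decay with distance.
* `generate_scores()` draws each group's latent suitability from a Gaussian
  niche curve `f(pH) = A · max_j exp(−(pH − µ_j)²/(2σ²))` (bimodal niches
  are a max, not a sum, so A stays ≤ 1), adds Gaussian noise (SD 0.1) and
  thresholds at 0.25/0.5/0.75 into scores 1/2/3, plus a small Bernoulli
  baseline (1 %) of spurious weak detections. The default 18-group panel
  mirrors the archetypes such surveys report: mostly alkaline optima, one
  acid specialist, several bimodal groups with optima near 5.5 and 8.5, a
  strong narrow circumneutral group, one σ = 2 generalist, and four probes
  that never fire (amplitude 0).
* `generate_sequences()` plants one concrete expansion of the forward
  primer at the start, the reverse complement of the reverse primer at the
  end (~1,900 ± 25 bp records, so in-silico PCR recovers one full-length
  product) and exactly one expansion of the group's probe internally.

What the generator does **not** emulate: triplicate-assay noise structure
(inputs are treated as already averaged), probe cross-hybridization beyond
the flat baseline rate, signal-intensity compensation chemistry, and any
taxonomic structure in the background sequence. Green tests therefore
demonstrate that the pipeline recovers what this generative model plants —
not that real membranes are free of cross-reactions.

## Numerical choices and validation sizes

* pH binning divides with a 10⁻⁹ guard so values sitting exactly on an edge
  (7.0/0.2) land in their upper class despite floating-point division.
* Fractions conserve to 1 within 10⁻¹²; the normalized maximum is exactly 1
  (the maximum divided by itself); smoothed values stay inside the
  normalized range.
* Mantel permutations are generated from an explicit seed and evaluated by
  index lookup into the lower triangle, keeping 999 permutations at n = 20
  around 20 ms.
* Validation sizes, chosen to characterize behavior well at interactive
  cost: oracle equivalence of window matching on 1,000 random probe/target
  pairs at 0 and 1 mismatches; profile invariants on 200 random score
  matrices; niche-optimum recovery (µ = 6.0, σ = 0.3) on 100 replicates of
  300 habitats, requiring the argmax class within ±0.2 pH of µ in ≥ 95 %;
  bimodal classification of the 5.5/8.5 archetype on 50 replicates of 161
  habitats, requiring ≥ 90 %; Mantel type-I error over 1,000 null
  replicates of 999 permutations, requiring 0.05 ± 0.02.

## Known limitations

* Coverage of a real culture collection requires the user to supply the
  ITS FASTA; the package validates its coverage arithmetic against planted
  synthetic collections only.
* The simple-matching similarity is a stand-in for an alignment-derived
  encoding that is not reproducible as a matrix operation; Mantel r values
  on real data are therefore comparable in sign and rough magnitude, not
  digit-for-digit.
* Shape classification inherits the subjectivity of its thresholds; they
  are explicit and logged, but a different parameterization can relabel
  borderline broad/bimodal profiles.
* The ordinal score model (thresholds 0.25/0.5/0.75, noise SD 0.1) is an
  invented but exported convention; parameter-recovery results quantify the
  pipeline under this model, not under membrane chemistry.
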