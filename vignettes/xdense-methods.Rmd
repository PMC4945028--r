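---
title: "Methods: repeat density, motif scanning, and binding models in xdense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat density, motif scanning, and binding models in xdense}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xdense)
```

`xdense` analyses how GA dinucleotide repeats and GA-rich binding motifs
are distributed over a genome, and how they relate to the binding of a
GA-recognising zinc-finger protein measured in vitro (protein-binding
microarrays, PBMs) and in vivo (ChIP-seq coverage and peaks). This
vignette records the models, the parameter choices and their rationale,
the numerical conventions, and what the synthetic-data tests do and do
not establish.

## Coordinates and input conventions

All interval arithmetic is 0-based half-open (the BED convention), so BED
files round-trip byte for byte; GFF3 gene rows are converted on read by
subtracting 1 from the start. A gene's TSS is `start` on the + strand and
`end - 1` on the - strand. The center of an even-width peak is the floor
of its midpoint — an arbitrary but deterministic tie-break. Chromosome
class labels (`X`, `autosome`, `other`) come from an explicit YAML
side-car rather than name matching: arm naming differs across species,
and the set of chromosomes entering a density denominator should be an
auditable choice, not a guess. `N` bases are legal in genomes; they never
match a motif or extend a repeat run, but they stay in density
denominators (assembly gaps shrink the effective sequence, and keeping
the denominator at the nominal length is the simpler, stated convention).

## PBM probe analysis

Probes are classified PBM+ when their median replicate intensity is
*strictly greater* than the threshold (default 6500 fluorescence units, a
value between the two modes of a bimodal intensity histogram); the
boundary value itself is PBM-, following the "higher than" phrasing
literally. `find_bimodal_threshold()` recovers such a threshold from
data: a Gaussian kernel density (Silverman's rule-of-thumb bandwidth) on
log2 intensities, the minimum between the two highest modes, reported on
the original scale. Two guards make the failure mode explicit rather than
silent: local maxima below 5% of the global density maximum do not count
as modes (kernel estimates of unimodal data show negligible tail
wiggles), and the valley must dip below 95% of the smaller mode.

All intensity transforms use log2. The source analyses say only
"logarithmic"; one base had to be fixed, log2 is the genomics default,
and every downstream quantity (mixture means, regression responses) is
documented in log2 units.

The two-component Gaussian mixture is fitted by plain EM: initialisation
from the empirical median split (deterministic), convergence when the
absolute log-likelihood change falls below 1e-8, a cap of 500 iterations
reported with a warning on non-convergence, and component standard
deviations floored at 1e-6 to avoid degenerate spikes. Means are reported
in ascending order; "strongly bound" means a posterior probability of at
least 0.95 for the higher-mean component. Zero-variance input is an
error, not a fit.

Motif-similarity classification keeps the published asymmetric cutoffs:
best scan p-value below 1e-4 is `MRE+`, above 1e-3 is `MRE-`, and the gap
(1e-4, 1e-3] is returned as `ambiguous` — the source defines both classes
but leaves the gap unlabelled, and silently assigning it either way would
bias downstream contrasts.

Intensity quantiles: `q1` is the *highest*-intensity quantile, sizes
differ by at most one, ties go to the lower-index quantile with input
order as the final tie-break, so the split is deterministic.

## Minimal-motif flank scan

Bound and unbound probe sequences are each aligned to the core PWM
(best-scoring offset/strand; ties: smaller offset, then + strand). For
every extension `(a, b)` with `0 <= a <= max5`, `0 <= b <= max3`, the
`(a + w + b)`-mer around each core match is extracted in motif
orientation, and

```
overlap(a, b) = 100 * |distinct bound k-mers also seen in unbound| /
                      |distinct bound k-mers|
```

The minimal window is the zero-overlap cell minimising `a + b`, ties
broken toward the smaller 5' extension. Distinct-type counting is the
default because it is order-independent and matches the idea of
"sequences shared between the sets"; per-probe token counting is
available (`level = "token"`). Sequences too short for a given extension
are dropped from that cell only, with per-cell drop counts reported.
The overlap matrix is checked for monotone non-increase along both axes;
this holds whenever bound k-mer diversity grows no faster than
separation (always true for the consensus-flank design), and a violation
is reported as a warning because it signals exactly that assumption
failing, not an arithmetic error.

## PWM scanning with exact p-values

Scores are log-odds in bits against the PWM's background (uniform by
default; a genome-derived mononucleotide background can be supplied when
building the PWM — uniform is the reproducible default since the original
scan's background is not printed). A small frequency increment (0.01) is
added at scoring time so log-odds stay finite; PWMs built from sequence
sets default to a 0.5 pseudocount.

P-values are exact for the *discretised* score: per-position scores are
rounded to a grid of 1/1000 bit, the full distribution of the gridded
window score under the background is built by dynamic programming
(convolving the four-letter distribution position by position), and the
p-value of a window is the tail mass at its own gridded score. Because
scanner and p-value table share the grid, the DP tail equals the
exhaustive enumeration over all 4^w k-mers exactly — the test suite
asserts bitwise agreement up to width 8. The discretisation can only
move a score by at most `w/2000` bits, so the p-value error is bounded by
the background mass within that sliver of the threshold; at the default
grid this is negligible compared with any threshold used in practice.

## Sequence + shape regression

Aligned equal-length sequences are encoded as indicator blocks: 4 columns
per position (1mer), 16 per adjacent pair (2mer), 64 per triple (3mer).
Shape features contribute 4 columns (MGW in Angstrom, ProT, Roll, HelT in
degrees) per position with full pentamer context (positions 3..L-2);
edge positions are dropped rather than padded because padding conventions
vary and silently invent context. Shape columns are z-scored per feature
by default so their scale matches the indicators under a single ridge
penalty.

The ridge model minimises `||y - Xw - w0||^2 + lambda ||w||^2` with an
unpenalised intercept, solved by the normal equations on centered data —
deterministic, and exact for these column counts. A singular design with
`lambda = 0` is an explicit error. Cross-validation uses a seeded
shuffle into 10 folds; R² is the squared Pearson correlation between
held-out predictions and responses (the phrasing "R² between predicted
and experimental intensities" describes a correlation; the
`1 - SS_res/SS_tot` form is available via `r2 = "ss"`). When no penalty
is fixed, lambda is chosen per training split by inner 5-fold CV over a
log grid 10^-4..10^4 (17 points). Model *comparisons* share one fold
assignment across encodings and report paired t and Wilcoxon tests plus
the relative gain in percent; the package's own comparisons fix a single
moderate penalty for all encodings so that differences reflect the
feature families rather than per-model tuning, at the cost that a richer
model can show a slightly negative gain on data its extra features cannot
explain — which is precisely the "marginal gain" pattern the comparison
is meant to expose.

## Repeat runs and densities

A repeat run is a maximal in-phase tandem of a short unit: `"AGAGAG"`
contains a (GA)2 run plus flanking single letters, and scanning every
phase guarantees the longest in-phase run is found. GA and TC (the
reverse-complement unit) are pooled by default because a repeat tract is
a strand-symmetric genomic feature; a forward-only flag exists, and
palindromic units are scanned once. Two counting conventions are
implemented because both appear in published accounting: `maximal`
(a run of n units counts only at length n) and `cumulative` (it counts at
every k <= n). Densities are counts per Mb (1e6 bases), N included in the
denominator; the pooled X:A ratio is
`(sum X counts / sum X Mb) / (sum autosome counts / sum autosome Mb)`
per repeat length, with per-arm variants. Ratios whose autosomal count is
zero are reported as absent (`NA`), never infinity.

Exact-consensus motif hits are counted greedily left-to-right without
overlap, on both strands; greedy counting is deterministic and avoids
inflating counts for self-overlapping consensi, and the PWM-threshold
mode exists because the published "exact match" unit is ambiguous
between the two.

## Landscape statistics

Neighbour distances are midpoint-to-midpoint between peaks of the same
category on the same chromosome; `dbar(n)` per site is the mean distance
to its n nearest neighbours, and the category value averages over sites
(sites with too few neighbours are excluded from that n, with counts).
Normalisation divides by the *median* over 10 randomized sets that
preserve per-chromosome, per-category counts with uniform placement — no
mappability masking, since the randomisation only needs to calibrate the
count-dependence of nearest-neighbour distances. CES proximity uses the
median n=1 distance among X peaks as its reference radius (the
"median distance value of the X chromosome" does not fix n; n=1 is the
natural and configurable choice).

Metagene profiles rescale each gene to unit length and span [-1, 2] gene
lengths around it (one length upstream of the TSS to one downstream of
the TTS), flipping minus-strand genes; a feature may be counted once per
overlapping gene window (deduplication would silently privilege one gene
of an overlapping pair). Per-bin values are `count / (n_genes *
bin_width)`, so total mass times bin width equals incidences per gene —
a conservation law the tests assert. Body:5' ratios pool hits and widths
across the genes of a group: body `(TSS + 250 bp, TTS]`, 5' end
`TSS ± 250 bp`; a group with an empty 5' window yields `NA`.

Locus enrichment is `((chip + 1) / chip library) / ((input + 1) / input
library)` with library = total track mass; the pseudocount keeps
zero-input loci finite and its effect shrinks as loci grow. Note that
library normalisation discounts planted enrichment itself: with a
fraction f of the genome enriched m-fold, the recoverable per-locus value
is `m / (1 + f (m - 1))`, and the tests compute that expectation rather
than pretending the dilution away.

The two-sample KS test reports `D = sup |ECDF_a - ECDF_b|` with the
asymptotic Kolmogorov p-value evaluated at
`(sqrt(ne) + 0.12 + 0.11/sqrt(ne)) D`, `ne = nm/(n+m)` — the standard
effective-n correction. The plain `sqrt(ne)` asymptotic is noticeably
conservative at moderate n (its exact size at n = m = 100 and nominal
0.05 is 0.036), while the corrected version is calibrated (0.054);
small samples without ties (`min(n, m) <= 25`) use the exact
distribution. Across many pairwise comparisons p-values are reported raw,
with an optional Benjamini-Hochberg column left to the caller.

## What the synthetic data emulates — and what it does not

Every generator is a pure function of (config, seed); a root seed fans
out to per-generator child seeds through a documented string hash, so
regenerating one artifact never perturbs another, and rerunning with the
same seed is byte-identical.

* `generate_genome` plants exact numbers of maximal (GA)k runs (k >= 2)
  on uniform background, spaced at least 4 bp apart, and then mutates the
  background until no unplanned run of 2+ units of any planted unit (or
  its reverse complement) remains. Without this scrubbing a 1-Mb uniform
  chromosome would carry roughly 2e6 * 4^-4 / 2 chance (GA)2+ runs and
  exact closed-loop recovery would be impossible. Consequently planted
  densities are meaningful for k >= 2 only; single-unit counts are
  background-dominated by construction. CES are disjoint windows that can
  concentrate extra runs.
* `generate_probe_set` builds 36-nt variable regions (core at position
  15, mimicking the fixed-position design of genomic-context PBMs) inside
  60-nt probes with a constant 24-nt primer. Bound probes carry 4 + 3
  consensus flank bases around the core; unbound probes draw flanks
  uniformly, rejecting any draw reproducing both consensus flanks at
  once, and rejecting contexts in which the core does not match uniquely.
  Two decoy unbound probes — copies of bound probes differing only at the
  outermost 5' (or 3') flank base — pin the zero-overlap region of the
  flank scan to `a >= 4 and b >= 3` *deterministically*: with purely
  uniform flanks at n = 200 the sub-threshold cells would often be empty
  by chance and the minimal window ill-defined. Intensities are
  `base + effect * min(n_units, 10) + noise` per replicate (defaults:
  unbound base 3000, bound base 7000, effect 400, noise sd 300
  fluorescence units), which yields the bimodal log-intensity histogram
  and the plateau at 10 repeat units that the analyses expect.
* `generate_peaks`, `generate_genes`, `generate_coverage` produce uniform
  or CES-clustered peak midpoints, non-overlapping log-normal genes
  (median ~2 kb), and Poisson-binned coverage with planted multipliers.
  Coverage emulates tag counts after alignment; read-level artifacts
  (mappability, duplicates, fragment-length effects) are outside the
  model.
* `generate_shape_table` is *synthetic*: structurally valid (all 1024
  pentamers, plausible ranges — MGW 2.8-6.2 A, ProT -17-0, Roll -8-8,
  HelT 30-40 degrees) but with no relationship to real DNA structure. It
  tests plumbing and leakage (random shape values must not beat sequence
  features), not shape biology.

Passing the closed-loop tests therefore shows the estimators recover
known truth under idealised conditions — clean bimodality, exact planted
runs, uniform background, Poisson noise. It does not show robustness to
array spatial artifacts, imperfect/interrupted repeats, assembly
collapse of repeat tracts, or non-uniform genomic background; all of
those remain the user's responsibility when moving to real data.

## Problem sizes used in tests and the acceptance script

The test suite and `scripts/acceptance.R` run on desk-scale data chosen
to make each statistical check well-powered while staying quick to
verify: 1-Mb synthetic chromosomes (30 vs 10 planted runs per Mb), 200 +
200 probes for the flank scan, n = 5000 for mixture recovery, n = 3000
probes of length 36 for the regression comparison (with a fixed ridge
penalty of 10 across encodings), 400 peaks per 5-Mb chromosome with 30
CES for clustering, 2000 null simulations for KS calibration, and
exhaustive scanner enumeration up to width 8 (65,536 k-mers). These sizes
are the package's own study conditions; scaling any of them up changes
tolerances, not conclusions.

## Known limitations

* Repeat detection is exact-tandem only; mismatch-tolerant or
  interrupted repeats need a dedicated tandem-repeat finder.
* The scanner's p-values are exact for the gridded score, not the real
  score; at 1/1000 bit this is far below any practical threshold, but a
  coarser grid trades accuracy for table size.
* `occupancy_by_motif_class` and `locus_enrichment` consume bedGraph step
  functions; BAM/bigWig ingestion is out of scope by design.
* The EM mixture fits exactly two components; truly multimodal intensity
  distributions should be split upstream.
* Overlapping genes double-count features in metagene profiles by
  default (documented above); a deduplicating mode is the alternative.
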