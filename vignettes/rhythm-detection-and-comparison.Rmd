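---
title: "Detecting and comparing diurnal transcriptome rhythms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and comparing diurnal transcriptome rhythms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmcomp)
```

## The problem

A diurnal transcriptome experiment samples a tissue repeatedly across the
light/dark cycle — here the canonical design is a 48 h time course sampled
every 4 h, giving 12 timepoints at ZT0 through ZT44 (ZT = Zeitgeber Time,
hours since lights-on) — and asks three questions:

1. Which transcripts are rhythmic, and with what phase (peak time), period,
   and waveform shape?
2. How well do two detection algorithms with different assumptions agree?
3. How similar are the rhythmic programmes of two datasets (another tissue,
   developmental stage, or species), both as gene sets and as phase
   relationships?

`rhythmcomp` implements the full chain: two complementary detectors,
circular phase statistics, transcript-to-gene and ortholog collapsing, and
set/phase comparison, together with a synthetic-data generator that provides
ground truth for validation.

## Detector 1: model-based pattern matching

The pattern-matching detector fits every gene against a library of candidate
waveforms. The library crosses five shape families — cosine, spike (one
timepoint high), box (high for half a period), rising ramp, falling ramp —
with all 24 integer phases at a fixed 24 h period, giving 120 patterns on
the standard grid. Each gene is scored against each pattern by ordinary
least-squares regression; the score is the signed Pearson correlation *r*,
and only positive matches are eligible.

A gene is called rhythmic when its best *r* clears the detection rule. The
default rule is the conjunction of two criteria:

* a fixed correlation cutoff of **0.81**, and
* a permutation-calibrated threshold: the time labels of every row are
  independently shuffled, the best-pattern correlation recomputed, and the
  95th percentile of the pooled null correlations taken, so that roughly the
  top 5% of comparable noise would pass.

The conjunction is the stricter reading of combining a printed cutoff with a
top-percentile rule; `mode = "cutoff"`, `"permutation"` and
`"top_fraction"` expose the individual readings. An amplitude/fold-change
filter exists (`min_fold`) but is off by default.

Ties between patterns with equal *r* are broken by shape order and then the
lower phase, so results are deterministic. Because the statistic is a
correlation, calls and phases are invariant under per-gene affine transforms
`y -> a*y + b` with `a > 0`.

One degeneracy is worth knowing about: for spike-shaped genes the
permutation null is uninformative, because shuffling the time labels of a
one-point spike produces another perfect spike and the null best-correlation
saturates near 1. The fixed cutoff carries the detection in that regime;
this is an intrinsic property of any pattern library closed under time
permutation, not an implementation artefact.

## Detector 2: nonparametric concordance (Kendall) test

The second detector is rank-based. For each candidate (period, lag) a
reference cosine is evaluated on the grid and the gene is scored by
Kendall's S:

$$S = \sum_{i<j} \mathrm{sign}(y_j - y_i)\,\mathrm{sign}(r_j - r_i),$$

where pairs tied in either vector contribute 0. The period lattice holds
every multiple of the sampling interval inside [20, 28] h — on a 4 h grid,
{20, 24, 28} — and the lag lattice has one lag per timepoint step within
each period (18 combinations in total). The combination maximising |S| wins;
a negative best S is a rhythm in antiphase to its reference, so the reported
phase is the lag plus half a period.

The p-value is exact, not asymptotic. Under the null the observed series is
an exchangeable random ordering, and S is distributed as the
Jonckheere–Terpstra statistic for the reference's tie-group structure: with
groups of sizes $n_1, \dots, n_g$, $S = M - 2k$ where $M$ is the number of
reference-untied pairs and $k$ the number of inversions of a random multiset
permutation. The inversion distribution is the product of Gaussian-binomial
generating functions, computed by polynomial convolution (Pascal recurrence)
and cached per tie structure. The two-sided p-value
$P(|S| \ge |S_{obs}|)$ is Bonferroni-adjusted by the number of (period, lag)
combinations, and genes with adjusted p below 0.05 are called. Bonferroni is
conservative, so the realised false-call rate on pure noise sits below the
nominal level.

The null distribution assumes no ties in the observed series. Simulated and
continuous-valued expression data satisfy this with probability one;
integer-valued input would make the test conservative, which we document
rather than correct.

## Circular phase statistics

All phase arithmetic lives on the 24 h circle.

* **Circular mean**: phases map to unit vectors at angle $2\pi h/24$, the
  vectors are averaged, and the mean direction maps back to hours. This
  automates the dawn correction — the mean of ZT2 and ZT22 is ZT0, not ZT12.
  A perfectly antipodal set has no mean direction; the smaller input phase
  is returned with an explicit tie flag.
* **Phase distance**: the shorter arc, with the complementary interval
  ($24 -$ distance) attached — e.g. cluster means at ZT1.6 and ZT12.7 are
  11.1 h apart one way and 12.9 h the other.
* **Pair adjustment for correlation**: when two matched phases differ by
  more than 12 h, 24 h is added to the smaller one, extending the scale past
  24 so that a (ZT23, ZT1) pair correlates as a 2 h difference. The
  squared Pearson correlation of adjusted pairs is the reported R².
  A caveat discovered by Monte Carlo: the adjustment itself induces
  positive association, so *independent* uniform phases score around 0.38
  rather than 0. The R² is therefore a comparative score (matched tables
  approach 1), not an absolute one, and its null floor should be kept in
  mind when interpreting moderate values.
* **Agreement fraction**: the share of matched pairs within a window,
  evaluated by default at the 4 h sampling interval.
* **Contour grid / histograms**: 2-D and 1-D phase histograms with
  half-open bins labelled by their lower edge; grid marginals equal the 1-D
  histograms by construction.

## Collapsing and set comparison

Transcript-level calls collapse to genes through a user-supplied mapping
table (many-to-many allowed; a transcript contributes to every gene it maps
to). Merged phases use the circular mean; when members disagree on period or
shape the modal value wins, with ties resolved toward the pattern-matching
entry and then the lower period — a documented package decision, since no
convention is standard. Ortholog mapping is the deduplicated union of
targets, with unmapped and multi-mapped counts reported. Mapping tables are
files, never live database queries, so analyses are hermetic.

Gene-set similarity uses the Tanimoto-Jaccard index scaled to 100,
$100 \cdot |A \cap B| / |A \cup B|$, rounded half-up to one decimal. A
size-based overload (`jaccard100(|A|, |B|, n_common = |A∩B|)`) exists so
printed set sizes can be checked without membership lists. Tissue
specificity bins genes by presence count across a 12-dataset panel:
specific (1-3 datasets) versus common (≥ 4, configurable).

## The synthetic-data generator

`generate_dataset()` draws, per rhythmic gene, a shape (weight table), a
period from {20, 24, 28} h, a phase (uniform or a mixture of wrapped-normal
clusters), and builds `baseline + amplitude * waveform + N(0, noise_sd)`;
arrhythmic genes are baseline plus noise. Defaults emulate the liver-style
experiment: 12 timepoints at 4 h, 11% rhythmic (matching the reported
union fraction of rhythmic transcripts), amplitude 1 against noise SD 0.2,
cosine-dominated shape weights with minority spike/box/ramp cohorts.
`generate_comparative_scenario()` builds two datasets with an exact Venn
partition of rhythmic sets and a controlled phase shift of the shared
cohort.

What the generator does **not** emulate: probe-level microarray noise,
RMA normalisation artefacts, autocorrelated or heteroscedastic noise, batch
effects, or amplitude distributions. Passing tests therefore demonstrate the
statistical machinery under clean i.i.d. Gaussian conditions, not
performance on raw array data.

Waveform conventions are fixed and tested: the cosine peaks at its phase;
the spike occupies the single grid residue nearest the phase (ties to the
earlier residue); the box occupies the half-open interval
[phase, phase + period/2); ramps reset at the phase. The box convention
makes grid membership unambiguous. On a 48 h grid the column-permutation
property under phase rotation holds exactly for 24 h periods (the grid
covers whole cycles); 20 and 28 h periods tile the 48 h span unevenly, so
rotation is only residue-wise there.

## Numerical choices

* Circular means snap results within 1e-9 of 24 back to 0, so boundary
  cases print as ZT0 rather than ZT24.
* Reference cosines are rounded to 9 decimals before ranking so that
  symmetric values (e.g. ZT0 vs ZT24 of a 24 h cosine) form exact tie
  groups.
* Constant expression rows have correlation defined as 0 (never called) and
  contribute S = 0 to every reference (never called); constant model
  patterns are dropped from the library with a warning.
* Indexes and percentages round half-up, matching how such values are
  conventionally printed; `round()`'s banker's rounding is deliberately
  avoided.
* The permutation threshold is seeded and reproducible; it is invariant to
  row order only up to Monte-Carlo error, since the draws are consumed in
  row order.
* Exact-null computation is guarded to n ≤ 60 timepoints; coefficients stay
  exactly representable in doubles at the series lengths used here.

## Problem sizes

The bundled analyses and tests run at deliberately modest scale — 2,000
genes in the simulated detection study, 1,000-gene null panels for error
control, 300-gene panels for phase-recovery measurement, 200 permutation
rounds — sizes at which the Monte-Carlo bounds asserted by the test-suite
are stable across seeds while the whole suite stays fast.

## Known limitations

* The pattern library is fixed at a 24 h period; short/long periods are the
  concordance test's job, mirroring the complementary strengths of the two
  algorithms (pattern matching contributes shape diversity, the rank test
  contributes period range).
* The phase resolution of the concordance test is its lag lattice (the
  4 h sampling interval); the pattern library resolves 1 h.
* QuantiGene-style normalisation follows the stated order of operations
  (average technical replicates, subtract background, divide by the
  same-sample reference gene); plate-wise scaling interactions beyond that
  are out of scope, and the trough/acrophase comparison takes explicit
  timepoint sets rather than inferring them. Welch's t-test is used; the
  equal-variance variant can be compared externally.
* Harmonic (12 h) rhythms, amplitude estimation, and multi-period pattern
  libraries are out of scope.

## A worked micro-example

```{r}
spec <- synthetic_spec(n_genes = 200, frac_rhythmic = 0.3,
                       noise_sd = 0.2, seed = 42)
d <- generate_dataset(spec)
out <- run_detection(d$tc, default_config(n_perm = 100, seed = 1))
out$report$haystack
out$report$jtk
out$report$union
```

```{r}
circular_mean(c(2, 22))          # dawn-corrected average
phase_distance(1.6, 12.7)        # shorter arc + complement
jaccard100(2609, 2882, n_common = 489)
```
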