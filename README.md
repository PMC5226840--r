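# rhythmcomp

Rhythm detection and comparative analysis of diurnal transcriptome time
courses.

## What it is for

Diurnal/circadian profiling experiments sample a tissue across the
light/dark cycle — typically 48 h at 4 h resolution, 12 timepoints ZT0–ZT44
(ZT = Zeitgeber Time, hours since lights-on) — and ask which transcripts are
rhythmic, when they peak, and how the rhythmic programme compares across
tissues, stages, or species. `rhythmcomp` implements that analysis chain for
anyone working with such expression matrices:

* **Two complementary detectors.** A model-based pattern-matching detector
  fits each gene against a library of waveforms (cosine, spike, box, ramps ×
  24 phases, 24 h period) by least-squares and calls hits with best Pearson
  *r* ≥ max(0.81, permutation top-5% threshold). A nonparametric detector
  scores each gene's Kendall concordance
  *S* = Σ<sub>i&lt;j</sub> sign(y<sub>j</sub>−y<sub>i</sub>)·sign(r<sub>j</sub>−r<sub>i</sub>)
  against reference cosine orderings over periods 20–28 h and all lags, with
  **exact** null p-values from a generating-function convolution over the
  reference tie structure, Bonferroni-adjusted, called at p &lt; 0.05.
* **Circular phase statistics.** Vector-averaged circular means (the mean of
  ZT2 and ZT22 is ZT0, not ZT12), shorter-arc/complement phase distances,
  dawn-adjusted phase-pair correlation (R² after adding 24 h to the smaller
  member of pairs &gt; 12 h apart), agreement fractions, and 1-D/2-D phase
  histograms.
* **Collapsing and comparison.** Transcript→gene and gene→ortholog
  collapsing through user-supplied tables with circular-mean phase merging;
  Venn partitions; Tanimoto-Jaccard similarity (100·|A∩B|/|A∪B|) with
  panel ranking; tissue-specificity binning of a gene × dataset presence
  matrix.
* **A synthetic-data generator** producing time courses and two-dataset
  scenarios with known ground truth (shape, period, phase, overlap, phase
  shift) for validation.

## Worked example

```r
library(rhythmcomp)

spec <- synthetic_spec(n_genes = 200, frac_rhythmic = 0.3,
                       noise_sd = 0.2, seed = 42)
d <- generate_dataset(spec)
out <- run_detection(d$tc, default_config(n_perm = 100, seed = 1))

out$report$haystack   # $n 37  $percent 18.5
out$report$jtk        # $n 40  $percent 20
out$report$common     # 20
out$report$union      # $n 57  $percent 28.5

head(out$calls, 5)
#>         id       method phase period   shape     score      p_value
#> 1 gene0002     haystack     2     24 ramp_up 0.8636361           NA
#> 2 gene0003 haystack+jtk    11     24  cosine 0.9744665 0.0022510823
#> 3 gene0004     haystack    19     24   spike 0.9094604           NA
#> 4 gene0005 haystack+jtk    17     24     box 0.9365272 0.0057142857
#> 5 gene0006 haystack+jtk    20     24  cosine 0.9695707 0.0001731602
```

Of 200 simulated genes (60 truly rhythmic, noise SD 0.2 against amplitude
1), pattern matching calls 37 (18.5%), the concordance test 40 (20%), with
20 genes shared and a union of 57 (28.5%). Each merged call records the peak
phase in ZT hours, the period, the best-matching waveform family, the
detector score (correlation or S), and the adjusted p-value where the
detector produces one.

Phase arithmetic works the same way standalone:

```r
circular_mean(c(2, 22))      # 0   — dawn-corrected average, not 12
phase_distance(1.6, 12.7)    # 11.1, complement attribute 12.9
jaccard100(2609, 2882, n_common = 489)   # 9.8
```

## The analysis workflow

`analysis/` holds numbered drivers that run the full study on synthetic
data, writing tables under `results/`:

1. `01_simulate.R` — generate the liver-style time course and a two-dataset
   comparison scenario with controlled overlap.
2. `02_detect_rhythms.R` — run both detectors, merge calls, summarise shape
   and period composition, and measure cross-detector phase agreement.
3. `03_compare_datasets.R` — Venn partition, Tanimoto-Jaccard index,
   agreement fraction, contour grid and adjusted R² between the two
   datasets.
4. `04_tissue_specificity.R` — specificity binning and similarity ranking
   on a synthetic 12-tissue presence panel.

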