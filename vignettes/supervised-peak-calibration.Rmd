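---
title: "Supervised calibration of peak detectors from visual labels"
author: "peakcal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised calibration of peak detectors from visual labels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakcal)
```

# The model

`peakcal` treats peak detection as a supervised learning problem. The
observable is a coverage profile `x`, a vector of nonnegative integer
read counts over the bases of a chromosome; a peak caller is a function
returning a binary vector `y` over the same bases (1 = peak), which we
represent as its maximal runs of 1s — a sorted list of disjoint,
non-abutting half-open intervals. All coordinates in the package are
0-based, half-open `[start, end)`, matching BED, bedGraph and narrowPeak.

Supervision comes from *labels*: genomic regions a scientist has judged
by eye, each of one of four types.

| type | assertion | false positive when | false negative when |
|------|-----------|--------------------|---------------------|
| `noPeaks` | only background noise | ≥ 1 overlapping peak | never |
| `peaks` | ≥ 1 overlapping peak, any size | never | 0 overlapping peaks |
| `peakStart` | exactly one peak start inside | > 1 start in region | 0 starts in region |
| `peakEnd` | exactly one peak end inside | > 1 end in region | 0 ends in region |

Overlap means a nonempty intersection — a single shared base suffices,
and abutting intervals do not overlap. A peak's start counts for a
`peakStart` region `[s, e)` when `s ≤ start < e`; a peak's end counts
for a `peakEnd` region when `s < end ≤ e`, because the end coordinate is
exclusive, so a peak ending exactly at `e` has its last covered base
inside the region. Each label contributes at most one error, so the
total label error `E = FP + FN` lies in `{0, …, |L|}`. A label applied
to a group of g samples is scored against each of them and counts g
times in `|L|`.

Two edge cases deserve explicit statement, since they are conventions of
this package rather than forced by the verbal rules:

* **A spanning peak is a miss.** A peak covering a whole `peakStart`
  region without starting inside it contributes no start, so the label is
  a false negative: the region demands a *visible* boundary. The same
  holds for `peakEnd`.
* **Error counts are monotone only under peak addition.** Adding a new,
  distinct peak to a call set can never decrease FP nor increase FN (it
  can only add coverage, starts and ends). But *extending* an existing
  peak — merging a new interval into it — is not monotone for boundary
  labels: label `[100, 200)` with peak `[150, 300)` is correct, yet
  merging in `[50, 160)` produces `[50, 300)` whose start lies outside
  the region, creating a false negative. The run representation has no
  memory of the old start. The test suite asserts monotonicity for
  distinct-peak additions and pins the merge counterexample as expected
  behavior.

Abutting predicted peaks are merged at construction time: the binary
vector cannot represent two touching peaks, so "one peak" must be well
defined before boundary counting.

The implementation counts overlaps, starts and ends with rank queries on
the sorted peak coordinate vectors; the test suite checks it against an
independent base-resolution recount (rasterize, scan, count) on a
thousand random instances.

# Training and evaluation

For a one-parameter family of call sets `c_λ` on a finite grid, training
is plain grid search: evaluate the total label error at every grid
threshold on the training windows, return the minimizer. Among tied
minimizers the **largest** threshold is chosen — the most conservative
model — because over-calling is the characteristic failure mode of
untrained thresholds. Evaluation at a threshold not on the grid is an
error rather than an interpolation; grid membership is tested with an
absolute tolerance of 1e-9 to absorb decimal round trips through text
files.

Resampling is by **window**, never by label or sample: labels within a
window were created together and are not independent, while windows are.
Fold assignment is a seeded shuffle followed by round-robin, so fold
sizes differ by at most one and the assignment is reproducible from
(window order, k, seed). Cross-validation trains on all-but-one fold and
evaluates both the trained threshold and the family's default threshold
on the held-out fold; fold summaries report mean and *sample* standard
deviation of percent error.

The ROC-like sweep reports, per threshold, `tpr = 1 − FN / #positive
labels` (`peaks`, `peakStart`, `peakEnd`) and `fpr = FP /
#false-positive-capable labels` (`noPeaks`, `peakStart`, `peakEnd`).
`peaks` labels are excluded from the fpr denominator because the error
rules never charge them a false positive; with them included, fpr = 1
would be unattainable. The two denominators are different label subsets
— hence "ROC-like", not a per-instance ROC. Output headers record both
formulas.

Learning curves fix one fold as the test set and train on growing
prefixes of a random ordering of the remaining windows — *nested*
training sets, so each size adds one window to the previous set. Size 0
is defined as the default threshold (the model you have with no labels).
Several orderings give a mean line and a min/max band.

# The built-in caller

The reference caller exists so the pipeline is exercisable without
external software: smooth the coverage with a centered moving average
(`bandwidth` bases, truncated at chromosome edges), mark bases whose
smoothed value is at least λ, bridge marked runs separated by at most
`max_gap` bases, and drop runs shorter than `min_peak_width`. Defaults
(`bandwidth = 1`, `min_peak_width = 1`, `max_gap = 0`) make it an
identity-like thresholder whose behavior is analytic in tests; the
synthetic benchmarks use `bandwidth = 11` and `min_peak_width = 10` so
the exported call families actually exercise smoothing.

With `max_gap = 0` the called **base set** is nested: raising λ can only
shrink it, and a surviving run always sits inside a lower-λ run at least
as long, so the width filter preserves nesting. The **number of peaks**,
by contrast, is *not* monotone in λ and cannot be: at λ = 0 every base is
marked and the whole chromosome is one peak; any threshold above
background splits it into many, and only past the signal range does the
count fall to zero. The peak count over a threshold sweep is
rise-then-fall (it counts connected components of a superlevel set), and
the suite documents this rather than asserting a monotone count.

The caller's *default* threshold is defined as the global mean coverage —
deliberately naive. Whenever peaks occupy a minority of the genome the
mean sits just above background, so this default over-calls exactly the
way untrained significance thresholds tend to. The threshold grid is
linear on `[0, max smoothed coverage + 1]`, which guarantees the two
extremes "everything with signal called" and "nothing called"; the
default threshold is inserted into the grid when absent so that trained
and default models are evaluated on identical call sets.

# The synthetic benchmark

The generator produces the labeled multi-sample data the evaluation
machinery needs, with known ground truth:

* **Geometry.** Windows are laid consecutively along one synthetic
  chromosome with short gaps. Per window, peak widths are drawn
  uniformly from the configured range and positions are placed with
  enough separation (twice the maximal label margin plus 10 bases) that
  no two peaks' labels can collide; infeasible geometry (too many or too
  wide peaks for the window) errors before any sampling.
* **Sharing.** Each peak is carried by each cell type independently with
  probability `peak_sharing_prob` (0.7 by default; a peak carried by no
  type is reassigned to one random type); all samples of a carrying type
  carry the peak. This emulates the observation that the same peaks
  recur in all samples of a cell type, and it is what gives labels their
  group structure.
* **Coverage.** Counts are independent Poisson draws per base, mean
  `background_mean` (μ0 = 5) outside the sample's peaks and `peak_mean`
  (μ1 = 30) inside. Poisson is the simplest law matching nonnegative
  integer counts with variance tied to the mean; it is a test fixture,
  not a claim about real ChIP-seq noise.
* **Labels.** Every window gets one `noPeaks` label over a peak-free
  leading zone (10% of the window, all samples). Every planted peak gets
  a `peaks` label over its *interior* — the peak minus a margin m on each
  side, with m = 10% of the peak width, at least 5 bases — for the
  carrying cell types, and, when some types do not carry it, a `noPeaks`
  label over the same interior for those types. Half the peaks (in
  expectation) additionally get `peakStart`/`peakEnd` labels over
  `[start − m, start + m)` and `[end − m, end + m)` for the carrying
  types. The interior/flank split is what makes two constraints
  simultaneously satisfiable: labels never overlap on a sample, and each
  true boundary lies strictly inside its boundary label.

By construction the planted peaks satisfy every label —
`total_error(truth_calls(truth), labels) = 0` — which is the generator's
central contract and is tested across seeds and presets.

Two presets fix the study conditions. `sharp` (localized,
H3K4me3-style): 20 samples in 4 cell types, 8 windows of 15 kb, 2 peaks
per window of 200–2000 bases. `broad` (extended, H3K36me3-style): peak
widths 5000–50 000 bases in 180 kb windows, at 6 samples in 3 cell types
and 6 windows, sized so a benchmark remains comfortable to simulate and
score interactively. These problem sizes — and the test suite's instance
counts (1000 random scoring instances, 100 caller profiles, 20
generator seeds per preset, 5 end-to-end seeds) — are the package's
choices for a thorough-but-quick default run.

What the generator does **not** emulate: read-level artifacts (fragment
size, GC bias, mappability, duplicated reads), input/control tracks,
copy-number variation, overdispersed noise, and the output distribution
of any real peak caller. Passing tests on this benchmark therefore show
that the error function, training and resampling machinery are correct
and that thresholds are recoverable when signal and background are
separable — not that any particular caller is accurate on real data. On
real data the intended use is unchanged except that the thresholded call
files come from the external caller under study, via the manifest
format.

# Numerical and interface choices

* Empty intervals are rejected everywhere (`start < end` strictly);
  comparing intervals on different chromosomes is an error, not `FALSE`.
* Coverage profiles are run-length encoded and single-chromosome; a
  multi-chromosome bedGraph is rejected. Gaps in bedGraph input are
  implicit zeros; the writer emits runs exactly as stored, so files
  round-trip bit-exactly, including the profile length.
* Peak files are trusted only in their first three columns; overlapping
  or abutting input intervals are merged on load.
* The browser-style label dialect (`chrom:start-end type group…`, commas
  allowed in numbers, blank lines delimiting windows) mirrors what a
  genome browser displays; a TSV alternative carries explicit window
  ids. Overlap violations abort a load; a window missing a `noPeaks` or
  positive label only warns, since real labeled data may fall short of
  the protocol.
* All CLI outputs are written atomically (temp file then rename) and
  carry `#`-comment headers with the tool version and resolved
  parameters; identical argv (including seeds) produce bit-identical
  files.
* Percent errors are reported at full precision in return values; tables
  are for machines, rounding is for display.

# Limitations

* Training calibrates a single significance threshold; multi-parameter
  search over a caller's full parameter space is out of scope.
* The error metric is per-label and binary — no base-pair-weighted or
  partial credit, no probabilistic labels.
* Strand is ignored (coverage is unstranded) and chromosome names must
  match exactly.
* The boundary-counting conventions (half-open start counting, spanning
  peak = miss) are one consistent reading of "exactly one visible
  boundary"; other implementations may differ on these edge cases, and
  comparisons across tools should check them first.
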