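---
title: "Methods: windowed ChIP enrichment, resampling nulls, and spike-in expression in chromadapt"
author: "chromadapt maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed ChIP enrichment, resampling nulls, and spike-in expression in chromadapt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromadapt)
```

# Scope

`chromadapt` implements the computational core of a two-condition chromatin
study: how does a gene-body histone mark (an H4K20me1-like signal) change
genome-wide when cells are starved of amino acids, and does a
promoter-binding factor (a MYC-like signal) preferentially gain occupancy at
a designated gene set? The package covers enrichment calling from aligned
reads, gene-anchored signal summaries, a resampling null for gene-set
differential binding, spike-in-anchored expression quantification, and
polysome-profile quantification — plus a synthetic-data generator so that
every stage can be validated against known ground truth without any
external download.

# The enrichment caller

## Model

The genome is tiled into non-overlapping windows of `window_size` bp
(default 50 bp, matching 50-bp single-end sequencing). Each deduplicated
read is assigned to exactly one window by its midpoint. For window $i$ with
IP count $k_i$ and matched input count $m_i$, the window's p-value is the
Poisson upper tail

$$p_i = P(X \ge k_i), \qquad X \sim \mathrm{Poisson}(\lambda_i),$$

with the local background

$$\lambda_i = \max(m_i, \bar m),$$

where $\bar m$ is the genome-wide mean input count per window. The floor at
$\bar m$ prevents zero-$\lambda$ artifacts where the input is sparse; it is
a conservative local-background choice in the spirit of window-based
callers. The mean is taken per genome rather than per chromosome because
the caller treats the tiling as one experiment; on the toy genomes used in
tests there is usually a single chromosome anyway.

A window is a *candidate* when $p_i < \alpha$ (default $\alpha = 10^{-3}$).
A candidate becomes *significant* under the default `neighbor_rule =
"both"` when both immediate flanking windows are also candidates. The
phrase "the cutoff is met in two neighboring windows" admits a second
reading — two consecutive neighbors on one side — which is selectable as
`neighbor_rule = "one_sided"`; the default is the stricter of the two.
Chromosome-edge windows can never be significant under the default rule: a
missing neighbor counts as failing.

Peaks are maximal runs of at least three consecutive candidate windows
containing at least one significant window (under the default rule the two
conditions coincide: any run of three candidates has a significant middle
window). A peak records its span, window count, smallest window p-value,
and mean IP/input counts.

## Pre-processing

* **Deduplication** removes reads sharing (chromosome, start, strand).
  For fixed-length single-end reads the end coordinate carries no extra
  information, so this matches duplicate removal on position + strand.
* **Depth equalization** subsamples the larger of IP and input, without
  replacement and seeded, to the size of the smaller. Because the Poisson
  test compares raw counts, equal depths are a precondition, not an
  option.

## Calibration and recovery

Two properties anchor the caller and are exercised in the test suite:

* On background-only simulations (all enrichment factors 1, equal depths,
  $10^5$ windows) the candidate rate stays at or below $\alpha$ — the
  $\max(\cdot,\bar m)$ floor makes the test conservative — and merged peaks
  are absent in essentially all runs, since a run of three independent
  candidates has probability on the order of $\alpha^3$ per window.
* On simulations with 8-fold body enrichment, called peaks recover the
  enriched bodies with high recall and precision (the suite demands
  $\ge 90\%$ and $\ge 95\%$ respectively at moderate depth).

# Gene-anchored summaries

All coordinates are 0-based half-open; BED-dialect files are read and
written natively and GTF-lite input is converted at the boundary. A gene's
TSS is its body start on the plus strand and its body end on the minus
strand.

* **Peak-to-gene association** marks a gene when any peak overlaps the
  interval from 1 kb upstream to 5 kb downstream of its TSS, measured in
  transcription orientation.
* **TSS profiles** average per-gene signal vectors over
  $[-1\,\mathrm{kb}, +5\,\mathrm{kb})$ (configurable), with minus-strand
  genes flipped so every vector runs 5′→3′. Signal over an arbitrary
  interval is the length-weighted mean of the window values covering it,
  computed from a cumulative-sum representation, so bins need not align
  with the window grid. Positions off the chromosome end contribute zero
  signal but stay in the denominator.
* **Metagenes** rescale each gene body onto a fixed 3-kb axis. Scaled bin
  $j$ averages the track over the matching fractional slice of the real
  body — an area-preserving form of linear interpolation chosen so that a
  constant track yields an exactly flat metagene for any mixture of gene
  lengths and strands, and a gene of exactly 3 kb reproduces its raw
  binned signal. Flanks (default 1 kb) are copied unscaled. Genes shorter
  than one bin are skipped with a warning and a reported count.
* **Heat-map matrices** are the per-gene rows beneath a TSS profile,
  sorted by descending row mean; the ordering of a reference condition can
  be reused so panels align across conditions. Column means equal the
  average profile by construction, and the tests assert it.
* **Difference tracks** subtract two count tracks after normalizing each
  to reads per million. Inside the pipeline depths are already equalized,
  making the normalization nearly a no-op, but it keeps the operation
  correct standalone.

# The resampling null for gene-set binding

To ask whether a target gene set (e.g. translation-related genes) gains
promoter-proximal signal beyond what any same-sized gene set would show,
the package compares the target's mean difference-track signal within
$\pm 1$ kb of the TSS against `n_trials` (default 100) random draws of the
same size from a universe that excludes the target genes. The result
carries the observed profile, the pointwise null mean and min–max envelope
(the plotted "range"), the per-trial scalar summaries, and an empirical
p-value.

Two p-value conventions are used deliberately:

* Monte-Carlo mode applies the add-one correction
  $p = (1 + \#\{b : s_b \ge s_{\mathrm{obs}}\})/(B + 1)$, so $p$ is never
  exactly zero and is uniformly distributed under the null (the suite
  checks this with a Kolmogorov–Smirnov test over 200 replicate
  experiments).
* Exhaustive mode (`exhaustive = TRUE`) enumerates every subset of the
  universe and reports the exact fraction
  $\#\{S : s_S \ge s_{\mathrm{obs}}\}/\binom{|U|}{k}$, which is the number
  the Monte-Carlo p estimates; the tests verify the two agree with a
  brute-force enumeration oracle.

Implementation note: per-gene profiles are computed once and each trial is
a row-subset average, so 100 trials cost little more than one.

# Expression quantification with spike-ins

Raw exon counts become RPKM (reads per kilobase of exon per million mapped
reads). Spike-in rows — exogenous transcripts of constant true abundance —
anchor cross-sample normalization: each sample's scale factor is the mean
across samples of the spike-in RPKM sums divided by that sample's own
spike-in sum. The mean was chosen as the reference so adjusted values stay
on the scale of raw RPKM; any fixed reference would equalize the sums, and
after adjustment the spike-in sums are identical across samples to
floating-point precision (asserted at $10^{-9}$ relative).

Differential labels are fold-change-based by design: a gene is
`undetected` below `min_expr` (default 1 adjusted RPKM) in both
conditions, `up` at ratio $\ge$ `fold_cutoff` (default 2), `down` at ratio
$\le 1/$`fold_cutoff`, else `unchanged`. Ratios apply a pseudo-RPKM floor
of 0.01, which only matters for genes already near the detection filter.
No shrinkage or count-model testing is attempted — the labels classify
spike-in-calibrated effect sizes, and the recovery tests show the
classifier finds $\ge 95\%$ of genes with a true $|\log_2$ fold$| \ge 2$
at moderate expression even under a 2-fold library-depth distortion.

Category over-representation uses the hypergeometric upper tail. Following
the reimplemented significance filters, categories overlapping the
selection in fewer than `min_genes` (default 10) genes are excluded
*before* correction, and the Bonferroni multiplier is the number of
categories actually tested; significance requires corrected $p < 0.01$.

# Polysome quantification

An absorbance trace over a sucrose-gradient axis is integrated by the
trapezoidal rule over two disjoint index regions — monosome (80S) and
polysome — and summarized as their ratio. The simulator builds the
monosome as a single Gaussian and the polysome as a decaying five-peak
train, scales each region to the requested area, and adds small noise; the
requested areas are recovered within 1%.

# The synthetic-data generator

`simulate_chip()` draws read midpoints from an explicit per-bp rate:
`background_rate` everywhere, multiplied by a per-gene `body_enrichment`
over gene bodies and a per-gene `promoter_enrichment` over TSS-centred
windows (multiplicative where they overlap). Sampling from the explicit
rate makes the model exact for any factor $\ge 0$, including the
sub-unity factors that express condition-2 body loss. Reads are emitted as
fixed-length intervals with uniform strands; exactly `n_reads` are
produced, and everything is bit-reproducible under a fixed seed.

What the generator does *not* emulate — and what passing tests therefore
do not certify about real data: fragment-size and sonication-shear
variation, GC and mappability bias, diploid genomes, paired-end reads,
overdispersed (non-Poisson) counts, multi-isoform genes (toy genes are
single-exon so exon length equals body length), and replicate structure.
The noise model is Poisson throughout because that is the significance
model the caller assumes; robustness to overdispersion is out of scope.

`make_fixture()` bundles the generators into an on-disk dataset. The
`demo` scale is the package's reference simulation and the conditions
every headline number in this vignette and the README refers to: one 5-Mb
chromosome, 200 non-overlapping genes of 1–10 kb, 8-fold gene-body
enrichment in condition 1 reduced by 40% at every gene in condition 2
(`loss = "global"`), $5 \times 10^5$ IP reads plus matched uniform input
per condition, a 50-gene target set with 4-fold expression induction, 30
repressed genes at 0.25-fold, 10 spike-ins, and a 2-fold library-scale
distortion on condition 2. The `tiny` scale keeps the same structure at
roughly a tenth of the size for fast tests. These sizes were chosen as the
smallest at which gene-level Poisson noise is clearly dominated by the
simulated effects, and they are fixed: results quoted for the demo
simulation always mean these settings.

# Numerical and degenerate-input choices

* Poisson tails come from `ppois(k - 1, lambda, lower.tail = FALSE)`; the
  tests hold them to an explicit-summation oracle at $10^{-12}$ relative
  error over $k \le 50$, $\lambda \le 20$.
* Interval means use a cumulative-sum integral of the window step
  function; out-of-genome stretches contribute zero numerator but full
  denominator.
* The last window of a chromosome may extend past the chromosome end;
  bedGraph output clips it, and window vectors always have
  `ceiling(length / window_size)` entries.
* Empty read sets tile to all-zero tracks; an empty gene list is an error
  for profiles (an average over nothing has no meaning); `n_points < 50`
  is rejected for polysome traces because the peaks cannot be resolved.
* Peak score is $-\log_{10}(\min p)$ with the p-value floored at the
  smallest positive double.
* All user-facing randomness flows through a single seed per operation;
  derived sub-seeds keep independent stages decorrelated while staying
  within 32-bit integer range.

# Known limitations

The caller has no broad/narrow mode and applies no multiple-testing
correction across windows — the fixed Poisson cutoff with the neighbor
rule *is* the definition of significance here. The expression module
deliberately does not reproduce count-model adjusted p-values; its labels
are spike-in-calibrated fold classifications. Null gene sets are matched
on size only, not on expression, length, or GC content. The pipeline
processes exactly two conditions.
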