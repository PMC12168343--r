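# chromadapt

Analysis toolkit for two-condition chromatin experiments: how does a
gene-body histone mark (H4K20me1-like) redistribute genome-wide when cells
are deprived of amino acids, and does a promoter-binding factor (MYC-like)
preferentially gain occupancy at a designated gene set, such as
translation-related genes? The package is aimed at computational
biologists who want the full path — from aligned-read intervals to
publication-style summaries — as small, tested, reusable functions, with a
synthetic-data generator so every claim can be checked against known
ground truth.

## What it implements

**Windowed Poisson enrichment calling.** The genome is tiled into 50-bp
windows; reads are deduplicated on (chrom, start, strand), IP and input
are randomly subsampled to equal depth, and each window's IP count *k* is
tested against

&nbsp;&nbsp;&nbsp;&nbsp;*p* = P(X ≥ k),&nbsp; X ~ Poisson(λ),&nbsp;
λ = max(input count, genome-wide mean input per window)

A window is significant when *p* < 10⁻³ and its neighboring windows also
meet the cutoff; runs of at least three candidate windows merge into
peaks.

**Gene-anchored summaries.** Peak-to-gene association over the oriented
−1/+5 kb TSS window, average TSS profiles, metagenes with bodies rescaled
to a fixed 3 kb (flanks unscaled), heat-map matrices sorted by descending
signal, and reads-per-million difference tracks between conditions.

**Random-gene-set resampling null.** The mean difference-track signal
within ±1 kb of the TSS of a target gene set is compared against 100
equal-size random gene sets drawn from the non-target universe, yielding a
min–max null envelope and an empirical p-value
(*p* = (1 + #{null ≥ observed}) / (trials + 1); an exhaustive mode
enumerates all subsets exactly).

**Spike-in-normalized expression.** RPKM per transcript; per-sample scale
factors from spike-in RPKM sums (factor = mean of sums across samples /
that sample's sum), fold-change classification (up / down / unchanged /
undetected), and hypergeometric category enrichment with a ≥10-gene
prefilter and Bonferroni-corrected *p* < 0.01.

**Polysome profiles.** Trapezoidal area under the monosome and polysome
regions of an absorbance trace, summarized as the polysome/monosome ratio.

**Synthetic data.** Toy genomes, non-overlapping gene models,
two-condition ChIP read sets with controlled body/promoter enrichment,
spike-in-bearing counts with known fold changes, and polysome traces with
known areas — all seeded and bit-reproducible.

## Worked example

Generate a small synthetic dataset and run the whole pipeline on it:

```r
library(chromadapt)

dir <- file.path(tempdir(), "demo")
make_fixture(dir, scale = "tiny", seed = 42)   # writes BED/TSV/JSON inputs
res <- run_pipeline(fixture_config(dir, seed = 42))

res$manifest$n_associated
#> [1] 15
res$manifest$global_loss_percent
#> [1] 100
table(res$expression$de$label)
#>      down unchanged        up
#>         8        22        10
res$resampling
#> resampling_result: observed summary -22.5, null range [-34.81, -12.47]
#> over 100 trials, empirical p = 0.4356
round(unlist(res$polysome_ratios), 3)
#> cond1 cond2
#>   2.5   0.5
head(res$peaks$cond1, 3)
#>   chrom start   end n_windows        min_p  mean_ip mean_input    score
#> 1  chr1 54050 54200         3 3.106240e-04 11.33333   2.666667 3.507765
#> 2  chr1 58150 58350         4 2.401192e-08 14.00000   2.000000 7.619573
#> 3  chr1 59500 59700         4 7.639245e-05 11.75000   2.750000 4.116950
```

Reading the output: 15 of the 40 simulated genes are called significantly
enriched near their TSS in condition 1 at this shallow sequencing depth,
and 100% of them show lower depth-normalized gene-body signal in
condition 2 — the fixture simulates a 40% loss of body enrichment at every
gene, and the pipeline recovers it. The expression module, after spike-in
normalization undoes the simulated 2× library distortion, labels exactly
the 10 induced genes `up` and the 8 repressed genes `down`. The resampling
p-value is non-significant, as it should be: in this fixture the body-mark
loss is uniform, so the target set behaves like any random set. The
polysome ratios recover the simulated areas (2.5 and 0.5). Peak
coordinates are 0-based half-open; `score` is −log₁₀ of the best window
p-value.

A larger reference simulation (`scale = "demo"`: 5-Mb chromosome, 200
genes, 5 × 10⁵ reads per sample) associates 198/200 genes and also
reports 100% body-signal loss.

A thin command-line wrapper is installed with the package
(`inst/scripts/chromadapt`) with `fixture`, `run`, and `validate`
subcommands over the same functions.

## Package layout

- `R/` — genome/gene models, IO (BED6, tagAlign, BED12, GTF-lite,
  bedGraph), window tracks, peak caller, profiles, resampling,
  expression, pipeline + fixture generator
- `tests/testthat/` — unit, property, and end-to-end suites (all
  fixtures generated in code)
- `vignettes/chromadapt-methods.Rmd` — the methods vignette: model
  details, parameter choices, generator scope, numerical decisions
- `scripts/acceptance.R` — reference-simulation reproduction script
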