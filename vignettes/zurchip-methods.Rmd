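---
title: "Methods: peak calling and operator-box analysis for bacterial ChIP-on-chip"
author: "zurchip authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peak calling and operator-box analysis for bacterial ChIP-on-chip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zurchip)
```

# The problem

ChIP-on-chip measures where a DNA-binding protein sits on a chromosome by
hybridizing immunoprecipitated DNA (IP) and a whole-cell-extract control
(WCE) to a tiling microarray, two dyes on one array.  For a bacterial
repressor such as the zinc-uptake regulator Zur, the analysis must turn
raw per-probe two-channel intensities into a list of binding regions, each
with an enrichment score, a possible operator-box (Zur box) match, and a
position class relative to the nearest translational start — the inputs to
any downstream regulon definition.

`zurchip` implements that chain as composable functions plus a one-call
pipeline, and ships a synthetic tiling-array generator so the whole chain
is testable against a known ground truth.

# Model and procedure

## Normalization

For each probe, $M = \log_2(\mathrm{IP}/\mathrm{WCE})$ and
$A = (\log_2 \mathrm{IP} + \log_2 \mathrm{WCE})/2$.  Two-color arrays show
an intensity-dependent dye bias: the MA cloud curves.  `loess_correct()`
fits a locally weighted linear regression of $M$ on $A$ and subtracts the
fit.  Defaults: span 0.4, degree 1, robust (Tukey biweight) fitting with
three robustness iterations — standard two-color practice; all three are
arguments.  Correction is computed on all probes, peaks included: bound
regions cover a small fraction of a tiling array, and the robust fit is
insensitive to them (verified on simulated data by binning corrected
off-peak probes by $A$: bin means stay within ±0.02).  Replicates are
normalized separately.  A degenerate $A$ (all probes equal) falls back to
subtracting the mean of $M$, with a warning.

## Peak detection and the ChIPScore

The corrected track is smoothed by two rounds of a centered 29-probe
moving mean (about 320 bp at the default 11-bp probe spacing).  Windows
wrap around the origin on a circular chromosome and truncate otherwise.
A probe is a *maximum* when its smoothed value equals the maximum over its
own centered 29-probe window; minima are symmetric.  Runs of tied probes
yield one extremum, at the leftmost probe of the run — a deterministic
tie-break that matters on plateaus produced by smoothing.

Maxima within 300 bp are merged by single-linkage clustering; each cluster
keeps its highest maximum (leftmost on ties).  We read the 300-bp merge as
acting on maxima positions, not on whole peak extents, which is the
simpler of the two readings and the one that needs no extra peak-width
model.  A peak's *height* is its smoothed maximum minus the mean of the
two flanking minima (the nearest minimum on each side), clipped at zero.
Using the mean of both flanks is symmetric and uses all the information
the extremum scan provides; taking only the higher flank would be more
conservative and is an easy local change.

The enrichment statistic is

$$\mathrm{ChIPScore} = \frac{\mathrm{height} - \mathrm{median}(H)}
                             {Q_3(H) - \mathrm{median}(H)}$$

where $H$ is the set of all peak heights in that replicate and quantiles
use linear interpolation of order statistics (R's type 7).  The score is a
robust standardization: 0 at the median height, 1 at the upper quartile,
and it is invariant to adding a constant to the whole track.  It needs at
least four peaks, and errors on a degenerate height distribution
($Q_3 = $ median).

Replicates are reconciled by greedy nearest-distance matching of maxima:
all cross-replicate pairs within 300 bp are taken in order of ascending
distance, each peak used at most once.  Matched pairs where *both* scores
reach the cutoff (default 4.0) become consensus peaks, placed at the
circular midpoint of the two maxima and scored by the mean of the two
replicate scores.  Filtering after matching (rather than before) makes
the consensus count monotone non-increasing in the cutoff.

## Motif scanning with exact p-values

`build_pwm()` turns an alignment of equal-length sites into a
position weight matrix with pseudocount 0.25 per cell (a quarter
observation per base, the usual small-sample regularizer).  Scanning
scores each window by the log-odds sum
$\sum_j \log_2(p_{b_j,j}/q_{b_j})$ against a zero-order background $q$,
which defaults to the scanned sequence's own mononucleotide composition
(uniform on request).

Significance is the exact tail probability $P(S \ge s)$ of the score of a
random background sequence of the motif's width.  Per-column scores are
discretized to a grid of $10^{-3}$ bits and the full score distribution is
computed by dynamic programming over that grid — exact on the grid, and
the scan's window scores are computed on the same grid, so reported
p-values are internally consistent with reported scores (the maximum
discretization error of a width-20 score is 0.01 bits).  Ambiguous bases
contribute zero log-odds, i.e. score as background.  Both strands are
scanned; reverse-strand hits are reported by forward start coordinate.
Because an (approximately) palindromic operator reports nearly coincident
hits on both strands, opposite-strand hits overlapping by at least half
the motif width are deduplicated to the better-scoring strand.  The 9-1-9
inverted-repeat structure of the Zur box is not imposed as a constraint;
the matrix carries it implicitly.

A peak is *motif-associated* when a hit start lies within ±50 bp of the
peak maximum; the lowest-p hit in range is attached.  The 50-bp flank
matches the half-width of the region a motif-discovery step would be run
on (100 bp centered on each binding site).

## Peak classification

Each consensus peak is placed relative to the nearest translational start
(start codon), with distance signed along the gene's strand — negative
upstream.  Ties in absolute distance resolve toward the gene for which
the peak is upstream.  Categories:

* `promoter_proximal`: $-200 \le d < 0$;
* `start_overlap`: $0 \le d \le 200$ and inside the nearest gene's CDS;
* `intragenic`: $d > 200$ and inside a CDS;
* `distal`: everything else.

The two published 200-bp rules (upstream and far-downstream) leave peaks
0–200 bp *downstream* of a start uncovered; giving them their own
`start_overlap` class avoids silently inflating either named class.  The
categories are mutually exclusive and exhaustive, re-derivable from the
stored distance and CDS containment, and invariant under a strand flip of
the whole problem (both properties are tested).  The peak "position" used
throughout is the peak maximum.

# The synthetic generator

`simulate_chip_dataset()` builds the complete study object: a random
circular chromosome (default 200 kb, GC 0.435), a non-overlapping gene
tiling covering most of it (gene lengths 300–1800 bp, gaps 50–250 bp,
random strands), planted 20-nt operator boxes, and per-replicate probe
tables.  Defaults, chosen once as the simulated study conditions:

| parameter | default | meaning |
|---|---|---|
| `probe_spacing` | 11 bp | tiled probe pitch (29 probes ≈ 320 bp) |
| `fragment_width` | 500 bp | half-width of the enrichment kernel |
| `n_sites` | 20 | planted boxes, min 2 kb apart |
| `enrichment_range` | 8–32 | fold enrichment per site |
| `wce_log_mean`, `wce_log_sd` | 10, 1 | WCE is $2^{N(10,1)}$ |
| `replicate_noise_sd` | 0.25 | per-probe log2 noise, per replicate |
| `dye_bias_coeffs` | $(-1, 0.15, -0.002)$ | mild quadratic $g(A)$ |

The expected log2 enrichment at a probe is
$\sum_i \log_2(f_i)\,\max(0, 1 - d_i/w)$ — a triangular kernel of
half-width `fragment_width` around each site center $i$ with fold $f_i$,
distances circular.  A triangle is the first-order model of
sonicated-fragment coverage and has a closed form that unit tests can
check probe by probe.  The IP channel is then
$\mathrm{IP} = \mathrm{WCE}\cdot 2^{e + g(A) + \varepsilon}$.  The dye
bias polynomial is evaluated at the probe's noise-free mid log2 intensity
$A = \log_2(\mathrm{WCE}) + e/2$; evaluating at the *observed* $A$ would
make the generative equation implicit in itself, and for the biases of
interest the two differ only by a smooth reparameterization that loess
absorbs either way.  Planted sites are half promoter-proximal (50–150 bp
upstream of a start) and half intragenic (280–700 bp downstream, inside
the CDS) by default.  The PWM training alignment is simulated as 40
copies of the consensus with 0–3 random substitutions each.

What the generator does *not* emulate: probe-sequence-specific
hybridization bias, spatial array artifacts, copy-number variation,
cross-linking efficiency differences between loci, or read-through
enrichment shapes beyond the triangular kernel.  Passing tests therefore
show the pipeline's statistical machinery is correct under its stated
model, not that the model captures every failure mode of real arrays.

# Numerical choices

* Quantiles: linear interpolation of order statistics everywhere (type 7).
* Loess: span 0.4, degree 1, `family = "symmetric"`, interpolating
  surface; idempotent to numerical precision on noise-free biased tracks.
* PWM score grid: $10^{-3}$ bits; DP is exact on the grid and is tested
  against exhaustive enumeration over all $4^w$ sequences for widths
  up to 8.
* Extremum ties: leftmost probe of the tying run, including runs that
  wrap the origin (represented by the first probe after the gap).
* Heights clip at zero so flat noisy stretches cannot produce negative
  heights.
* Coordinates are 1-based inclusive internally; BED/bedGraph output is
  0-based half-open via `rtracklayer`.
* All randomness flows from one integer seed; replicate seeds are derived
  as `seed + 100 + r`, the PWM-training seed as `seed + 500`.

# Problem sizes used in validation

The test-suite and the acceptance script exercise the default conditions:
a 200 kb genome (18 181 probes per replicate, two replicates), 20 planted
sites, one full scan of the 200 kb sequence on both strands; oracle
cross-checks run on 200 random tracks of up to 2 000 probes and 50 random
matrices of width up to 8.  These sizes keep a complete end-to-end run in
a few seconds while leaving every code path exercised, and they scale
linearly for larger genomes.

# Known limitations

* With a dense gene tiling, a peak planted upstream of one gene can sit
  just downstream of the *preceding* gene's start codon (on the minus
  strand); classification follows the nearest start, so planted-category
  tallies on crowded genomes can legitimately differ from the planted mix.
* The ChIPScore is relative to each replicate's height distribution, so
  scores are not comparable across arrays with very different peak counts.
* Exact p-values are exact for the zero-order background; no
  multiple-testing correction is applied to genome-wide scans (a raw
  p cutoff of $10^{-6}$ is the operative rule).
* `consensus_peaks()` reconciles exactly two replicates, the design of the
  assay it models.
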