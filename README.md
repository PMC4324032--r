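# zurchip

Genome-wide mapping of transcription-factor binding sites from two-color
ChIP-on-chip tiling arrays on circular bacterial chromosomes — the kind of
data produced when a tagged regulator such as the zinc-uptake repressor Zur
is immunoprecipitated and the IP and whole-cell-extract (WCE) channels are
hybridized to a genome tiling array.

The package implements the full analysis chain:

1. **Normalization** — per-probe `M = log2(IP/WCE)`,
   `A = (log2 IP + log2 WCE)/2`, dye bias removed by robust loess
   regression of M on A.
2. **Peak calling** — two rounds of 29-probe sliding-window smoothing;
   maxima/minima defined as probes extreme within their own smoothing
   window; maxima within 300 bp merged; peak height = smoothed maximum
   minus the mean flanking minimum; enrichment scored with the
   **ChIPScore**:

   ```
   ChIPScore = (height − median(H)) / (Q3(H) − median(H))
   ```

   over each replicate's height distribution H (interpolated quantiles).
3. **Replicate reconciliation** — greedy nearest matching of maxima within
   300 bp; a consensus peak requires ChIPScore ≥ 4.0 in *both* replicates.
4. **Motif scanning** — a position weight matrix built from aligned
   operator-box sites is slid over both strands; hit significance is the
   *exact* tail p-value of the log-odds score under a zero-order
   background, computed by dynamic programming (default cutoff p ≤ 1e-6),
   with palindrome-aware strand deduplication.
5. **Classification** — each consensus peak is placed relative to the
   nearest translational start: `promoter_proximal` (< 200 bp upstream),
   `start_overlap` (0–200 bp downstream, in the CDS), `intragenic`
   (> 200 bp downstream, in a CDS), or `distal`.

A fully specified synthetic tiling-array generator (circular genome,
planted 20-nt operator boxes, triangular enrichment kernels of
sonicated-fragment width, intensity-dependent dye bias, independent
replicate noise) provides ground truth for every stage.

## Worked example

```r
library(zurchip)

params <- sim_params(seed = 1)            # 200 kb genome, 20 planted sites
ds     <- simulate_chip_dataset(params)

tracks <- lapply(ds$signals, function(s) loess_correct(compute_ma(s)))
peaks  <- lapply(tracks, call_peaks, genome_length = params$genome_length)
cons   <- consensus_peaks(peaks[[1]], peaks[[2]],
                          genome_length = params$genome_length)

pwm  <- build_pwm(simulate_aligned_sites(seed = 501))
hits <- scan_pwm(ds$sequence, pwm, p_threshold = 1e-6, circular = TRUE)
ann  <- annotate_peaks(cons, ds$genes, params$genome_length,
                       hits = hits, genome = ds$sequence,
                       consensus = pwm$consensus)
summarize_annotations(ann)$category_counts
#>            category count
#> 1 promoter_proximal     9
#> 2     start_overlap     1
#> 3        intragenic    10
#> 4            distal     0
sum(ann$motif_associated)
#> [1] 20
```

All 20 planted sites are recovered as consensus peaks (each within a few
bp of its planted center), every one is associated with an operator-box
hit at p ≤ 1e-6, and the recovered category mix matches the planted
50/50 promoter-proximal/intragenic design (one planted upstream site sits
just downstream of the *preceding* gene's start codon and is classified
accordingly).

The same run, end to end with all artifacts (FASTA, GFF3, bedGraph, BED,
TSV tables, JSON manifest) written to disk:

```r
run_pipeline(run_config(output_dir = "run1", seed = 1))
```

A thin command-line front end with per-stage subcommands
(`simulate`, `normalize`, `callpeaks`, `scan`, `annotate`, `run-all`)
ships at `inst/scripts/zurchip.R`.

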