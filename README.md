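# frdemux

Fragment-ratio demultiplexing and quality control for Tn5-barcode-multiplexed
droplet scATAC-seq.

## The problem

Tn5-based sample multiplexing makes droplet scATAC-seq dramatically cheaper:
each sample is tagmented with a transposome carrying its own sample barcode,
samples are pooled, and one 10x Genomics run profiles them all. The catch is
**barcode hopping** — free, unbound Tn5 inserts survive pooling, enter GEMs,
and act as amplification primers, so a cell's fragments end up scattered
across several samples' fragment files under the wrong sample barcode. In a
ten-plex experiment only a small minority of cell barcodes remain private to
a single sample, and the naive "incidence" rule (keep a barcode only if it
appears in exactly one sample) throws away most of the run.

## The method

frdemux implements the fragment-ratio (FR) classifier. Let `N_cs` be the
number of fragments observed for cell barcode `c` in sample `s`. The
fragment ratio of barcode `c` against its best-supported sample is

```
r = max_s N_cs / Σ_s N_cs
```

and `c` is assigned to that sample when `r > 0.6` (strict inequality; both
the threshold and a minimum-fragment floor are configurable). Hopped
fragments are a minority scattered over the other samples, so genuine
singlet cells clear the threshold easily, while cross-sample doublet GEMs —
whose fragments split roughly evenly between two samples — are left
ambiguous. After assignment, `split_fragments()` materialises clean
per-sample fragment files, discarding (or optionally merging) each assigned
barcode's hopped fragments.

The package also provides:

* the standard ATAC QC metrics used to benchmark library quality across
  experimental conditions — FRIP, ENCODE-style TSS enrichment, nucleosome
  signal, mitochondrial fraction, fragment-length histograms — pooled and
  per cell (`qc_report()`, `per_cell_qc()`);
* peak-set comparison: directional overlap fractions, upset-style
  intersection counts (region- and reference-anchored), and per-peak
  fraction-of-cells-with-signal correlation (`upset_counts()`,
  `overlap_fraction()`, `fraction_cells_with_signal()`);
* a synthetic fragment simulator with a generative model of Tn5 barcode
  hopping and doublet GEMs, with full ground truth (`sim_config()`,
  `simulate_fragments()`, `evaluate_assignment()`), so the whole pipeline is
  testable without any external data;
* a command-line front end: `inst/exec/frdemux` with subcommands
  `simulate`, `demux`, `qc`, `compare-peaks` and `evaluate`.

All coordinates on the package surface are 0-based half-open (the
fragments.tsv and BED convention).

## Worked example

Simulate a four-plex experiment with 20% per-fragment hopping, demultiplex
it, and score the result against the known truth:

```r
library(frdemux)

cfg <- sim_config(n_samples = 4, cells_per_sample = 200,
                  mean_fragments = 800, genome_length = 4e6,
                  n_peaks = 200, seed = 42)
sim <- simulate_fragments(cfg)

fit <- fr_demux(sim$fragments)   # r > 0.6, min 100 fragments
fit
#> Fragment-ratio demultiplexing fit
#>   800 cell barcodes across 4 samples (S01, S02, S03, S04)
#>   threshold r > 0.6, min fragments 100, weighting 'fragments'
#>   assigned        732  (91.5%)
#>   ambiguous        46  (5.8%)
#>   low_count        22  (2.8%)
#>   incidence-model unique fraction: 0.0%

evaluate_assignment(fit, sim$truth)
#> Assignment evaluation against simulation truth
#>   barcodes evaluated:        800
#>   assigned fraction:         0.9150
#>   singlet precision:         1.0000
#>   singlet recall:            0.9721
#>   doublet assigned fraction: 0.0000
#>   incidence unique fraction: 0.0000
```

With hopping, *no* barcode stays private to one sample — the incidence
baseline keeps 0% — yet FR thresholding assigns 91.5% of barcodes, all of
them to the correct sample (precision 1.0), and leaves every doublet
ambiguous. QC on one sample's fragment file:

```r
qc_report(sim$fragments$S01, peaks = sim$peaks, tss = sim$tss)
#> ATAC QC report
#>   fragments:          155300
#>   FRIP:               0.4541
#>   TSS enrichment:     17.4541
#>   nucleosome signal:  0.6202
#>   mito fraction:      0.1005
```

`summary(fit)` adds per-sample assigned-cell counts and fragment-ratio
quartiles; `plot(fit)` draws the per-sample FR boxplots with the threshold
line; `split_fragments(sim$fragments, fit)` produces the cleaned per-sample
fragment tables plus a discard pile, conserving every input fragment.

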