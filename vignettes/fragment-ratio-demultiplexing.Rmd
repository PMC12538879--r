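---
title: "Fragment-ratio demultiplexing: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-ratio demultiplexing: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frdemux)
```

## The classification model

Tn5-based sample multiplexing tags every transposition fragment with a
sample barcode before pooling. Free, unbound Tn5 inserts that enter GEMs
after pooling act as amplification primers, so a fraction of each cell's
fragments is amplified under the *wrong* sample barcode and, after
per-sample processing, one cell barcode is observed across several samples'
fragment files. Demultiplexing is therefore a per-barcode classification
problem on the count matrix `N_cs` (fragments for cell barcode `c` in
sample `s`).

The fragment-ratio classifier assigns `c` to `argmax_s N_cs` when

    r = max_s N_cs / Σ_s N_cs  >  threshold  (default 0.6, strict),

provided `Σ_s N_cs ≥ min_fragments`. The statistical picture: if a singlet
cell with `n` fragments hops each fragment independently with probability
`h` to a uniformly chosen other sample, its true-sample count is
`Binomial(n, 1 − h)`, so `r` concentrates around `1 − h` with fluctuations
of order `1/√n`. At realistic depths (hundreds to thousands of fragments)
the probability of a singlet with `h` well below 0.4 falling under the 0.6
threshold is negligible, which is why precision and recall above 0.99 are
achievable while the incidence baseline (keep a barcode only if it appears
in exactly one sample) collapses to nearly zero retention — any hop at all
removes a barcode from the incidence-unique set. Conversely a cross-sample
doublet splits its fragments between two samples in roughly balanced
proportion, so its `r` concentrates below 0.6 and it stays ambiguous: the
threshold doubles as a doublet filter. At `h = 0.5` with two samples the
expected ratio is exactly 0.5, so assignment collapses as depth grows; this
phase boundary is asserted in the test suite.

Assumptions worth stating explicitly:

* Hopping is diffuse — no systematic pairwise contamination between two
  particular samples. A strongly asymmetric hop (e.g. one dominant
  contaminating sample at > 40%) would defeat any per-barcode ratio rule.
* Cell barcodes are comparable across the per-sample pipeline runs.
  Pipelines append GEM-group suffixes (`-1`) per run, so barcodes are
  compared after stripping a trailing `-<digits>` suffix by default
  (`strip_suffix = FALSE` restores exact string identity). Whether the
  upstream runs used identical barcode whitelists is not observable from
  the fragment files; the package assumes they did.
* `N_cs` counts fragment records, not read support
  (`weighting = "fragments"`), because depth of PCR duplication is a
  library property, not evidence of origin; `weighting = "reads"` is
  provided for sensitivity analysis.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `threshold` | 0.6 | minimum (strict) fragment ratio for assignment; raising it trades recall for doublet exclusion |
| `min_fragments` | 100 | barcodes below this total are `low_count`, never assigned; mirrors common scATAC cell-calling floors and keeps ambient/noise barcodes out of the assignment statistics |
| `weighting` | fragments | what `N_cs` counts |
| `strip_suffix` | TRUE | GEM-group suffix handling (above) |

Strictness at the threshold (`r > t`, not `≥`) matters only for barcodes
landing exactly on `t`; they are classed ambiguous. Ties at the argmax are
broken towards the lexicographically smallest sample identifier — a tied
barcode has `r ≤ 0.5` and can never be assigned at any threshold above 0.5,
so the rule affects reporting only, and determinism costs nothing.

After assignment, `split_fragments()` discards an assigned barcode's
fragments found in *other* samples' files: under the hopping mechanism they
are amplification artifacts carrying the wrong sample context. Since one
could also argue they are genuine molecules of the assigned cell,
`merge_hopped = TRUE` reroutes them into the assigned sample instead; the
conservation invariant (every input fragment appears in exactly one output)
holds in both modes.

## The synthetic experiment

`simulate_fragments()` generates a full multiplexed experiment with ground
truth. Default conditions model a ten-plex droplet run: 10 samples × 500
cells, per-cell depth `NB(mean = 2000, size = 2)` (overdispersed, so the
`min_fragments` filter is actually exercised), per-fragment hop rate 0.2,
5% cross-sample doublets with mixing proportion uniform in [0.3, 0.7] (so
doublets concentrate below the 0.6 threshold), 500 non-overlapping 500-bp
peaks on a 10-Mb autosome with one TSS at each peak centre, fragment
lengths from a 60/40 normal mixture at 70 ± 20 bp (nucleosome-free) and
200 ± 30 bp (mono-nucleosome) truncated at 20 bp, and 10% mitochondrial
fragments on a 16.6-kb `chrM`. The published ten-plex experiment does not
report a per-fragment hop-rate estimate, so 0.2 is a plausibility choice,
not a claim about real data; it is deep enough into the regime where the
incidence baseline fails that the qualitative contrast (near-total FR
retention versus near-zero incidence retention) is stable across seeds.

Peaks carry per-peak accessibility weights drawn once from `Gamma(1, 1)`
and shared by all samples and cells. Real peaks span orders of magnitude in
accessibility, and uniform peak usage would make every per-peak
fraction-of-cells-with-signal identical in expectation — cross-sample
correlation of those fractions would then be pure noise rather than a
meaningful reproducibility measure. The weight distribution is exposed as
`peak_weight_shape` (large values approach uniform usage).

What the generator does **not** emulate: genomic sequence (coordinates
only), chromatin-driven spatial autocorrelation of insertions, PCR
duplication (support is always 1), read-level errors, ambient fragments,
same-sample doublets (invisible to demultiplexing by construction), and
nonuniform hop destinations. Passing tests therefore demonstrate
correctness of the *computation* and sane behaviour of the *classifier
under its own generative assumptions* — not performance guarantees on any
particular real dataset.

Determinism: one seed drives a single pseudorandom stream with a documented
draw order, and the global RNG state is saved and restored around the
simulation. Outputs are bit-reproducible for one implementation; only
distributional equivalence is promised across implementations.

## QC metric definitions and numerical choices

The source experiments plot FRIP, TSS enrichment and nucleosome signal
without printing their formulas, so the package pins down
convention-aligned definitions and exposes every constant:

* **FRIP** — fraction of fragments overlapping a merged peak by ≥ 1 bp,
  half-open semantics (a fragment ending at a peak's start shares no base).
  Merging first makes the value invariant under peak order and under
  splitting a peak into bookended pieces.
* **TSS enrichment** — ENCODE-style aggregate. Both fragment ends are
  insertion events, counted at offsets in ±2000 bp around each TSS
  (strand-flipped for minus-strand TSS), normalised by the mean count over
  the outermost 100 positions per side, smoothed with a 21-bp centred
  moving average; the score is the smoothed maximum. When the flank
  background is exactly zero it is floored at
  `total insertions / (window width × 1000)`, keeping the score finite
  while preserving "very enriched" semantics. The per-cell variant instead
  averages the normalised density over the central ±100 bp — a per-cell
  maximum over 4001 mostly-empty positions would be noise-dominated; this
  deliberate mode difference is documented in `per_cell_qc()`.
* **Nucleosome signal** — count ratio of mono-nucleosome fragments
  (147 < length ≤ 294 bp) to sub-nucleosomal fragments (≤ 147 bp), the
  nucleosomal-wrap convention; reported as `NA` when the denominator is
  empty (undefined, not an error).
* **Mitochondrial fraction** — support-weighted fraction on `chrM`/`MT`.
* Fragment length is `end − start`; the upstream +4/−5 Tn5 offset
  correction is assumed already applied, and the package never shifts
  coordinates.

Parameter recovery of the simulator's `frip_target` is asserted on nuclear
(chr1) fragments: the generative model draws the in-peak event only for
non-mitochondrial fragments and `chrM` carries no peaks, so including the
mitochondrial fraction would measure `(1 − mito) × frip_target` instead of
the parameter itself. The measured value still runs slightly above target
because off-peak fragments can graze a peak by chance — with the default
geometry the peak footprint is ~3% of the genome, comfortably inside the
±0.03 assertion band.

For peak-set comparison, the published upset figure is ambiguous between
two countings, so both are implemented: `mode = "region"` counts connected
components of the union labelled by contributing sets (verified against a
per-base membership oracle), and `mode = "reference"` counts each reference
peak by which other sets overlap it — the natural reading of "peaks shared
with the fresh sample". The overlap predicate is ≥ 1 bp everywhere, with
`min_overlap_bp` to tighten it; the published ~70% overlap statistic does
not state its criterion, so the default is the weakest standard one.
Pattern labels are canonicalised (set names sorted within a pattern) so
counts are invariant to input order.

## Problem sizes in the test suite

The suite validates operations against independent brute-force oracles at
small sizes (≤ 100 fragments, ≤ 20 peaks, ≤ 5 × 4 count matrices), and the
end-to-end behaviour on simulated experiments: the full ten-plex at
5000 cells / ~10 M fragments for recovery under hopping, a two-sample
deep-coverage run (mean 5000 fragments/cell) for the phase boundary, five
hop rates at 500 cells each for recall monotonicity, and ~60 k-fragment
runs for parameter-recovery checks. These sizes keep the suite quick while
leaving every statistical assertion far from its sampling noise floor.

## Known limitations

* The classifier is per-barcode and uses no fragment-level covariates
  (position, length); a mixture model over counts could in principle
  recover part of the ambiguous class.
* `min_fragments` is a hard floor, not a calling algorithm; knee-point
  cell calling is out of scope.
* Doublet handling is purely "leave ambiguous"; no explicit doublet score
  is produced.
* The simulator's uniform hop destination is the maximum-entropy choice;
  structured contamination (e.g. adjacency on a plate) is not modelled.
* BAM/FASTQ input, peak calling, embeddings and differential accessibility
  are deliberately outside the package: fragments files in, tables and
  clean fragments files out.
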