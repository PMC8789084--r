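---
title: "Profiling replication fork direction from 3'-end break-mapping reads"
author: "traelkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling replication fork direction from 3'-end break-mapping reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traelkit)
```

## The measurement

TrAEL-seq style libraries label free DNA 3' ends and sequence a single-end
read whose 5'-most mapped base is the nucleotide adjacent to the break. In
S-phase cells the dominant source of free 3' ends is the replication fork
itself, so each read is effectively a snapshot of one fork in one cell. The
strand of the read encodes the direction the fork was moving: forward-strand
reads come from leftward-moving (right-to-left) forks, reverse-strand reads
from rightward-moving forks.

Summing forward (F) and reverse (R) read counts in running windows gives the
read polarity

$$\mathrm{polarity} = \frac{R - F}{R + F} \in [-1, 1],$$

whose sign encodes the locally predominant replication direction. Three
features of the profile are biologically interpretable:

* a sharp negative-to-positive transition marks an **active replication
  origin** (forks diverge from it);
* a gradual positive-to-negative transition marks a **fork convergence
  zone** (forks from neighbouring origins meet there, at a position set by
  their firing times and the fork speed);
* a local excess of one strand *without* depletion of the other marks
  increased fork residency — **stalling** — because slow or paused forks are
  photographed more often.

The raw reads carry an 8 bp unique molecular identifier (UMI) followed by
1–3 templated T bases and then genomic sequence
(`NNNNNNNN(T)nSEQUENCESPECIFIC`), which demands dedicated pre-processing
before alignment.

## The simulator

Because the phenomena of interest live in single cells, the package ships a
generative model (`fork_model()`, `simulate_break_sites()`) used as
ground truth for every downstream stage:

* each origin fires independently per cell with probability `efficiency` at
  a fixed `firing_time` (fractions of S phase);
* two forks progress outward at `fork_speed` (bp per unit S-phase time);
  an origin already passively replicated by an earlier-firing neighbour's
  fork does not fire; converging forks annihilate at the meeting point
  implied by firing times and speed; forks stop at chromosome ends;
* each cell is observed at a single time drawn uniformly over S phase, and
  every fork alive at that moment contributes one break-site molecule at its
  current position, with strand set by the direction convention above;
* a fork inside a stall zone is observed with probability multiplied by
  `1 + residence_weight`. This is implemented by thinning: every fork is
  accepted with probability `(1 + w)/(1 + w_max)`, so relative window
  densities equal the residence-weight ratio exactly while probabilities
  stay in `[0, 1]`. A stall site has a spatial extent (`width`, default
  500 bp — the scale of a protein-mediated fork barrier region) because a
  single-bp stall cannot produce a measurable window-level enrichment;
* background (non-replicative) breaks are uniform with random strand.

`emit_reads()` then turns molecules into reads: an independent random 8-mer
UMI per molecule, a poly-T of 1–3 bases, genomic sequence read into the
fragment in the orientation implied by strand, constant qualities, and exact
PCR copies appended with probability `pcr_duplication_rate`.

The model deliberately omits several features of real libraries: sequencing
errors, adapter contamination and quality trimming (delegated to external
trimmers in practice), barcode errors, chromatin effects on origin firing,
and any coupling between transcription and stalling. Firing times are fixed
per origin rather than stochastic, so convergence zones are sharper than in
real data. Passing tests therefore demonstrate the correctness of the
pipeline's bookkeeping and statistics on an idealised signal, not
performance on real libraries.

The defaults for fork speed and firing times are free parameters of the
simulator, chosen to be plausible for a budding-yeast S phase (forks of
1.5–3 kb/min over a 20–40 min S phase traverse 50–100 kb): the benchmark
generator (`random_fork_model()`) uses 100 kb per unit S phase with
origins spaced ~60 kb, which makes every inter-origin gap converge within
S phase.

## Pre-processing and deduplication

`extract_umi()` moves the first 8 bases into the read id (`:` delimiter,
SAM-safe); `trim_polyT()` removes up to 3 leading Ts. When the genomic
sequence itself begins with T, trimming absorbs those bases (up to the cap)
and shifts the mapped 5' end by 1–2 bp — an intrinsic ambiguity of the
T-tailed read structure that the tests account for explicitly.

Two deduplication modes exist, matching two stages of the pipeline:

* `dedup_by_sequence()` (optional, off by default) collapses reads on their
  first 23 bases (8 bp UMI + 15 bp genomic) *before* alignment. It exists
  for tandem multi-copy loci: PCR copies of a repeat-derived molecule align
  to different repeat copies at random, so they survive position-based
  deduplication; identical 23-mers identify them regardless of placement.
* `umi_dedup()` collapses alignments on (chromosome, 5' position,
  orientation, UMI) after alignment — the standard UMI deduplication.

`align_reads()` is an exact-match aligner sufficient for simulated reads
(seed of 20 bases via `Biostrings::matchPDict` on both strands, full-length
verification); multi-mapping reads are discarded and counted, which is the
reproducible choice. Real libraries should be aligned externally and
imported with `import_sam()`. `mask_reference()` hard-masks intervals with
Ns so integrated constructs cannot attract multi-mapping reads.

## Quantification and normalisation

`truncate_to_break()` reduces each alignment to the single 5' nucleotide;
`count_windows()` sums sites per strand in running windows (50 bp windows
every 10 bp for display profiles; 200 bp every 50 bp for differential
testing). `filter_blacklist()` excludes windows overlapping non-single-copy
regions by at least 1 bp. `normalize_rpm()` scales included windows to reads
per million; `normalize_enrichment()` matches the count distributions of
several libraries by rescaling each so that the trimmed mean of per-window
totals between the 20th and 90th percentiles equals the cross-library
geometric mean. The percentile band is interpreted as a trimmed-mean
estimator because that is the minimal scale-only reading of a "20–90%"
enrichment normalisation; being scale-only it provably leaves polarity
untouched.

## Origin and convergence calling

There is no standard algorithm for turning a polarity profile into origin
calls; visual inspection is the traditional method. `call_origins()` makes
it reproducible with a flank-mean change-point score: each window is scored
as the mean defined polarity over the next `flank` windows minus the mean
over the previous `flank` (undefined windows are skipped, not zero-filled —
zero-filling would bias transitions toward low-coverage regions). A window
is a candidate origin when the score exceeds `min_score`, the left mean is
negative and the right mean positive, and flank coverage reaches
`min_coverage`; nearby candidates merge to the maximum-score window.
Defaults: `flank = 15` windows, `min_score = 0.5` (scores lie in [-2, 2]),
`min_coverage = 5` counts per window. `call_convergence()` is the symmetric
procedure for positive-to-negative transitions and reports zones (intervals)
because convergence positions vary from cell to cell.

These thresholds are pipeline parameters, not biological constants: an
origin whose polarity transition is weaker than `min_score` (e.g. a
low-efficiency origin inside a mostly passively-replicated region) will not
be called. The packaged benchmark (20 random models, 3–6 origins of
efficiency at least 0.7) runs at roughly 300,000 molecules per model so that
flank-mean sampling noise (standard deviation about 0.1 at ~35 counts per
window) sits far below `min_score`; at much shallower depth, noise in
mixed-population regions whose true polarity is near ±0.5 can cross the
threshold and produce spurious weak calls.

## Differential fork accumulation

`differential_windows()` compares raw single-strand window counts between
two conditions with replicates, using library-size offsets and an exact
conditional negative-binomial test with a single method-of-moments common
dispersion shared across windows (the Poisson/conditional-binomial limit
when the dispersion estimate is zero). Two p-value modes are provided:

* `lfc = 0`: plain equal-rate null, two-sided by minimum likelihood, with
  the mid-p correction — discrete exact tests are otherwise conservative,
  and mid-p restores near-nominal size (empirically ~0.04–0.05 at the 0.05
  level on null simulations);
* `lfc > 0`: composite null "|log2 fold change| ≤ lfc", the appropriate
  question when *calling regions* of biologically substantial difference.
  The p-value doubles the smaller of the two one-sided tail probabilities
  computed at the respective fold-change boundaries. Any procedure that
  ranks plain p-values admits roughly `FDR × (number of discoveries)` false
  windows however well calibrated it is; the fold-change threshold removes
  them because a null window essentially never exceeds a two-fold observed
  change at realistic counts.

Benjamini–Hochberg adjustment runs across tested (non-zero) windows.
Windows are correlated when `step < window`, so calibration assessments in
the test suite use non-overlapping grids.

## Phenotype statistics

For the copy-number and growth phenotypes that accompany fork profiling:

* `cnv_percent()`: 100 × (CNV band intensity) / (all band intensity) per
  gel lane; band classes are user-supplied (densitometry is out of scope).
* `screen_fold_change()`: mutant/wild-type CNV ratio with enhancer (> 2)
  and suppressor (< 0.5) classification bands.
* `adaptation_auc()`: area under OD versus inhibitor concentration by the
  trapezoid rule over the measured range, with no extrapolation — the
  minimal assumption for a dose–response summary. Optional per-plate blank
  subtraction (clipped at zero) is off by default since blanking schemes
  vary.
* `compare_groups()`: one-way ANOVA with pairwise pooled-variance t
  comparisons and Šidák's correction, adjusted p = 1 − (1 − p)^m. Zero
  error variance is handled explicitly (identical data give p = 1).

## Numerical conventions and edge cases

* Coordinates are 0-based half-open internally and in BED output; SAM
  import converts from 1-based. Externally printed closed 1-based mask
  coordinates can be consumed with `closed_1based = TRUE`.
* A site belongs to a window by its single break coordinate, half-open.
* Deduplication sorts records by (chromosome, position, strand, UMI,
  read id) before keeping the first of each key, making the operation
  deterministic, idempotent and order-insensitive.
* Windows with F + R = 0, and excluded windows, have undefined polarity and
  never enter flank means, coverage means or normalisation factors.
* All simulation entry points accept a `seed`; identical seeds give
  byte-identical outputs end to end.

## A small worked example

```{r example, eval = FALSE}
g <- build_genome(genome_spec(c(chr1 = 200000)))
m <- fork_model(data.frame(position = c(50000, 150000),
                           efficiency = c(0.9, 0.8),
                           firing_time = c(0.15, 0.2)),
                fork_speed = 80000)
sim <- simulate_break_sites(m, g, n_cells = 20000, seed = 1)
er <- emit_reads(sim$sites, g, pcr_duplication_rate = 0.3, seed = 2)

aln <- align_reads(trim_polyT(extract_umi(er$reads)), g)
sites <- truncate_to_break(umi_dedup(aln))
profile <- compute_polarity(count_windows(sites, g, 50, 10))
call_origins(profile)
call_convergence(profile)
```

## Known limitations

* The built-in aligner is exact-match only; any realistic data must be
  aligned externally and imported as SAM/BAM.
* The common-dispersion estimate is a single pooled value; strong
  window-specific overdispersion (e.g. copy-number heterogeneity) would be
  better served by trended or empirical-Bayes dispersions.
* Origin calls are point estimates of transition centres; no attempt is
  made to infer origin efficiency or firing-time distributions from the
  polarity shape.
* The thinning implementation of stalling rescales total library yield when
  strong stalls are present; comparisons across conditions should always go
  through library-size normalisation (as `differential_windows()` does).
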