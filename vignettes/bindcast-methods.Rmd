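---
title: "Predicting TF binding from ATAC-seq: models and methods in bindcast"
author: "bindcast authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting TF binding from ATAC-seq: models and methods in bindcast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`bindcast` predicts transcription-factor binding sites (TFBS) genome-wide
from two inputs: DNA sequence and base-pair-resolved chromatin
accessibility (ATAC-seq or scATAC-seq pseudobulk). This vignette is the
package's account of the science: the signal model, the network, the
training scheme, the evaluation machinery, the synthetic fixtures the
tests run on, and the numerical and design choices that were genuinely
open.

## 1. The accessibility signal

ATAC-seq reads mark Tn5 transposase insertions, offset by the enzyme's
9 bp duplication. `inferCutSites()` therefore shifts plus-strand read
starts by +4 bp and minus-strand read ends by −5 bp (defaults in
`signalConfig()`); both insertion events of a fragment are kept, which
matters for shallow pseudobulk libraries. 10x-style fragment files are
treated as already Tn5-corrected, so in fragment mode both fragment ends
become cut sites with no further shift. Fragment `count` fields (PCR
duplicate multiplicities) are carried as metadata but do not multiply cut
sites: duplicate marking is an upstream concern.

Insertion points are between-base points: `smoothCutSites()` expands the
point c into the half-open window [c−20, c+20), exactly 40 bp — about the
footprint of the Tn5 dimer — clamped at chromosome ends. A flank of 0
degenerates to the single cut-site base.

Per-base coverage of these windows is depth-normalized to
reads-per-20-million, `RP20M = count / depth × 2e7`, with depth counted
as inferred cut sites (one per read; two per fragment) before blacklist
filtering. Replicates are averaged after RP20M scaling; robust min-max
parameters are fitted on the averaged track (the order is not externally
constrained; fitting after averaging makes the parameters describe the
track the model actually sees).

Robust min-max normalization divides by the P-th percentile of the
signal rather than the absolute maximum, because transformed cell lines
carry biological outlier regions (e.g. amplified super-enhancers) that
would otherwise crush the dynamic range. Three choices here were open
and are fixed as follows:

* **Reference distribution of the percentile.** The genome is mostly
  zeros, so a percentile over all bases would itself be 0.
  `fitMinMax()` uses the nearest-rank percentile of the *nonzero*
  per-base values, with the minimum pinned at 0. Default percentile 99
  (95 and 100 are accepted; 100 reproduces standard min-max).
* **Values above the robust maximum.** The transform alone exceeds 1
  above the P-th percentile; scores feeding the network are expected in
  [0,1], so `minmaxNormalize()` clips at 1 by default. `clip = FALSE` is
  available for diagnostics and is recorded in the track metadata.
* **Blacklist order.** Cut sites inside blacklisted regions are removed
  before any counting, so they contribute to neither coverage nor the
  percentile.

`SignalTrack` objects store the per-base values run-length encoded with
their `Seqinfo` and normalization state; bedGraph is the canonical
on-disk dialect (text-exact, 0-based half-open, zero runs omitted) with
bigWig as an optional encoder over the same runs via `rtracklayer`.

## 2. The network

`architectureSpec()` captures every hyperparameter; the defaults are the
model: 1,024 bp × 5 input channels (4 one-hot DNA + 1 signal), five
convolutional blocks of two ReLU-activated, same-padded, width-7
convolutions, batch normalization per block, width-2 max pooling between
blocks, filter counts `trunc(15 × 1.5^(k−1))` = 15, 22, 33, 50, 75, and
a sigmoid output convolution producing 32 scores at 32 bp resolution.

Three architectural details are under-determined by the printed
description and resolved as follows (each is isolated in `layerPlan()`):

* **Six dilation rates, five blocks.** The dilation schedule
  1, 1, 2, 4, 8, 16 has one more entry than blocks. Blocks 1–5 take
  1, 1, 2, 4, 8; the trailing 16 drives a final two-layer convolutional
  stage (75 filters, batch-normalized) preceding the output convolution.
  The arrangement is guarded by the receptive-field requirement: the
  one-sided extent, computed analytically by accumulating
  (kernel−1) × dilation × cumulative-stride contributions and truncated
  at the input boundary, reaches ±512 bp (`receptiveField()`), and the
  analytic value is pinned to empirical input-perturbation extents in
  the tests.
* **Pooling.** Pool width is 2; the number of pooling stages is derived
  from the shape constraint 1,024 → 32 (five 2× reductions), interleaved
  after the blocks with any surplus after the final dilated stage. A
  spec whose input/output ratio is not a power of the pool width is
  rejected at construction.
* **Normalization placement.** Batch normalization follows each
  convolution pair (momentum 0.9, epsilon 1e-5 — chosen so running
  statistics settle within the short training runs used at desk scale).

Weights are Glorot-uniform initialized, deterministically from a seed.
The forward/backward/ADAM core is compiled (RcppArmadillo). Convolutions
run in single precision — activations and gradients are far inside float
range, and sgemm doubles throughput on one CPU — while batch-norm
statistics, losses and the exported parameters stay double. Gradients of
every layer are verified against finite differences of a pure-R
double-precision reference in the test suite. Training uses an in-C++
session (`nn_session_*`) so per-batch work allocates nothing on the R
heap; inference (`predictWindows()`, `predictGenome()`) runs through the
R layer stack on the exported parameters.

## 3. Training: peak-centric, pan-cell sampling

Only ~1% of the genome is accessible in vivo, so uniformly random
training windows contain almost no positives. `buildRoiPool()` builds
the union of ATAC and ChIP peaks of every training cell type (blacklist
removed, tagged with origin), restricted to the training chromosomes.
`sampleExamples()` draws a fraction `random_ratio` of windows uniformly
(default 0) and centers the rest on pool-interval midpoints without
jitter (midpoint centering is the plainest reading; jitter would be a
one-line extension). Under pan-cell sampling the cell type supplying
both the signal and the labels is drawn uniformly from all training cell
types, independent of the interval's origin — a region bound in the
origin cell type is then frequently paired with a cell type in which it
is not bound, enriching hard negatives. Labels always describe binding
in the cell type whose accessibility is shown; pairing labels with the
origin instead would be biologically incoherent.

A 32 bp bin is labeled bound iff ChIP peaks cover strictly more than
half of it: exactly 16 bp is negative. The strict reading makes the
boundary testable.

Chromosomes are split once (defaults: chr2/chr19 validation, chr1/chr8
test, the remaining listed autosomes training) so sequence never leaks
between partitions. Training minimizes mean binary cross-entropy with
ADAM (learning rate 0.001; published budget 100 epochs × 100 batches ×
1,000 examples; reduced budgets are a `trainConfig()` choice), and the
epoch maximizing the soft dice coefficient on a fixed validation-example
set is kept. The validation set is peak-centric pan-cell examples drawn
once from the validation chromosomes (512 by default) — the composition
is not externally specified; a fixed set makes epoch selection
comparable across epochs. Reverse-complement augmentation
(`rc_augment`) doubles each batch with complement-swapped,
position-reversed copies; it is off by default since it did not robustly
help at the published scale. All randomness flows from `config$seed`;
fixed seeds reproduce histories bit-for-bit.

For toy-scale genomes the sampler decodes per-chromosome sequence,
signal and cumulative label indicators into dense vectors once per
training run; at 3 Gb this would be memory-hungry and a streaming
sampler would be the first thing to add for full-genome training.

## 4. Prediction and calibration

`predictGenome()` tiles chromosomes into non-overlapping 1,024 bp
windows from position 0 (stride unspecified upstream; non-overlap is the
cheapest consistent choice and is isolated so sliding variants can be
added), pads the trailing window with N sequence and zero signal,
discards scores beyond the chromosome end, and zeroes bins overlapping
the blacklist. It refuses signal that is not min-max normalized.
Donor-specific prediction substitutes homozygous SNVs into the reference
with `applyVariants()` (indels and heterozygous calls are rejected —
phasing accessibility signal is out of scope).

`calibrate()` maps scores to validation performance on a fixed 0.001
grid (a fixed grid keeps tables comparable across models and bounds
their size). Precision is not automatically monotone in the threshold,
so the table is reduced to its strictly-increasing precision frontier
scanning thresholds upward; a precision value attained at several
thresholds therefore keeps the threshold of maximal recall. F1 at
P = R = 0 is defined as 0. `thresholdToBed()` merges maximal runs of
bins at or above a cutoff into intervals carrying the run maximum. Note
the interval *count* need not fall as the cutoff rises (a run can split
in two); the covered bases do.

## 5. Benchmarking

`binScores()` takes the maximum score per non-overlapping 200 bp bin
(trailing partial bins dropped so the bin width stays constant);
`labelBins()` marks a bin positive on any ≥1 bp overlap with a ChIP peak
— deliberately more permissive than the >50% training-label rule.
Blacklist-overlapping bins are excluded from every numerator and
denominator. `prCurve()` thresholds at each unique score, descending,
with ties entering together; `auprc()` is the average-precision step sum
(matching the usual library convention rather than trapezoids);
`precisionAtRecall()` reports the precision at the first threshold whose
recall reaches the target; `randomPrecision()` is the positive-bin
fraction. Method comparisons use `log2FoldChange()` with a 0.1
pseudocount to moderate ratios of small AUPRs.

Two baselines are shipped. Motif scanning: MEME-minimal PWMs
(`readMeme()`), log-odds scores discretized at 1e-3, and the match
p-value threshold derived by exact dynamic programming over the score
distribution under the background model (`pwmScoreThreshold()`); both
strands are scanned, exact-coordinate duplicates removed, overlapping
non-identical matches kept, multi-motif hit streams unioned, and hits
counted per bin by any-overlap (`motifRankBins()`). Average ChIP:
per-base mean of arcsinh-transformed −log10 p-value tracks across
training cell types (`averageChipBaseline()`).

## 6. Synthetic fixtures and what they show

`generateFixture()` builds a deterministic toy study: an i.i.d. uniform
background genome (no GC structure, so motif-match p-values stay exactly
analytic; a Markov background would be the natural extension), four
chromosomes mapped onto the default split (chr1 test, chr2 validation,
chr3/chr4 training), non-overlapping candidate accessible regions of
500 bp (40 per 100 kb), a consensus 8-mer planted verbatim at the center
of 60% of them, per-cell-type accessibility (50% of regions shared by
all cell types, the rest private to one), and binding defined as
accessible ∧ motif-bearing ∧ an 85% Bernoulli — so binding is
cell-type-specific and learnable from sequence plus signal, emulating
the Jaccard-overlap regime of real TFBS. Fragment libraries (30,000 per
cell type, 80–250 bp) place midpoints as a mixture calibrated to a
10-fold accessible-over-background intensity; ChIP signal tracks are
stepped pyramids over true sites plus sparse noise.

The end-to-end test trains on two fixture cell types and predicts the
third on the test chromosome (20 epochs × 20 batches × 64 examples —
problem sizes chosen so the whole suite runs comfortably on one CPU —
over three seeds), requiring median AUPR ≥ 5× random precision, and
checks that peak-centric pan-cell sampling beats fully-random sampling
on validation AUPR at a matched smaller budget. Two caveats on reading
these results across to real data: the toy genome is ~15–20% accessible
versus ~1% in vivo, which makes genome-wide metrics easier and can even
favor random sampling on *test* chromosomes (the validation-AUPR
direction is the robust one at this scale); and uniform background
sequence means the network needs only the planted motif plus signal, not
the clustered, degenerate motif grammar of real enhancers. Passing the
suite demonstrates that the machinery — signal math, sampling, the
network and its optimization, tiling, binning and ranking — is correct
and end-to-end consistent, not that the paper-scale performance numbers
transfer.

## 7. Known limitations

Single-task models only (one TF per model); no quantitative (regression)
outputs; non-overlapping prediction tiling; dense per-chromosome
decoding in the training sampler; BAM ingestion expects reads as
`GRanges` (e.g. via `Rsamtools`) rather than parsing BAM internally;
indel/phasing-aware personalization is out of scope.
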