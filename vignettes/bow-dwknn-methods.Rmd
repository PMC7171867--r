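---
title: "Bag-of-words DWKNN interaction prediction: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bag-of-words DWKNN interaction prediction: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bowdti)
```

## Model

A receptor–drug pair is represented by a 256-dimensional vector and scored
by a distance-weighted K-nearest-neighbor (DWKNN) classifier.

### Receptor block (128-D)

1. The amino acid sequence is encoded residue-by-residue with an AAindex
   property scale (`encode_sequence()`), turning it into a numeric series.
2. Sliding fragments of lengths 2, 3 and 4 are collected across a training
   corpus and clustered with hard C-means (`stats::kmeans`) into a
   **wordbook**: 20 words of length 2, 30 of length 3, 58 of length 4
   (`build_wordbook()`). Length-1 "words" are simply the 20 amino acids.
3. A sequence becomes the concatenation of four frequency histograms —
   amino acid composition plus one histogram per fragment length, each
   fragment assigned to its nearest word — giving
   20 + 20 + 30 + 58 = 128 values (`gpcr_features()`).

### Drug block (128-D)

The 256 hexadecimal fingerprint characters are read as digits 0–15 and
treated as a real discrete signal. The magnitudes of DFT coefficients
k = 0…127 (the unique half of a real signal's conjugate-symmetric
spectrum, DC included), normalized to sum 1, form the drug vector
(`drug_features()`). An all-zero fingerprint has no spectrum to normalize
and maps to the uniform vector 1/128.

### Classifier and ensemble

`dwknn_fit()` stores the training vectors; scoring a query finds its
K = 13 nearest training pairs by Euclidean distance and weights them as

\[ w_k = \frac{d_K - d_k}{d_K - d_1}, \]

with all weights 1 when \(d_K = d_1\). The score is the weighted fraction
of interacting neighbors, and a pair is called positive only when the
score is **strictly** greater than the threshold (default 0.5), so a score
exactly at the threshold is negative.

`ensemble_fit()` bags this learner: one wordbook per bundled AAindex scale
(hydropathy, molecular weight, isoelectric point, and the two terminal-pK
scales), 4 engines per scale, each with K drawn uniformly from [1, 15] and
an independent per-feature discard mask (discard probability 0.05,
redrawn if it would discard everything). The ensemble score is the plain
mean of the base-learner scores. Training pairs are not resampled by
default (`bootstrap = FALSE`).

## Parameter defaults and why

| Parameter | Default | Rationale |
|---|---|---|
| wordbook sizes | 20/30/58 for lengths 2/3/4 | the published configuration; total receptor dimension 128 mirrors the drug block |
| fragment sampling | all sliding fragments | deterministic; `sampling = "random"` (500 per sequence) reproduces the cheaper published variant, falling back to sliding when a sequence has fewer fragments |
| K | 13 | the published operating point |
| threshold | 0.5 | symmetric default; `max_mcc_threshold()` finds the MCC-optimal value when a calibrated cutoff is wanted |
| ensemble | 5 scales × 4 engines, K ∈ [1, 15], 5% discard | the published bagging design |

## Numerical conventions

These choices are deliberate and tested:

* **k-means**: `stats::kmeans` with `nstart = 10` and 300 iterations,
  seeded per fragment length; centers are sorted lexicographically so a
  wordbook is a canonical object independent of cluster-label
  permutations. (The original method used a kmeans++-style seeding; the
  standard multi-restart Lloyd's algorithm is used here instead.)
* **Word assignment ties** go to the lowest word index (`which.min`).
* **Degenerate sequences**: a sequence shorter than a fragment length
  contributes an all-zero histogram for that length; every non-degenerate
  histogram sums to 1.
* **Unknown residues** (`B J O U X Z`, etc.) are assigned the mean index
  value by default (preserving fragment counts) or dropped on request.
* **DFT**: computed by `stats::fft`; the DC term is included, so constant
  fingerprints map to a spike at coefficient 1. Note the normalized
  magnitude spectrum is invariant to cyclic shifts and positive rescaling
  of the fingerprint — distinct drugs can collide if their fingerprints
  are related that way.
* **DWKNN ties**: neighbors are ranked with `order()`'s stable sort over
  training rows pre-sorted by (gpcr_id, drug_id), so scores do not depend
  on input row order.
* **Strict threshold**: `score > t`, verified at `score == t`.
* **MCC** is defined as 0 whenever its denominator vanishes.
* **ROC AUC** uses trapezoidal integration over tie-grouped thresholds and
  equals the Mann–Whitney rank statistic exactly (a tested identity).
* **Model persistence** writes doubles as `%.17g` and reparses them with
  base R's correctly rounded converter, so reloaded models score
  bit-identically even where neighbor distances nearly tie.

## Evaluation protocols

`cross_validate()` offers stratified k-fold CV (default k = 10) and
pair-level leave-one-out CV.

* In k-fold CV the wordbook is rebuilt from each fold's training
  sequences by default (`rebuild_wordbook = "fold"`), keeping the held-out
  fold untouched by feature learning.
* In LOOCV the wordbook is built once from all sequences and each pair is
  excluded only from the neighbor search. Rebuilding per held-out pair
  would be quadratic in corpus size for negligible leakage: a single
  pair's receptor usually remains in the corpus through its other pairs.

Reported metrics: sensitivity, specificity, accuracy and their mean
("strength") in percent, MCC, AUC, and the MCC-optimal threshold.

## The synthetic generator

Real GPCR benchmarks are external downloads, so `generate_dataset()`
manufactures datasets with a controllable planted signal:

* Each receptor and each drug belongs to one of `n_classes` latent
  classes. An interacting pair is (before noise) a class match.
* **Receptor signal**: a class-specific tripeptide motif (e.g. `IVI`)
  tiled roughly once per 10 residues of otherwise uniform random sequence;
  dense enough that motif words dominate the fragment histograms.
* **Drug signal**: a class-specific 32-character square-wave block
  (distinct period per class) written at a class-specific offset over a
  sparse random bit background (density 0.10). Square waves give each
  class a distinct line spectrum; constant blocks would be invisible
  because nearly all their energy lands in the shared DC term.
* `motif_strength` is the probability that a molecule carries its class
  signal at all, gating both modalities; `noise` flips labels
  independently.

Defaults (30 receptors of 50–1000 residues, 60 drugs, 400 pairs, positive
fraction 635/1860, `motif_strength` 0.9, `noise` 0.05) are the package's
study conditions. Under them a single base learner reaches pair-level
LOOCV AUC around 0.85–0.91 and the ensemble matches or beats it; with
`motif_strength = 0` the AUC sits near 0.5.

Null-calibration runs use a larger, sparser design (60 receptors, 120
drugs, 800 pairs): in small dense designs, LOOCV self-exclusion inside
same-receptor neighborhoods biases the null AUC away from 0.5 even though
no signal exists.

What the generator does **not** emulate: real GPCR family structure,
homology between receptors, realistic FP2 bit correlations, or the
chemical similarity structure of real ligands. It validates the pipeline's
ability to recover a planted sequence+fingerprint signal — nothing more.

## Limitations

* AAindex values are bundled for five scales only; others can be loaded
  from AAindex1 flat files or two-column tables via `read_aaindex()`.
* Fingerprints must be exactly 256 hex characters (the FP2 convention
  used here); other fingerprint lengths are rejected rather than padded.
* The published benchmark tables can only be reproduced with the external
  datasets; `inst/scripts/benchmark_protocol.R` documents that protocol.
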