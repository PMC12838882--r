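---
title: "Methods: max-pooled attention sleep staging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: max-pooled attention sleep staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maxsleep)
```

## The model and its assumptions

`maxsleep` classifies the sleep stage of the last of `L` consecutive
30-second single-channel EEG epochs sampled at 100 Hz. The pipeline has
three learned stages — a convolutional feature extractor (FE), a Transformer
sequence encoder with max-pooled keys and values (TSE), and an attention
pooling classifier (AS2C) — plus a contrastive projection head used only
during pre-training.

The central efficiency idea exploits a property of sleep EEG: the signal is
highly redundant in time, and stage-discriminative events (spindles,
K-complexes, delta waves) are sparse, high-amplitude excursions. Max pooling
the key/value token sequence by a stride `n` before the attention
projections keeps exactly those high-response components available to every
full-resolution query while cutting the score and aggregation cost by a
factor of `n`. The assumption is therefore that attention needs precise
*query* positions but only a salient *summary* of the context. The
average-pooling variant (AvgFormer) replaces the summary statistic and is
available behind the same `pool_mode` switch; `pool_mode = "none"` recovers
the standard Transformer, and the implementation guarantees (and tests) that
stride 1 is *numerically identical* to standard attention.

Training is two-phase. Phase 1 minimizes the supervised contrastive (Supcon)
loss over multiview batches: each sequence is augmented twice, projections
are L2-normalized onto the unit hypersphere (so cosine similarity is a dot
product), positives are all same-stage samples in the batch, and the
denominator runs over all other samples. Phase 2 freezes FE and TSE and
fits only AS2C with a cross-entropy summed over pyramid scales. Freezing is
a contract, not an optimization detail: the tests assert the encoder
parameters are bitwise unchanged. A `freeze_encoder = FALSE` flag exposes
the full-fine-tuning ablation axis.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `L` | 10 | epochs | with reductions 25/125/625 this yields token lengths 1200/240/48, the canonical pyramid; exposed in `model_config()` |
| `d_f` | 128 | channels | embedding width of encoder and classifier |
| encoder depth | 6 | layers | performance saturates around this depth |
| heads | 8 | — | `d_k = d_f / h = 16` |
| `ffnn_ratio` | 1 | — | FFNN hidden width equals `d_f` |
| `pool_stride` (`n`) | 6 | tokens | best accuracy/cost trade-off; `n = 48` collapses the coarsest scale to one token and still works for pyramid backbones |
| dropout | 0.1 | — | on attention weights and the FFNN hidden layer; unspecified upstream, standard Transformer value |
| `tau` | 0.07 | — | Supcon temperature |
| optimizer | AdamW, lr 1e-4, eps 1e-8, betas 0.9/0.999, decay 0 | — | classification batches 1024, contrastive batches 128 |
| validation interval | 400 (SCL) / 50 (CE) | iterations | patience 20 evaluations, minimum-validation-loss checkpoint kept |
| augmentation | amplitude shift ±10, scale 0.5–2, time shift ±300 samples, zero mask ≤300 samples, 2-Hz band-stop with lower edge in 0.5–30 Hz, noise σ ≤ 0.2, each with probability 0.5 | mixed | noise σ is in units of the z-scored signal's standard deviation, since recordings are normalized at generation/ingest time |

## What the synthetic generator emulates — and what it does not

`generate_dataset()` draws a hypnogram from a sticky Markov chain whose
stationary distribution matches requested class weights (default: the
Sleep-EDF distribution 35.0/10.8/34.7/6.5/13.0% with self-transition 0.85,
mimicking stage persistence), then synthesizes each epoch as band-limited
Gaussian noise per stage-specific oscillation band over a weak 1/f
background, plus spindle bursts and K-complex-like deflections for N2,
scaled by a stage-specific baseline amplitude and z-scored per recording.
The default stage signatures follow the textbook picture: posterior alpha
in wake, low-amplitude theta in N1, spindles over theta in N2,
high-amplitude delta in N3, and mixed-frequency activity with elevated fast
components in REM.

These are spectrally controllable *fixtures*, not physiology. By design the
five classes are linearly separable from band powers (a nearest-centroid
classifier exceeds 90% accuracy, and the tests pin this), which is what
makes the end-to-end training checks meaningful: if the contrastive →
frozen-classifier pipeline cannot recover separable classes, something is
wrong with the learning machinery. Conversely, success here says nothing
about real polysomnography, where stage boundaries are ambiguous, artifacts
abound, and inter-scorer agreement itself is limited — benchmark accuracy
on clinical datasets is explicitly outside this package's test scope.

## Numerical choices

- **Sublayer topology.** Residual connections wrap both the attention and
  FFNN sublayers, with post-sublayer layer normalization — the original
  Transformer arrangement. Layer norm is toggleable (`layernorm = FALSE`);
  with it off and zeroed output projections, an encoder layer is exactly the
  identity, a property the tests use. The stride-1 equivalence pins the rest
  of the topology.
- **Positional encoding pairing.** Sinusoid frequencies use the classic
  `⌊j/2⌋` pairing (sin on even rows, cos on odd rows at the same
  frequency), which is the only pairing under which the coarse-scale
  encoding reduces exactly to the classic form at the finest scale. The
  hop offset is the window center `⌊R^{i−3}/2⌋`.
- **Ragged tails.** Pooling uses `⌈T/n⌉` windows; the last window pools
  over its valid entries only (equivalent to −∞ padding for max). The toy
  backbone zero-pads ragged scale transitions the same way, so the
  classifier-visible token count is always `⌈3000L/r_i⌉`.
- **AS2C scoring.** The scalar attention score is the inner product of a
  learnable context vector with the tanh-transformed attention state
  (SeqSleepNet-style); ties in the fused argmax break to the lowest class
  index for determinism.
- **FLOPs accounting.** One multiply-accumulate = 1 FLOP; softmax,
  layer-norm, bias and activation costs are excluded, and `L` in the cost
  formulas is the *token* sequence length, not the number of sleep epochs.
  The max-pooled projection constant `(2 + 2/n + 2r)` equals the standard
  `(4 + 2r)` at `n = 1`, so the two accountings coincide there. The
  empirical oracle counts actual matrix-product dimensions during a real
  forward pass and agrees with the closed forms exactly by construction of
  the accounting.
- **Degenerate inputs.** Zero-amplitude stage specifications produce
  all-zero epochs; per-class F1 with a zero denominator is defined as 0 and
  flagged; Cohen's κ with chance agreement 1 is reported `NA` with a
  warning; Supcon anchors without positives are skipped with a warning;
  projector normalization is epsilon-guarded.
- **Seeding.** Every stochastic component (hypnogram, epoch synthesis,
  augmentation draws, batching, dropout, initialization) derives a named
  substream from one master seed via a 32-bit mixing function, so components
  are independently reproducible and adding one transform does not perturb
  another's draws.
- **Gradient correctness.** There is no autodiff here; every backward pass
  is hand-derived and pinned by central finite-difference tests (relative
  error below 1e-5 on random parameters of every layer type).

## Open design points and how they were resolved

- *Augmentation granularity:* transforms are applied to the whole
  `X(L)` sequence (a per-epoch variant would multiply filtering cost by
  `L`); positives for the contrastive loss are defined by the label of the
  target epoch of each sequence.
- *Multi-scale aggregation* of the Supcon loss is by summation over scales
  (mean would only rescale the learning rate).
- *The projector is discarded* after phase 1, the standard contrastive
  practice; only FE + TSE weights feed fine-tuning.
- *Validation intervals* default to 400/50 for all dataset profiles.
- *Sleep-EDF profile* assumes native 100 Hz (no resampling) and applies
  30-minute wake trimming; the other profiles resample and do not trim.
- *Query pooling* (pooling along the embedding dimension of Q) degrades
  accuracy and is deliberately not implemented; only key/value pooling is.

## Problem sizes used by the shipped checks

The test suite and examples run a deliberately small configuration chosen
to exercise every code path on one CPU core: single-scale backbone with
`d_f = 32`, 2 encoder layers, stride 6, `L = 1`, 360 synthetic epochs from
6 subjects, contrastive batches of 32 for at most 100 iterations and
classifier batches of 64 for at most 250. Under these conditions the
two-phase pipeline reaches perfect held-out accuracy on the separable
synthetic stages, and swapping max-pooled attention for standard attention
changes accuracy by about one point — the desk-scale analogue of the
published comparability claim. Oracle comparisons (nested-loop attention,
double-loop Supcon, brute-force metric tallies) run on 8–64-token inputs.

## Known limitations

- No GPU or multicore path; the hand-written numerics are for inspection,
  testing and desk-scale experiments, not large-cohort training.
- The EDF writer/reader covers the minimal single-rate, 16-bit contract
  used for data exchange here, not EDF+ annotations.
- Real-data benchmark performance is out of scope; no claims are made
  beyond the synthetic recovery and the analytic cost model.
- Sequence-to-sequence scoring (one label per epoch of the window) is not
  provided; each window yields one target-epoch label.
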