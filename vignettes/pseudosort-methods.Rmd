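---
title: "Self-supervised spike sorting with density-based pseudolabels: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-supervised spike sorting with density-based pseudolabels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Extracellular electrodes record the summed activity of several nearby
neurons. Spike sorting assigns every detected action-potential waveform to
its putative source neuron, turning a single voltage trace into per-neuron
spike trains. `pseudosort` implements a self-supervised sorting pipeline for
single-channel recordings:

1. **Preprocessing** — bandpass filter (300–3000 Hz), robust noise estimate
   $\sigma_m = \mathrm{median}(|x|)/0.6745$, threshold detection at
   $5\sigma_m$ (negative-going), extraction of 64-sample windows (20 samples
   before the event, 44 from the event on), trough alignment, per-spike
   min–max normalization to $[0, 1]$, and mapping to the 63-dimensional
   gradient $\nabla x(t) = (x(t{+}1) - x(t))/\Delta t$ with
   $\Delta t = 50\,\mu s$ at 20 kHz.
2. **Contrastive pretraining** — a fully connected encoder
   $[63, 500, 500, 2000, 10]$ with ReLU hidden activations is trained
   self-supervised: each spike is augmented twice with Gaussian noise
   (maximum relative level 0.075 of the feature range), and the loss
   $$\mathcal{L} = -\log \frac{\exp(\mathrm{sim}(z_i, z_i^+)/\tau)}
   {\sum_j \exp(\mathrm{sim}(z_i, z_j)/\tau)}, \qquad \tau = 0.1,$$
   with cosine similarity $\mathrm{sim}$, pulls each embedding toward its
   nearest neighbor in a FIFO memory queue of past embeddings (the
   positive $z_i^+$) while contrasting against other samples. 25 epochs,
   batch 256, Adam at $10^{-3}$.
3. **Pseudolabel generation** — KNN density in the 10-d latent space (the
   inverse mean distance to the $K$ nearest neighbors, $K = 0.5\%$ of $n$),
   then sampling of high-confidence spikes either as the densest fraction
   ("densest") or by rank-weighted sampling without replacement
   ("weighted"); K-means++ on the sample assigns provisional classes. The
   class count comes from the elbow method on the densest 50% of the latent
   space, searched over $k \in [2, 20]$.
4. **Iterative fine-tuning** — the encoder gets a $k$-wide classification
   head and is trained with cross-entropy on the pseudolabeled subset
   (augmentation level 0.1, 50 epochs, batch 128), over a growing fraction
   schedule $0.01, 0.05, 0.10, 0.15, 0.20, 0.30, 0.40$; embeddings are
   recomputed and pseudolabels resampled between iterations. Final labels
   are the head's argmax over all spikes.

Evaluation uses *matched accuracy*: the fraction of spikes correct under the
best one-to-one (Hungarian) assignment between predicted and true classes.
A PCA + Gaussian-mixture sorter (`baseline_pca_gmm()`) serves as the
classical baseline, and unit quality is screened post hoc via the
refractory-period violation (RPV) rate (strictly below 0.1% at 2 ms) and
characterized by FWHM and trough amplitude.

## Design choices in detail

**Contrastive contrast set.** The loss above leaves open what the
denominator sums over. Using only the memory queue turned out to be
degenerate: queue entries are constants with respect to the gradient, so the
only learnable signal is attraction toward the queue neighbor and the
representation collapses to a point (we measured within/between class
distance ratios near 1 and chance-level cluster accuracy). `pseudosort`
therefore uses the batch as the contrast set, symmetrized over the two
augmented views: for each view-1 anchor, its queue nearest neighbor is
scored against all view-2 embeddings of the batch (positive on the
diagonal), and vice versa. Inter-sample repulsion then carries gradient and
the embedding stays spread. The queue (default 8192 entries, clipped to
$n$) is refreshed FIFO with the second view's embeddings each step.

**Projection head.** The loss operates on a two-layer projection head of
width 10 on top of the bottleneck; pseudolabeling and classification use
the 10-d bottleneck itself.

**Input conditioning.** Gradient features carry a $1/\Delta t$ factor
(units 1/s, magnitudes in the thousands). A single dataset-level constant
rescales them to mean absolute value 1 before they enter the network; the
constant is stored in the encoder and applied identically at embedding,
fine-tuning and prediction time. This affects optimization conditioning
only, not the features seen by any other module.

**Weighted sampling.** The "exponential decay overlaid on the normed
density distribution" is implemented rank-based: weight
$w_i = \exp(-\lambda\, r_i)$ with $r_i$ the density rank normalized to
$[0, 1]$ (0 = densest) and $\lambda = 5$, giving roughly $e^5 \approx 148$:1
odds for the densest versus the sparsest point while keeping every point
selectable. Rank-based weights are invariant to the density scale.
Sampling is without replacement and always returns exactly
$\lceil \text{fraction} \cdot n \rceil$ unique indices.

**Elbow operationalization.** For each $k$ the within-cluster sum of
squares of K-means++ (the lowest of 3 restarts — WCSS is a minimum over
partitions, so the best restart estimates it, as in `stats::kmeans`'
`nstart`) forms the inertia curve;
the estimate is the $k$ of maximum perpendicular distance to the chord
joining the curve's endpoints (Kneedle-style), clamped to $[2, 20]$. Ties
resolve to the smaller $k$.

**K estimation schedule.** $k$ is estimated once after pretraining on the
densest 50% of the latent space and held fixed, so the head width never
changes mid-run; re-estimation per iteration is available behind
`reestimate_k` in `finetune_config()`. When the neuron count is known (as
in benchmark protocols that provide it to every sorter), pass `k` to
`run_pseudosorter()` directly.

**Fine-tuning loss and scope.** Categorical cross-entropy on the
pseudolabels; the full network (encoder and head) is trainable, Adam at
$10^{-3}$. Each iteration re-clusters the sampled subset from scratch, so
K-means++ class identities are arbitrary; before training they are aligned
to the persistent head's current predictions by max-agreement one-to-one
matching, letting successive iterations refine the same classes instead of
re-learning a permutation. Only the final head's labels are reported.

**Matching convention.** Matched accuracy uses maximum-weight one-to-one
(Hungarian) assignment on the confusion matrix. Many-to-one matching would
inflate scores when a sorter splits a true class. Unmatched predicted
classes contribute zero.

**FWHM baseline.** Peak amplitude is the trough value against a 0 µV
baseline (bandpassed waveforms are zero-mean); half-amplitude crossings are
located by linear interpolation between samples on each side of the trough.

## The synthetic-data generator

`generate_recording()` and `generate_waveform_dataset()` emulate the
statistics of single-electrode benchmark simulations so the whole pipeline
is testable without external data:

- 5–15 source neurons; per-neuron firing rates uniform in 15–35 Hz;
  normalized electrode distances uniform in $[0, 1]$.
- Templates are sums of two or three Gaussian lobes with randomized widths,
  latencies and amplitude ratios (biphasic/triphasic, trough normalized to
  −1 at sample index 20), spanning FWHMs of roughly 0.1–0.5 ms at 20 kHz.
- The amplitude–distance law $A(d) \propto (1 + \alpha d)^{-1}$ maps
  distance 0 to the top of `target_snr_range` (default 12, near the
  benchmark maximum of ~11.6) and distance 1 to its bottom (default 4), so
  per-spike SNR is strictly decreasing in distance.
- Spike trains are homogeneous Poisson with an absolute refractory dead
  time (2 ms); overlaps across neurons are allowed, never within a neuron.
- Raw traces carry white Gaussian background noise (the detection path
  bandpasses it). Isolated waveform datasets instead carry *bandlimited*
  (300–3000 Hz filtered) noise scaled to `noise_sigma`: isolated spike
  files originate from filtered recordings, and their noise smoothness
  matters — with white per-sample noise the gradient mapping is
  noise-dominated and every sorter, including the PCA-GMM baseline,
  performs at chance.

What the generator does **not** model: compartmental biophysics, a
background population of distant neurons, electrode drift, multi-channel
geometry, or spike-shape variability within a neuron beyond additive noise.
Passing tests on synthetic data therefore demonstrate the pipeline's
mechanics and relative ordering of methods, not absolute accuracy on tissue
recordings.

## Numerical choices and degenerate inputs

- Distances of coincident latent points are guarded with
  $\varepsilon = 10^{-12}$ in `knn_density()`, keeping densities finite.
- Flat (constant) waveforms map to all-zero gradient rows and are flagged
  rather than dropped, keeping row indices stable.
- K-means++ runs that end with an empty cluster restart with a fresh
  seeding up to 5 times.
- Densest sampling resolves ties at the cut by ascending index.
- Zero-norm embeddings raise an error in the exported loss (cosine
  undefined) and are left as zero vectors inside the training loop.
- All randomness flows from explicit integer seeds; identical
  configurations and seeds reproduce results bit for bit.

## Problem sizes used in the checks

Training a $[63, 500, 500, 2000, 10]$ network on $10^5$–$10^6$ spikes for
25 + 7×50 epochs is a GPU-scale undertaking; the package's behavioral
checks run the same code at desk scale: $10^4$ spikes, 5 pretraining
epochs, three fine-tuning iterations (fractions 0.05/0.2/0.4, 10 epochs
each) for the baseline comparison, and 3000 spikes with a shared pretrained
encoder, five seeded fine-tuning runs over the full 7-fraction schedule
(3 epochs per iteration), for the accuracy-retention check. The elbow
recovery check uses 3000-point Gaussian blob fixtures at 20σ separation.
These sizes are the package's own scaled-down study conditions; the
reference hyperparameters remain the defaults of the configuration
objects.

## Known limitations

- Single-channel only; no drift handling or multi-electrode fusion.
- The contrastive stage needs a few hundred optimizer steps before the
  latent space organizes; very small datasets (under ~1000 spikes) gain
  little from pretraining.
- The elbow estimate inherits K-means' bias toward compact spherical
  clusters and tends to underestimate the neuron count when clusters
  overlap — the dominant failure mode of cluster-count estimation in this
  setting.
- Unit identity across recording phases (pre/post treatment) assumes one
  model applied to both phases; no drift-aware re-matching is attempted.
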