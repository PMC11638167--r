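---
title: "Decoding motor imagery with a geometry-anchored dynamic electrode graph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding motor imagery with a geometry-anchored dynamic electrode graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The decoding problem

Motor imagery (MI) — the mental rehearsal of a movement — modulates
sensorimotor rhythms in a band- and location-specific way: hand imagery
shifts mu/beta power over the contralateral hand area (electrodes
C3/C4), foot imagery over the vertex (Cz). A four-class MI
brain-computer interface must therefore resolve *which frequency bands*
changed and *where on the scalp*, from 1-s segments of 64-channel EEG
that are individually extremely noisy. The two stages of `dganet` mirror
those two questions: a multi-scale temporal-convolution module learns
frequency-selective features per electrode, and a graph attention
network integrates them across electrodes along a connectivity graph.

The distinguishing choice is how that graph is obtained. A fixed,
geometry-derived adjacency cannot adapt to individual differences in
activation topology; a fully learned adjacency can drift into noise and
drop physiologically essential nodes. Here the graph starts from an
inverse-distance prior `E` over the montage and is periodically
re-weighted by the learned similarity of node embeddings,
`P = E · K^γ` with `K ∈ (0, 1]` — so adaptation can only *attenuate*
prior edges, never invent connections between electrodes the geometry
deems unrelated. The support and the upper envelope of the graph remain
those of the head geometry throughout training; this invariant is
asserted in the test-suite after every update.

## Model and parameters

Per segment `x ∈ R^{64×160}` (1 s at 160 Hz):

* **Temporal scales.** Kernel lengths `k = (3, 7, 15)` taps with three
  layers of depth 3 per scale and a residual from layer 1 into layer 3's
  pre-activation. Short kernels pass fast structure, long kernels slow
  structure; together they give a 9-dim learned multi-band decomposition
  at every (electrode, time) position. Weights are shared across
  electrodes, so this stage is exactly equivariant to electrode
  permutation (tested).
* **Attention pooling.** A shared 9→16→9 MLP produces softmax weights
  over the 9 feature maps at each position; pooling is the resulting
  convex combination. A single scalar weight per position could not
  implement a weighted average over the feature axis, so the weights
  live on that axis — the only reading under which "softmax + average
  pooling" is well-defined; the weights summing to 1 at every position
  is asserted to 1e-6.
* **Graph attention.** 3 layers, 4 heads of 32 dims. Logits are the
  standard additive form `LeakyReLU(a_src·Wh_u + a_dst·Wh_v)` (slope
  0.2) plus `log P_uv`; the additive log bias is equivalent to
  multiplying the attention kernel by `P_uv` before normalization, which
  keeps α a probability distribution while letting an edge fade out
  smoothly as `P_uv → 0`. Self-loops are explicit with bias `log 1 = 0`;
  the diagonal of `P` itself stays zero, so `1/dist` never divides by
  zero.
* **Graph update.** `K_uv = ξ/(‖G³_u − G³_v‖₂^δ + ξ)` with
  `γ = 1, δ = 2, ξ = 0.5`, computed from the per-node mean of
  third-layer embeddings over the preceding epoch (a per-batch statistic
  would make the graph noisy), applied every 10 epochs. `K = 1` at zero
  distance and decreases strictly with embedding distance, which makes
  `P ≤ E` automatic for `γ ≥ 0`.
* **Head and optimization.** Flatten 64×32 node features, one linear
  map, softmax; Adam, lr 0.01, weight decay 1e-4 (weight decay is our
  reading of the published "learning-rate decay" next to Adam; an
  explicit per-epoch schedule is available via `train_config(lr_schedule=)`),
  800 epochs at full scale, batch 64. σ = ELU throughout (the published
  description names no activation); the MLP inside the attention pool is
  fixed to ELU, the convolution stacks accept any of elu / relu / tanh /
  identity.
* **Initialization.** Glorot-uniform from the model seed, zero biases.
  Identical seeds give bit-identical models and training runs under
  single-threaded numerics (asserted).

## Montage geometry

The published source cites MNI electrode coordinates without printing
them; since `E` only uses *relative* distances and is rescaled to max 1,
any faithful 10-10 geometry yields the same normalized prior up to small
distortions. We ship an idealized unit-sphere construction of the
64-channel extended 10-10 set: vertex at the top, the 10-10
circumference circle at 72° inclination (through FPZ, T7, OZ, T8),
midline electrodes every 18° along the nasion–inion arc, T9/T10 at the
90° preauricular level, and interior row electrodes by spherical
interpolation between the row's midline and circumference members. The
construction lives in code (`dganet:::spherical_1010_coords`) and as a
packaged TSV; tests pin the qualitative invariants (C3–C4 farther apart
than C3–C1, symmetry, positivity).

## Data protocol

Trials are 4 s (640 samples); the sliding window (length 160, stride 20)
yields 25 segments per trial, 2,100 for an 84-trial subject. Splits are
**trial-level, stratified by class, before windowing** — overlapping
windows of a single trial would otherwise leak between train and test;
the test-suite checks that no trial id crosses the split. Per class,
`floor(0.8 · n)` trials train and the remainder test. Within-subject
evaluation repeats the split/train/test cycle five times and reports
each repeat plus the mean; cross-subject evaluation draws disjoint
20-train / 5-test subject sets per repeat. Accuracy is per *segment*; a
trial-level majority-vote number is reported alongside, clearly labelled
as a convenience metric outside the protocol.

The PhysioNet-style loader cuts trials at T1/T2 annotation onsets, maps
runs 4/8/12 to left/right fist and runs 6/10/14 to both-fists/both-feet
(the dataset's standard convention; the source does not spell out the
mapping trial-for-trial), skips baseline and executed-movement runs, and
excludes subjects 88, 89, 92, 100, 104. No band-pass is applied by
default — the source recordings are already 1–35 Hz filtered, and
filtering twice would distort the band edges; `bandpass_trials()`
provides a 4th-order zero-phase Butterworth for genuinely raw input.

## The synthetic generator

The generator exists so the whole pipeline is exercisable without any
download, and it emulates exactly the structure the decoder exploits:

* per class, a band-limited sinusoid (random frequency inside the class
  band, random phase) whose amplitude falls off as a Gaussian
  `exp(−d²/2σ²)` of scalp distance from a class-specific focus electrode
  (left fist → C4, right fist → C3 in the 8–12 Hz mu band; both feet →
  CZ in mu; both fists → CZ in 18–26 Hz beta so the two midline classes
  are spectrally distinct);
* background noise with a `1/f^0.7` amplitude spectrum plus 20% white
  sensor noise, unit power per channel;
* `snr_db` sets oscillation power relative to that background at the
  focus electrode — the single "separability dial";
* per-subject log-normal channel gains (σ = 0.2) and a ±1 Hz class-band
  shift model cross-subject variability.

What it deliberately does **not** model: volume-conducted mixing with
realistic leadfields, event-related *de*synchronization (we add rather
than suppress power — the decoder is agnostic to the sign), artifacts
(blinks, EMG), nonstationarity within a trial, or electrode
displacement. Passing tests on this generator therefore demonstrate that
the architecture and optimization *recover planted spatial-spectral
class structure*, not that any particular accuracy transfers to real
recordings.

`class_separability()` (between/within scatter of log band-power
features) is tested to be monotone in `snr_db` and ≈ (K−1)/(N−K) for
pure noise; a nearest-centroid band-power classifier in the test-suite
serves as the independent oracle that the planted signal is actually
recoverable.

## Numerical choices

* All forward/backward passes are authored here: vectorized R
  composition over RcppArmadillo kernels for the convolution, the
  attention pool and the per-graph attention softmax. Analytic gradients
  for every parameter group are verified against central finite
  differences (rel. error < 1e-4 asserted; observed ≈ 2e-7).
* Both network modules are additionally pinned to naive nested-loop
  reference implementations on small instances (tolerance 1e-6).
* `log P` uses a 1e-12 floor; masked (absent) edges carry −∞ before the
  softmax so they get exactly zero attention.
* ELU derivatives are computed from cached outputs (`min(y+1, 1)`),
  avoiding a second exponential pass.
* t-SNE is the exact O(N²) algorithm (perplexity by bisection, early
  exaggeration 12, momentum 0.5→0.8, gains), adequate for the ≤ ~1,000
  segments a visualization uses.
* Two silhouette measures are exposed and they are *not*
  interchangeable: `stage_silhouette()` scores the class structure of
  the stage features themselves, while `tsne_features()$silhouette`
  scores the 2-D embedding. Because t-SNE preserves local neighborhoods
  rather than global geometry, a stage with class-pure local structure
  but poor global separation can receive a higher *embedding* silhouette
  than a stage that is better separated in feature space — we observed
  exactly this inversion for the raw pooled frequency features. The
  quantitative separability comparison between stages therefore uses
  the feature-space silhouette; the embedding silhouette only annotates
  plots.

## Desk-scale test conditions

The full published regime (109 subjects, 800 epochs) is not meaningful
for a self-contained test-suite, so the learning checks run the complete
pipeline at reduced size with the architecture untouched: one synthetic
subject, 8 trials/class at +10 dB, 12 training epochs with graph updates
every 2 epochs (≈ 600 training segments), which lands the decoder far
above the four-class chance level on ~200 held-out segments; the
no-signal control runs 2 epochs at −100 dB and must sit at chance. The
schedule check trains a miniature 4-electrode model for a full 334
epochs and counts 33 graph updates rather than asserting the arithmetic.
`scripts/acceptance.R` re-runs all of this from scratch against the
installed package and writes the numbers as JSON.

## Known limitations

* The desk-scale decoder is far from converged; its accuracy numbers
  characterize the test conditions, not the method's ceiling.
* The adjacency update is a hard replacement `P = E·K^γ` each period; no
  smoothing between updates is applied (none is described in the
  source). With `γ = 0` the graph is static, which is the natural
  ablation.
* Silhouette-on-t-SNE inherits t-SNE's seed sensitivity and its
  local-structure bias (see above); treat it as a plot annotation, not a
  statistic.
* The EDF reader covers the subset of EDF+ used by PhysioNet-style
  recordings (uniform 16-bit signals, one annotation channel); it is not
  a general EDF implementation.
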