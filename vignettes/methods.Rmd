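---
title: "Decoding affect from EEG: differential-entropy grids and an efficient transformer encoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding affect from EEG: differential-entropy grids and an efficient transformer encoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`eegemotion` classifies affective state — valence, arousal and dominance,
each rated per stimulus on a continuous scale — from multichannel EEG. This
vignette explains the model, its assumptions, the tunable parameters, the
synthetic data the package tests itself against, and the numerical choices
that an applied user or a reviewer would want spelled out.

## The feature model

EEG is segmented into non-overlapping one-second windows (trailing
remainders shorter than a window are dropped, so segment counts are exact
integers). Each window is band-pass filtered into four canonical bands —
theta (4–8 Hz), alpha (8–13 Hz), beta (13–31 Hz), gamma (31–45 Hz) — with a
fourth-order Butterworth filter applied forward and backward. The zero-phase
choice is ours: the four band-filtered copies of a segment then stay
time-aligned, so no plane of the final tensor carries a band-dependent group
delay. Filtering is implemented as a vectorised direct-form-II recursion
applied to thousands of (segment, channel) rows simultaneously; it is
validated in the test suite against `signal::filter()` row by row at 1e-9.

Each filtered window is summarised per channel by its **differential
entropy** under a Gaussian model,

$$\mathrm{DE}(X) = \tfrac{1}{2}\log\!\left(2\pi e \sigma^2\right),$$

with $\sigma$ the sample standard deviation and natural logarithms
throughout. For band-limited EEG on one-second windows the Gaussian
approximation is the standard working assumption in this literature; the
closed form makes the feature cheap and analytically checkable (a doubling
of amplitude must shift DE by exactly $\ln 2$, which the tests assert to
1e-12).

DE values are min-max normalised to $[0, 1]$ **per subject, per channel,
per band**, with the statistics computed over all of that subject's
segments. Pooling statistics across the whole subject before
cross-validation mirrors the protocol evidenced by the magnitudes of
published subject-dependent results; it does leak weak information (the
fold-wise extrema) into test folds. `run_experiment(strict_normalization =
TRUE)` therefore recomputes the min/max from each fold's training segments
only; the default is the pooled protocol. A constant channel (zero range)
normalises to 0 rather than NaN, and is flagged upstream as a degenerate
segment when its band-passed variance is exactly zero.

Each band's normalised values are placed on a sparse **9 × 9 scalp grid**
at cells fixed by a channel layout following 10–20 electrode geometry
(row 0 frontal; unmapped cells exactly 0). The layouts are plain CSV
configuration files under `inst/extdata/`, not code constants — a user with
a different montage supplies their own table. A second set of four planes
applies the logarithmic dynamic-range enhancement

$$M_1 = \log(1 + 255\,M),$$

which expands contrast near zero the way the classic log transform does for
8-bit images. The published description of this transform is ambiguous
about whether the factor of 255 multiplies inside or outside the logarithm;
we read it as the inside-coefficient form (the classic transform) and
expose the outside form via `enhance(mode = "outside")`. Stacking DE and
enhanced planes gives the 8 × 9 × 9 input tensor (`feature_set = "both"`);
either half alone gives 4 × 9 × 9 (`"de_only"`, `"enhanced_only"`).

## The classifier

The network is deliberately compact:

1. **Convolutional front-end.** Two 3 × 3 convolutions (stride 1, padding 1,
   channels $C \to 32 \to C$), each followed by ReLU. The source
   architecture lists no activation; a purely linear double convolution
   would collapse to one linear map, so ReLU — the minimal conventional
   choice — is used.
2. **Tokenisation.** Each of the $C$ planes is flattened row-major into a
   token of width $d = 81$; two trainable tokens (initialised
   $\mathcal{N}(0, 0.02^2)$) are prepended, giving $n = C + 2$ tokens. The
   origin of the two extra tokens is not explained in the source
   description; learnable prepended rows are our interpretation, and they
   demonstrably receive gradient.
3. **Encoder stack** ($L = 15$ pre-norm blocks). The attention is the
   efficient linear-algebraic form
   $$\mathrm{ISA}(Q,K,V) = \Big(D \odot Q \odot \big(U_{copy}\,
     (\tfrac{K}{\|K\|_2} \odot \tfrac{V}{\|V\|_2})\, U_{sum}\big)\Big)
     U_{proj},$$
   with $[Q,K,V] = z\,U_{qkv}$ (bias-free), per-token L2 norms over the
   feature axis (guard $\varepsilon = 10^{-6}$), $D$ an $n \times d$
   trainable scaling matrix initialised to ones, $U_{copy}$ an $n \times n$
   token-mixing matrix initialised uniform $1/n$, and $U_{sum}$, $U_{proj}$
   $d \times d$. The published equations define a scale for $Q$ but never
   use it, while using a scale for $K$ they never define; we scale $K$,
   symmetric with $V$, and leave $Q$ unscaled. The shapes of the two mixing
   matrices are also unstated; the left-token/right-feature reading used
   here is the printed application order. Both points are genuine
   ambiguities, which is why the package's efficiency audit reports its own
   counts rather than claiming to reproduce published totals.
4. **Block wiring.** $z' = \mathrm{ISA}(\mathrm{LN}(z)) + z$, then
   $z_{\text{next}} = \mathrm{Linear}(\mathrm{GELU}(\mathrm{Linear}(
   \mathrm{LN}(z')))) + \mathrm{LN}(z')$. The second residual adds the
   *normalised* $z'$ — unusual (the standard form adds $z'$ itself) but
   implemented exactly as specified; the tests pin it down by zeroing the
   feed-forward weights and asserting the block returns
   $\mathrm{LN}(z')$ identically. A consequence worth knowing: the residual
   stream is re-normalised at every block, so activations cannot grow with
   depth.
5. **Head.** A trainable length-$n$ token-mixing vector collapses the
   tokens to one $d$-vector, followed by an affine map to the class count
   and softmax.

The `"original"` encoder variant swaps the efficient attention for
single-head scaled-dot-product self-attention with the same combined QKV
and output projections — the minimal standard encoder — and is used for
ablation and the efficiency audit.

GELU is computed with the sigmoid approximation
$x\,\sigma(1.702x)$ (Hendrycks–Gimpel); on this architecture the difference
from the erf form is far below training noise, and it costs one
transcendental per element. No positional encoding is used (none is
specified; token identity is carried by $D$, $U_{copy}$ and the learned
tokens).

### Implementation and its verification

No deep-learning framework is used: the forward pass, backpropagation and
AdamW are implemented in the package, in two interchangeable forms — a
vectorised R reference and a C++ translation (RcppArmadillo) used as the
fast path for the efficient variant. The test suite holds the two to each
other at 1e-10 and holds backpropagation to finite differences at relative
error 1e-3 (observed ~1e-7) for every parameter family, and the vectorised
attention to a deliberately naive loop-based oracle at 1e-5. Weight
initialisation is fan-scaled Gaussian; all randomness flows from explicit
seeds, so training is bit-reproducible.

## Training and evaluation protocol

Training follows the reference protocol: AdamW (learning rate 0.001, the
optimiser's conventional decoupled weight decay 0.01), cross-entropy loss,
batch size 240, fixed epoch budget (100 for DEAP-scale runs, 50 for
DREAMER-scale), no schedule, no early stopping, final-epoch model
evaluated. Experiments are **subject-dependent**: each subject's segments
are split into five shuffled folds; a fresh model is trained per fold; the
report aggregates per-subject fold means as mean ± sd across subjects.
Segment-level folds are the default because published subject-dependent
accuracies are only attainable when segments of one trial may appear on
both sides of the split; `fold_by = "trial"` provides the stricter
trial-held-out protocol for users who want generalisation across stimuli.

Label schemes: binary high/low per dimension (threshold 5 on 1–9 ratings,
3 on 1–5 ratings, `high` at the threshold); fine-grained 8-bin labels on
1–9 ratings with intervals [1,2], (2,3], …, (8,9]; the 5 integer ratings
used directly for 1–5 data; and composite VA (4 classes) / VAD (8 classes)
labels formed as big-endian bit codes of the per-dimension binary labels —
the bit order (V, A, D) is this package's convention, as no ordering is
prescribed anywhere.

All five reported metrics — accuracy, precision, specificity, recall, F1 —
are macro averages of one-vs-rest per-class values computed from the fold's
confusion matrix. Two conventions deserve emphasis. First, "macro
accuracy" is the macro average of per-class one-vs-rest accuracies
$(TP + TN)/N$, which for $k$ balanced classes equals
$1 - 2(1 - p)/k$ for plain accuracy $p$ — systematically higher than $p$
for $k > 2$. Second, for two classes macro specificity is mathematically
identical to macro recall; published tables that show specificity equal to
precision instead are inconsistent with these standard definitions, and the
package implements the standard ones. Per-class metrics with zero
denominators are defined as 0 and the affected classes flagged.

## The synthetic data generator

Real DEAP/DREAMER data are gated downloads, so the package carries a
generator whose recordings exercise every pipeline stage with a known
ground truth. Each trial belongs to a latent class; its signal is broadband
Gaussian noise plus band-limited noise (shaped by the same Butterworth bank
the feature extractor uses) in the class's target band, scaled by
$\sqrt{g - 1}$ so in-band power is $g$ times the broadband floor. The
defaults are the package's study conditions, chosen once: a DEAP-shaped
subject (32 channels, 128 Hz, 40 trials of 60 s), four balanced classes
targeting theta/alpha/beta/gamma with power gain 4 — strong enough that the
class signal is unambiguous, weak enough that a broken pipeline stage
(wrong band edges, wrong normalisation axis, scrambled grid) fails
visibly — and ratings at 1.5/3.5/5.5/8.5 on all three dimensions so the
binary threshold at 5 and the 8-bin labelling both separate classes
cleanly (bins 1, 3, 5, 8 are occupied; a 4-class experiment passes exactly
those bins as its class set).

What the generator does **not** emulate: 1/f spectral shape, artifacts,
inter-channel covariance, non-stationarity, or any genuine link between
oscillatory power and emotion. Passing the end-to-end test demonstrates
that the pipeline's stages compose correctly and that the optimiser can
recover a spectral class structure — it says nothing about accuracy on
real affective EEG.

The end-to-end check trains the default architecture for 10 epochs per
fold — the synthetic classes converge by epoch 6, so 10 adds margin while
keeping the five-fold, two-feature-set run tractable on one CPU — and
requires macro accuracy ≥ 0.90 on held-out folds for both the `both` and
`de_only` feature sets.

## Numerical choices and degenerate inputs

* Butterworth design via `signal::butter(4, band)` (MATLAB/SciPy
  convention); all four band filters are verified stable (pole moduli
  ≤ 0.975) at 128 Hz.
* Layer norm uses $\varepsilon = 10^{-5}$; attention norm guards use
  $10^{-6}$ and clamp, with the gradient of the clamp handled exactly.
* Softmax subtracts the row maximum; cross-entropy guards $\log(p)$ with
  1e-12; prediction ties break to the first class for determinism.
* Zero-variance (constant) segments are an error with full provenance
  (subject, trial, second, channel, band), not a silent NaN.
* A class absent from truth and predictions scores 0 on
  precision/recall/F1 and is flagged in the report.
* FLOP audit counts matrix-multiply MACs of one forward pass at batch 1
  (1 MAC = 1 FLOP by default, switchable to 2); elementwise work is
  excluded by convention. Parameter counts are exact enumerations of the
  initialised parameter tree.

## Known limitations

* With the chosen mixing-matrix shapes the efficient attention carries
  *more* parameters and MACs than the original single-head attention at
  $n = 10$, $d = 81$; the audit reports the signed difference honestly.
  Published totals for either variant are not reproducible from the
  printed description (see the shape ambiguities above).
* DEAP and DREAMER source containers are Python-pickle and MATLAB formats;
  loading them shells out to the system `python` (NumPy/SciPy). The
  package's own interchange bundle, RDS round-trips and the synthetic
  dialect need no Python.
* Cross-subject (leave-subject-out) protocols, artifact handling,
  resampling and hyperparameter search are out of scope.
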