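---
title: "Methods: TSST spectrograms and a compact ConViT for ECG beat classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TSST spectrograms and a compact ConViT for ECG beat classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the model, the modelling assumptions, and the
numerical choices behind **ecgconvit**. The package implements a
classification pipeline for single-lead ECG heartbeats: each beat is a
300-sample window centred on the R peak, labelled with one of the five AAMI
classes (N normal, S supraventricular ectopic, V ventricular ectopic, F
fusion, Q unknown/paced). Beats are converted to time-frequency images with
the time-reassigned synchrosqueezing transform (TSST) and classified by a
convolutional vision transformer (ConViT) trained with a focal loss on a
SMOTE-balanced training pool.

```{r setup}
library(ecgconvit)
```

## 1. Signal model and the synthetic generator

A heartbeat is modelled as a sum of smooth waves (P, Q, R, S, T) on a
300-sample grid at 360 Hz, i.e. a ~0.83 s window with the R peak at sample
150. `generate_beats()` draws beats from class-specific templates built from
Gaussian bumps:

* **N** — full P-QRS-T morphology;
* **S** — narrow QRS like N, but an early, flattened P wave and a shortened
  RR context (the window's neighbouring-beat remnants shift inward);
* **V** — wide, high-amplitude QRS with no preceding P wave and a
  discordant T;
* **F** — an average of the N and V morphologies (fusion of a normal and a
  ventricular activation), intermediate QRS width;
* **Q** — paced-like morphology: a sharp pacing spike followed by a wide
  QRS.

Each draw perturbs amplitudes and widths multiplicatively, jitters the wave
centres (`jitter_sd`, in samples), and adds white Gaussian noise
(`noise_sd`, relative to the unit R amplitude). The generator's purpose is
*desk-scale testability*: every module of the pipeline, including end-to-end
training, can be exercised without external data. Its limits should be kept
in mind:

* morphology variation is parametric and unimodal per class — real
  arrhythmia data has multimodal morphology per AAMI class (each AAMI class
  aggregates several annotation symbols, see `aami_map()`);
* baseline wander, electrode artefacts, and inter-record lead differences
  are not modelled;
* classes are generated balanced by default; the imbalance machinery is
  still exercised because the SMOTE targets oversample the pool (see §4).

Accuracy obtained on synthetic beats therefore does not transfer to any
clinical claim; the generator is a test harness, not a simulator of
pathology.

## 2. Time-frequency analysis

### 2.1 STFT

`stft()` computes a discrete short-time Fourier transform with a sampled
Gaussian window of standard deviation `window_sd` samples, truncated to
`window_len` samples and normalized to unit continuous mass
(`1/(σ√(2π))` scaling):

$$F^g_x(t, \omega_k) = \sum_\tau x(\tau)\, g(t - \tau)\, e^{-i\omega_k \tau},
\qquad \omega_k = \frac{2\pi k}{n_{\mathrm{fft}}}.$$

The implementation windows each frame and runs one FFT per frame
(`stats::mvfft` over the frame matrix); the test suite and the acceptance
script verify it against a direct $O(N^2)$ evaluation of the definition
above. Note the window argument is $g(t-\tau)$, not $g(\tau-t)$ — the
distinction matters for the sign of the group-delay estimator below
(a Gaussian is even, but the companion transform $F^{\tau g}$ is built with
the same convention).

### 2.2 Group delay and time reassignment

The TSST relocates STFT mass along the *time* axis only, to the group
delay

$$\hat t(t,\omega) = \Re\!\left( t - \frac{F^{\tau g}_x(t,\omega)}{F^{g}_x(t,\omega)} \right),$$

where $F^{\tau g}$ is the STFT taken with window $\tau\,g(\tau)$ (applied to
the shifted frame coordinate). Cells with $|F^g| \le \varepsilon$ are masked
and stay in place. `tsst()` then scatter-adds the *complex* STFT
coefficients into the frame nearest $\hat t$ (clipped to the grid):

$$S(s, \omega) = \sum_{t\,:\, \mathrm{round}(\hat t(t,\omega)) = s} F^g_x(t,\omega).$$

Two consequences are used as correctness oracles:

* **Conservation** — for every frequency bin, the complex sum over time is
  unchanged by reassignment (mass is moved, never created or destroyed).
  Tested at relative tolerance 1e-12.
* **Impulse concentration** — for $x = \delta_{n_0}$ the group delay is
  exactly $n_0$ at every unmasked cell, so the TSST concentrates all
  energy in one time row while the plain STFT smears it over the window
  support. This is the reason TSST suits ECG beats: the QRS complex is an
  impulsive, broadband event, and time reassignment sharpens it into a
  vertical ridge.

Numerical choices: hop 1 (every sample is a frame, so a 300-sample beat
gives a 300-frame grid), `n_freq = 160` retained non-negative frequency
bins (FFT length 318), Gaussian `window_sd = 8` samples with support
truncated at ±32. The masking threshold defaults to
`eps = 1e-10 * max|F^g|`, relative rather than absolute so the transform is
amplitude-equivariant.

### 2.3 Rasterization

`rasterize()` turns the complex grid into a `image_size × image_size`
(default 160×160) grayscale image: power $|S|^2$, bilinear resize to the
target raster, optional `log1p` compression (the default mode `"log"`;
`"linear"` is kept for comparison), then min-max normalization to [0, 1].
The log compression is applied *after* the resize of the power grid and
*before* min-max, so the dynamic-range compression acts on physical power
ratios. The image is oriented time × frequency; patches therefore tile 37.5
ms × ~11 Hz cells.

## 3. The classifier

### 3.1 Patch embedding and shape

A 160×160 image is cut into an 8×8 grid of 20×20 patches; each flattened
patch (400 values) is mapped by a learned linear projection to a
`embed_dim = 12` dimensional token. There is no CLS token: the class
representation is the mean over the 64 tokens after the final layer norm
(mean pooling is the documented assumption; the published architecture
feeds "the" token representation to a linear head without specifying
pooling, and mean pooling is the standard choice for ConViT-style models
without a CLS token).

### 3.2 Gated positional self-attention (GPSA)

Each of the first `n_gpsa` blocks uses GPSA. For head $h$ with query/key
projections $Q = Z W_q^T$, $K = Z W_k^T$ and relative-position encodings
$r_{ij} = (\lVert \delta_{ij}\rVert^2,\ \delta^1_{ij},\ \delta^2_{ij})$ of
the token-grid offsets,

$$A_{ij} = \mathrm{normalize}_j\Big[ (1-\sigma(\lambda_h))\,
\mathrm{softmax}_j(Q_i K_j^T) + \sigma(\lambda_h)\,
\mathrm{softmax}_j(v_{pos,h}^T r_{ij}) \Big],$$

i.e. a learned gate $\sigma(\lambda_h)$ mixes a content attention and a
pure positional attention, and rows are renormalized to sum to one (each
summand is already row-stochastic, so the renormalization divides by 1 at
exact arithmetic but keeps the property under the mixing). The content
logits are *unscaled* in GPSA by default (`scale_content_gpsa = FALSE`);
plain SA blocks always use the $1/\sqrt{d_h}$ scaling. The gate saturations
$\lambda \to \pm\infty$ recover pure positional / pure content attention —
an acceptance oracle.

**Convolutional initialization.** Each GPSA head starts as a fixed spatial
shift: $v_{pos,h} = -\alpha_h (1, -2\Delta^1_h, -2\Delta^2_h)$ puts the
positional softmax's mass on the token at offset $\Delta_h$ (exactly, as
$\alpha_h \to \infty$), $W_q = W_k = 0$, and the value projection starts
near identity. With heads on a grid of offsets, the initialized layer is a
convolution with delta filters; `conv_init_head()` and
`conv_head_centers()` expose this and the test suite checks the shift /
3×3-convolution identities at $\alpha = 100$. The package uses
`n_heads = 4` (heads must divide `embed_dim = 12`; the published head
count belongs to a larger embedding), with offsets on the first ring.

### 3.3 Block structure and head

Blocks are pre-LN residual: `X ← X + Attn(LN(X))`, then
`X ← X + FFN(LN(X))` with a two-layer GELU FFN of width
`ffn_mult × embed_dim`, dropout inside the FFN, and an L2 penalty on the
FFN weights (the published regularization lists dropout and weight
penalty). After the final block, layer norm, mean pooling, a linear head,
and softmax give class probabilities.

### 3.4 Training

Hand-written backpropagation through the whole graph (verified by central
finite differences in the test suite) and a hand-written Adam
(β₁ = 0.9, β₂ = 0.999, ε = 1e-8). The published recipe fixes learning rate
1e-4, batch 32, focal γ = 2, and a decay of 0.02 every 10 epochs, but does
not name the optimizer; Adam is this package's documented choice. The decay
is read as multiplicative learning-rate decay — the rate is multiplied by
(1 − 0.02) every `decay_every` epochs (`lr_at_epoch()` exposes the
schedule); `decay_mode = "weight"` implements the alternative reading
(plain weight decay at the same cadence) for comparison.

The loss is the focal loss
$\mathrm{FL}(p_t) = -(1-p_t)^\gamma \log p_t$, which reduces to
cross-entropy at γ = 0 (oracle) and down-weights confidently-correct
samples so gradient mass concentrates on hard minority beats.

## 4. Imbalance handling

`smote()` oversamples a class by interpolation between a beat and one of
its `k_neighbors = 5` nearest same-class neighbours (Euclidean distance in
the 300-sample beat space):
$Z_{new} = Z + r\,(Z_r - Z)$, $r \sim U(0,1)$. Every synthetic point lies
on a segment between two originals — the property the tests check. The
published construction can also be read literally as an elementwise
$Z + r\,|Z - Z_r|$ (which leaves the segment); that reading is available as
`mode = "paper_literal"`, with `"interpolate"` (standard SMOTE) the
default.

In the pipeline, SMOTE serves a second purpose: with
`smote_targets = 2` every class is oversampled to 2× the majority
count, so SMOTE acts as a data augmenter, not just a balancer. At the
training recipe used here (30 epochs, batch 32, lr 1e-4) the binding
constraint is the optimizer's total step count; enlarging the pool
proportionally increases steps per epoch and was worth ≈ +0.2 held-out
accuracy at desk scale. The gain is not a smooth function of the
multiplier: at 1.75× the model settles into a persistent N/S confusion
that the extra steps of the 2× pool escape. SMOTE is applied only to the
train+validation pool, after the test split — the test set never contains
synthetic beats.

## 5. Initialization at a small step budget

With 30 epochs × ~60 batches at lr 1e-4, Adam can move each parameter by at
most ≈ 0.18 in total (every Adam step is bounded by the learning rate, up
to bias-correction transients). The initialization therefore matters far
more than in a 120-epoch regime:

* residual-branch output scales are kept small
  (`init_sd$out = 0.05`, `init_sd$w2 = 0.02` in the pipeline default), so
  the residual stream is dominated by patch content rather than random
  attention/FFN features at the start;
* the GPSA gates start at σ(1) ≈ 0.73 toward the positional
  (convolutional) component;
* a fixed sinusoidal absolute positional embedding
  (`sinusoidal_encoding()`, `pos_embed = "sinusoidal"`) was investigated
  because GPSA carries only relative position and mean pooling is nearly
  blind to absolute time-frequency location: it raises the *linear
  separability* of the initial pooled features markedly, but consistently
  *hurt* end-to-end training at this step budget (the constant positional
  token component inflates variance without carrying image information).
  The default is therefore `pos_embed = "none"` — the literal
  architecture — and the option is retained with this note.

## 6. Pipeline, splits, and problem sizes

`ecg_pipeline()` wires everything together: generate beats → 80:20 split
(test held out) → SMOTE the pool → second 80:20 split (train /
validation) → TSST + rasterize → train → evaluate on the untouched test
set. The double 8:2 split gives 64/16/20% of the original data
(`split_dataset()`, deterministic per seed).

Desk scale defaults: 300 beats per class (1500 total, 300 test), SMOTE
target 2× majority → ~2400-beat pool → ~2000 train / ~500 validation
images, a 4-block model (3 GPSA + 1 SA, ~31k parameters), 30 epochs ≈ 1900
Adam steps. This runs end to end in roughly 12 minutes on one CPU. Evaluation
reports the per-class confusion-derived metrics (accuracy, sensitivity,
specificity, PPV, F1, MCC — `metrics()`), and one-vs-rest ROC/AUC
(`roc_auc()`, verified against **pROC** in the tests).

```{r, eval = FALSE}
res <- ecg_pipeline(n_per_class = 300L, noise_sd = 0.05, seed = 1L)
print(res)
```

## 7. Numerical conventions worth knowing

* All FFT-based transforms use R's unnormalized DFT convention; the STFT
  oracle in the tests re-derives every cell from the definition.
* The group delay uses the real part of the reassignment operator;
  non-finite / masked cells keep their original time index rather than
  being dropped, so conservation holds exactly.
* `rasterize()` order of operations: power → resize → log1p → min-max.
* Focal-loss gradients are computed in closed form w.r.t. logits
  (`(w\,\partial_p \mathrm{FL}\, p_t)(\mathbf{1}_y - p)`), not by autodiff.
* Dropout uses inverted scaling (`mask / (1 - p)`), so evaluation needs no
  rescaling.
* All randomized components (generator, SMOTE, splits, training) take
  explicit seeds and save/restore the global RNG state.
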