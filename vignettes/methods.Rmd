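---
title: "Pseudo-healthy synthesis for unsupervised BMEL segmentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo-healthy synthesis for unsupervised BMEL segmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmelseg)
```

## The model

Bone marrow edema-like lesions (BMEL) are hyperintense on fluid-sensitive
target sequences (TSE-like) and nearly isointense on the conditioning
sequence (DESS-like). `bmelseg` exploits this asymmetry: a conditional
generative model $G$ is trained on pairs $\{x, c\}$ drawn **only from
healthy studies**, where $x$ is a target-sequence slice and $c$ a
conditioning image built by one of three tasks (sequence translation, bone
inpainting, bone translation). At inference, $\hat{x} = G(c)$ is a
pseudo-healthy estimate of the slice, and the anomaly map is the positive
part of the difference, $a = \max(x - \hat{x}, 0)$.

The assumptions this rests on are explicit:

1. the two sequences are co-registered (real inputs are assumed registered
   upstream; the phantom generates them co-registered);
2. lesions occur only inside bone marrow, so a bone mask removes all
   out-of-bone anomalies without touching any lesion;
3. lesions are *hyper*intense in the target sequence, so negative
   differences carry no lesion evidence — that is why the anomaly map is
   the signed difference's positive part rather than its absolute value
   (an absolute value would convert synthesis artifacts into false
   positives);
4. the conditioning image carries no (or weak) lesion signal, so the
   generator cannot simply copy the lesion through.

Binarization uses a threshold chosen by three-fold cross-validation over
the *test* volumes: for each fold the other two folds are swept over a
candidate grid, the mean Dice (volumes averaged per rater, then raters
averaged) selects $\tau^*$, and the held-out fold is scored at $\tau^*$.
The final score is the arithmetic mean of the three fold scores. Folds are
assigned by volume, never by slice, to avoid leakage between a volume's
slices.

## Evaluation metrics

All scores derive from the smoothed Dice,
$\mathrm{DICE} = (2\,TP + \epsilon)/(2\,TP + \epsilon + FP + FN)$,
with $\epsilon \ge 0$ exposed everywhere (default $10^{-6}$; the value is
a reporting choice, not estimated from data). Two aggregations are
provided:

* **3D**: one score over all voxels of a volume. Pooled counts make it
  invariant to appending slices that are empty in both masks.
* **2D**: the slice-wise mean. With $\epsilon > 0$ a slice empty in both
  masks scores exactly $\epsilon/\epsilon = 1$, which pulls the all-slices
  mean towards 1; the `lesion_slices` scope drops slices with empty truth
  instead. With $\epsilon = 0$ such slices are undefined and are skipped
  (`policy = "skip"`, the default) or counted as 1
  (`policy = "include_as_one"`).

`evaluate_model()` implements the volumes-then-raters averaging order;
`reliability_report()` compares annotation sets pairwise and classifies
pairs as intra-rater (same rater, different repeat) or inter-rater. The
intra-rater definition is the standard one — a rater against their own
repeat — even though cross-comparisons to the other rater are also
conceivable; the pairwise `detail = TRUE` table exposes every comparison
so either reading can be reconstructed.

## The phantom

No public dataset with this paired-sequence structure exists, so the
package generates one. Each study contains:

* **geometry** — two elliptical bone components per slice (femur/tibia
  analogues) with smooth per-slice center drift and a through-slice taper,
  confined to the central ~80% of the field of view; a soft-tissue
  ellipse surrounds them. The in-plane bone area fraction is drawn from
  `bone_fraction_range` (default 0.12–0.22).
* **intensities** — piecewise tissue levels, lightly smoothed: in the
  target sequence marrow is dark (fat-suppressed appearance) and soft
  tissue mid-intensity; in the conditioning sequence marrow is bright.
  Additive Gaussian noise (`noise_sd`) and a per-volume multiplicative
  scale drawn from `intensity_scale_range` (default 0.8–1.6, emulating
  mixed acquisition bit depths) complete the raw volumes.
* **lesions** — blurred ellipsoid indicators, normalized to unit maximum;
  ground truth is the field thresholded at half maximum, intersected with
  bone. In-plane semi-axes default to 5–9 voxels with boundary blur
  $\sigma = 0.8$ voxels. These two defaults were chosen together so that
  the lesion plateau dominates its diffuse rim: the mean in-lesion target
  offset then tracks the nominal `target_lesion_contrast` (default 0.5)
  while the boundary still spans ~2 voxels of partial intensity. The
  conditioning-sequence offset (`conditioning_lesion_contrast`, default
  0.05) is an order of magnitude weaker, encoding the low lesion contrast
  of the conditioning sequence.
* **pseudo-healthy reference** — `healthy_target` is the target volume
  with the lesion term removed but the *same* noise realization and, after
  preprocessing, the *same* intensity transform as the target. This makes
  `healthy_target` equal to `target` exactly outside the lesion support at
  every pipeline stage, which is what lets the oracle backend isolate the
  segmentation framework from generative-model quality.
* **raters** — simulated annotators perturb the continuous lesion fields
  the way a semi-automatic workflow does: a per-lesion miss probability
  (presence disagreement), a shifted field threshold with an optional
  persistent per-rater bias (threshold disagreement — giving raters
  distinct biases makes repeats agree more than cross-rater pairs), and
  an in-plane dilation/erosion (extent disagreement). All-zero jitter
  reproduces the ground truth exactly, and masks are always clipped to
  bone.

What the phantom does **not** emulate: real anatomy (cartilage, menisci,
cortical bone), MRI physics (bias fields, partial volume, ghosting),
registration error, or the size/count distribution of clinical lesions —
the generator's lesion statistics are free parameters, not calibrated to
any cohort. Passing tests therefore demonstrate that the framework's
machinery is correct and that the method recovers lesions under its own
assumptions; they say nothing quantitative about clinical performance.

## Preprocessing

Per volume: max normalization, quantile clipping, affine rescaling onto
$[-1, 1]$ (matching a final tanh activation), and an optional center crop.
Numerical choices:

* **Quantile convention**: inverse-ECDF (type 1). With interpolated
  quantiles, re-clipping an already clipped volume moves the bound by a
  fraction of an order-statistic gap, so the pipeline would only be
  approximately idempotent; with type-1 quantiles the clip bound of a
  clipped volume is the bound itself and the pipeline is exactly
  idempotent on its own output. Quantiles are computed per whole volume
  (all slices jointly), not per slice.
* **Rescaling** is anchored at the low endpoint and clamped, so the output
  attains $-1$ and $1$ exactly; a constant volume raises an explicit
  degenerate-range error.
* **Cropping** keeps the slice count, centers the window, and takes the
  floor of the offset on odd margins (a 320×320 slice cropped to 256×256
  keeps 32-voxel margins on each side). The phantom's bone placement
  guarantees moderate crops never remove bone.
* The initial scaling step is per-volume max normalization; since clipping
  quantiles and the affine rescale are scale-invariant, its only role is
  to put all volumes on a common footing before any further arithmetic.

## Generative backends

There is no deep-learning runtime among the package's dependencies, and
the conditional generators are the heart of the method, so the few layer
types needed (same-padded 3×3 convolutions via im2col gathers and BLAS
matrix products, stride-2 downsampling, nearest-neighbour upsampling with
skip concatenation, leaky ReLU/tanh/sigmoid, Adam) are implemented
directly with analytic backpropagation, verified against finite
differences in the test suite.

**cGAN** (Pix2Pix-style): a small U-Net generator with a tanh head and a
patch-based discriminator with three convolutional layers on the
concatenated $(c, x)$ channels. The generator objective is the
non-saturating adversarial term plus $\lambda_{L1}$ times the mean
absolute error; $\lambda_{L1}$ defaults to 100 (the Pix2Pix convention —
the reference description specifies the loss family but not the weight).
The latent noise is realised implicitly by bottleneck dropout rather than
an explicit noise vector, again the Pix2Pix convention. The discriminator
is implemented as a PatchGAN; a U-Net "truncated at the bottleneck" with a
binary head is an equivalent intent and the patch form is the one pinned
down by the three-conv-layer description. Desk-scale defaults (width 4,
batch 4, learning rate $2\times10^{-3}$, Gaussian init) train usefully in
seconds on 64×64 slices; `cgan_config_paper_scale()` records the
full-scale reference settings (batch 36, learning rate $5\times10^{-4}$,
zeros init) without pretending they are runnable at desk scale.

**Conditional diffusion**: the noise model $\epsilon_\theta$ takes the
noisy target and the *undisturbed* conditioning image concatenated
channelwise at every step, plus a sinusoidal timestep embedding injected
as a per-channel bias. Training minimizes
$\|\epsilon - \epsilon_\theta(x_t, c, t)\|_2^2$; no reconstruction loss is
added. The quadratic schedule is the square of linearly spaced square
roots between $\beta_1$ and $\beta_T$ (the convention that makes
"quadratic" precise), with $T = 100$ at desk scale and 1000 in the
recorded full-scale preset. Sampling is standard ancestral DDPM sampling,
seeded and deterministic, with the final step noise-free and the output
clamped to $[-1, 1]$.

**Oracle**: returns the phantom's pseudo-healthy slice exactly — the
perfect generator. Any backend satisfying the two-function contract
(`backend_train()`, `backend_synthesize()`) can be dropped in; the
framework downstream is backend-agnostic, which the contract test
exercises with all three.

## Thresholding details

The candidate grid defaults to 51 evenly spaced values over the pooled
anomaly-value range of the fold's training volumes (the grid is not
prescribed by the reference description; an even sweep over the observed
range is the neutral choice). Ties in the Dice curve break towards the
smallest threshold — the more sensitive segmentation. Anomaly maps are
compared under one shared threshold without per-volume renormalization:
after preprocessing, a volume's multiplicative scale cancels out of the
anomaly amplitudes, so a shared threshold is meaningful; a per-volume
max-normalization could be layered on top by callers that need it.

## Problem sizes

The test suite and examples run on 16×64×64 phantom grids (the
framework-level checks) and 8×32×32 or 8×16×16 grids (training smoke
tests), with 1–6 training studies, 3–6 test volumes, 15–200 optimizer
steps, and diffusion horizons of 10–100 steps. These sizes were chosen so
the full suite runs on one CPU core in a few minutes while every
qualitative behaviour of interest — training gains, threshold recovery,
metric protocols — is still observable.

## Known limitations

* Desk-scale generative models are small; they demonstrate the training
  and synthesis mechanics, not clinical image quality.
* The phantom's lesion statistics are uncalibrated free parameters.
* No connected-component or morphological cleanup is applied to the
  binarized maps, and no surface-distance metrics (Hausdorff, ASSD) are
  reported.
* Real inputs must arrive co-registered with bone masks supplied; neither
  registration nor bone segmentation is in scope.
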