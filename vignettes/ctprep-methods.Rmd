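---
title: "Artifact-free learnable preprocessing for non-contrast brain CT: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Artifact-free learnable preprocessing for non-contrast brain CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctprep)
```

## The problem and the model

Ultra-early ischemic lesions on non-contrast CT are faint: the core and the
surrounding penumbra differ from healthy parenchyma by a few Hounsfield
units, and ordinary acquisition artifacts (noise, mild blur, brightness and
contrast drift between scanners) can swamp them. Generative
restoration networks can clean such images, but they synthesize pixels and
may hallucinate structure -- unacceptable when the downstream task is lesion
delineation.

`ctprep` implements the alternative: a *parameter-prediction* preprocessor.
A compact convolutional network $h$ looks at a downscaled copy
$I_{so}$ of the windowed slice and predicts a handful of scalar parameters

$$p_{1..n} = h(I_{so}),$$

which drive a bank of fixed, differentiable image filters applied to the
full-resolution image $I_o$. The enhanced image is

$$I_e = \operatorname{clip}\Big(I_o + \sum_i w_i\,\Delta_i(I_o, p_i),\ 0,\ 1\Big),$$

where $\Delta_i(I_o,p_i) = F_i(I_o,p_i) - I_o$ is the *residual* of filter
$F_i$ and the gains $w_i$ are fixed at 1. Because the network only chooses
filter strengths, never pixel values, the pipeline is structurally incapable
of inventing anatomy. The formal anchor of that claim is the neutrality
property: with neutral parameters (or zero gains) `enhance()` is the
bit-exact identity, and constant inputs always map to constant outputs.

### Why residuals

A literal sum of full filter *outputs* added to $I_o$ would roughly
$(n{+}1)$-fold the signal before clipping and could not be neutral at any
parameter setting. Summing residuals instead makes every filter's neutral
point (brightness 0, contrast 0, blur $\sigma\to 0$) contribute exactly
nothing, which matches the design goal that the module "does not directly
modify the image" unless it has a reason to. The bare summation form is
retained in `applyContrast(..., literal = TRUE)` for comparison; its
identity-at-neutral property fails by construction.

## The filter bank

All filters act channel-wise on a `[0,1]`-windowed image (brain window
WW = 80 HU, WL = 40 HU; the single channel is triplicated purely as a
tensor-shape convention) and use reflect padding, so unit-sum kernels
preserve constants.

* **Brightness** (1 parameter, tanh range): $I + b$. The formula is an
  additive offset -- the simplest one-parameter global adjuster; clipping is
  deferred to the pipeline so the residual is exactly $b$.
* **Contrast** (1 parameter): scale $s(r) = 1/(1-r)$ for $r>0$, else
  $(1-r)$, applied about mid-gray. The default mode restores the $+0.5$
  offset so $r=0$ is the identity; the published bare form is available as
  `literal` mode.
* **Sharpness** (1 parameter per channel): convolution with
  $(K + M q)/\nu(q)$ where $K$ is the fixed 5×5 matrix with a $-476$
  centre (entries sum to $-256$), $M$ the 0.8/0.9/1.0 ring-structured map
  matrix (sum 21), and $\nu(q) = -256 + 21q$, which never vanishes on
  $q\in[-1,1]$ so the kernel always sums to one.
* **Gaussian blur** (1 parameter): separable sampled Gaussian, $k = 2$
  (5×5) by default; the predicted logit is mapped by a sigmoid to
  $(0, \sigma_{\max}]$ with $\sigma_{\max} = 2$ px so $\sigma\to 0$
  recovers the identity. Off in the default configuration.
* **Median** (non-trainable): exact 3×3 median via a vectorised min/max
  selection network. It has no useful gradient and is excluded from
  training; off by default.
* **Pretrained-kernel combination ("CB")**: $\sum_i \alpha_i (K_i^{pretr}
  \circledast I)$ with $\alpha = \operatorname{softmax}(\text{logits})$, so
  the weights always sum to one. The three kernels (5×5, 7×7, 11×11) are
  frozen; only the logits are learned.

The default filter set is the combination that the ablation studies of the
underlying method found best: CB + brightness + sharpen + contrast.

### Kernel extraction

The bank kernels come from the skip paths of a pretrained symmetric
encoder--decoder ("skip-convolution U-Net", `buildSkipUNet()`): each skip
path passes through one linear convolution of fixed size, shallowest level
5×5, then 7×7, then 11×11 (the source never fixes this mapping; we assign
increasing receptive field to increasing depth). A multi-channel weight
tensor must be reduced to one spatial kernel; the default rule is the
channel mean, with `first-channel` and `frobenius-top-1` selectable, and the
rule is recorded in the bank manifest. Each extracted kernel then receives a
*unit-DC centre-tap correction* (the centre weight is shifted so the kernel
sums to exactly one). This keeps the combination block constant-preserving
-- the property the artifact-safety protocol relies on -- while leaving the
learned spatial structure untouched; for an untrained network it degrades
gracefully to a near-delta kernel. Pretraining defaults to segmentation
with the Dice loss on synthetic phantoms (mirroring how the source models
were ranked); a reconstruction mode (L1) is provided since the same
architectures double as autoencoders, and when samples carry degraded twins
it becomes a *denoising* autoencoder (degraded in, clean out). The training
harness and the reproduction script use the denoising mode to build their
bank: channel-mean extraction from a briefly-trained segmentation network
yields near-delta kernels with no enhancement capability, whereas denoising
pretraining imprints genuine smoothing/enhancement structure on the skip
convolutions -- which is the point of the block.

## The parameter generator

Three stride-2 conv/BatchNorm/ReLU blocks (widths 32/64/128 -- the widths
are chosen to reach a 128-channel 16×16 feature map from a 3×128×128
input) followed by two fully connected layers (hidden width 512) and
per-filter range activations: sigmoid for unit-range parameters, tanh for
signed ones, identity for the unconstrained combination logits. Two
variants exist because the published description is self-contradictory: a
flatten of the 16×16×128 map into the first FC layer alone costs over 16 M
weights, irreconcilable with the stated 45 K total. The default `"lite"`
variant replaces the flatten with global average pooling; at ~164 K
parameters it is still two orders of magnitude below the flatten variant,
though even this cannot reach 45 K with the stated widths -- the conv trunk
alone is ~93 K. `"paper-faithful"` keeps the flatten for fidelity
experiments. We do not guess which architecture produced the published
numbers.

The output layer is zero-initialised, so an untrained generator predicts
neutral brightness/contrast/sharpness and equal combination weights: the
pipeline starts as close to the identity as the filter set allows. This is
the standard initialisation for parameter-prediction enhancement networks
-- without it, early training must first undo large random distortions.

One shared generator produces all heads (the design replaces per-filter
generator copies with a single generator).

## Training

* **Preprocessor pretraining** minimises
  $w_{SSIM}\,(1 - \mathrm{SSIM}(I_e, I_{gt})) + w_{L1}\,\overline{|I_e - I_{gt}|}$
  (equal weights; the L1 term is a mean so weights are resolution
  independent) on pairs manufactured by the soft-degradation generator.
  Optimiser: AdamW, decoupled weight decay 0.05, betas (0.9, 0.99), initial
  learning rate $10^{-4}$ with cosine decay to zero; joint fine-tuning
  starts at $10^{-6}$ (from-scratch toy runs use a larger rate, see below).
  The best checkpoint is the one with the lowest validation loss.
* **Gradients.** All residuals of the default filter set are cheap
  elementwise functions of a few convolutions of the *input* image, which
  are precomputed once per sample. The loss gradient with respect to the
  ~8 filter parameters is taken by central finite differences
  ($\varepsilon = 10^{-4}$) on that surface. The contrast parameter needs
  care: $s(r)$ is piecewise with a kink at $r = 0$ where both branches
  increase contrast, so a symmetric probe cancels to zero there; near the
  kink the positive branch is probed one-sided. Gradients inside the
  generator and the U-Nets are exact analytic backprop (verified against
  numerical differentiation to $10^{-8}$ relative error during
  development). Joint
  training chains the segmenter's input gradient with analytic
  $\partial I_e/\partial p_j$ images instead, since a finite-difference
  probe would need a full segmenter forward per parameter.
* **Joint fine-tuning** runs the enhanced image through a segmenter under
  the soft Dice loss (smoothing $\varepsilon = 1$; background excluded,
  since only core and penumbra carry supervision) and updates both
  networks. The bundled segmenter is a deliberately small 3-level U-Net
  (~15 K parameters); large clinical backbones are out of scope. Because
  this toy segmenter is trained from scratch rather than fine-tuned, the
  harness's scaled experiments use a joint learning rate of $10^{-3}$ -- at
  the published $10^{-6}$, designed for already-pretrained networks, a
  few-epoch toy run would not move at all.
* **Streaming batch normalisation.** The reference loops process one image
  at a time. Normalising each image by its own spatial statistics (instance
  norm) would erase exactly the global brightness and contrast information
  the parameter heads must read -- with it, the brightness/contrast heads
  provably cannot become input-dependent. The BatchNorm layers therefore
  normalise with running (EMA) dataset statistics during training and
  inference alike, updating them from the per-image spatial moments; the
  statistics are treated as constants in the backward pass. This is the
  closest per-sample analogue of large-batch BatchNorm, which likewise
  preserves each image's deviation from the batch mean.

## The synthetic-data generator

Phantoms (`generatePhantom()`) are procedural 512×512 slices: an
elliptical skull ring, smooth mildly-textured parenchyma with ventricles,
and (with probability 0.85) a hypodense lesion -- a graded penumbra blob
containing a darker core, the two masks disjoint by construction and
confined to the brain. They emulate the *statistical* structure the method
assumes (smooth tissue, bright ring, subtle graded hypodensity); they carry
no anatomical realism, no scanner physics (beam hardening, streaks), and no
inter-slice anatomy. Passing tests therefore demonstrate the mechanism --
restoration gain, artifact safety, the direction of the joint-training
benefit -- not clinical performance.

Degraded twins (`softAugment()`) draw a random subset of: Gaussian blur
$\sigma\in[0,0.20]$ px, additive Gaussian noise with variance in $[10,50]$
on the 8-bit scale (the conventional augmentation-library parameterisation;
intensity-domain sd $=\sqrt{var}/255$), centre crop to $[400,512]$ of a
512 px frame (applied fractionally at other sizes) with resize back,
rotation $\pm10^\circ$, and brightness/contrast adjustment within a
$\pm20\%$ limit; each transform fires with probability 0.5. The
brightness/contrast limits follow the convention of the mainstream
augmentation libraries: brightness adds $\delta$ times the full intensity
range ($\delta \in [-0.2, 0.2]$), contrast rescales about mid-gray by
$1+\delta$. The percentage phrasing admits a purely multiplicative reading
of brightness as well; the additive-by-range convention is the one the
dominant libraries implement and makes brightness errors a first-class
degradation rather than a second contrast term. Geometric transforms are applied to
the target and masks too (a restoration target must stay aligned with its
input); masks use nearest-neighbour resampling so one-hot structure
survives, and a geometric draw that destroys more than 25% of the core is
redrawn with the count logged. The alternative pairing -- untransformed
clean target -- is exposed via `geometryToTarget = FALSE`.

## Metrics

Slice-wise Dice and Jaccard follow the set definitions with the convention
that two empty masks score 1 (a lesion-free slice predicted clean is
correct). Volumetric Dice/IoU sum intersections and sizes across slices
(equivalently, voxel-wise statistics); overlap metrics are spacing-free.
Distance metrics (Hausdorff, HD95 symmetrised by the maximum of the two
directed percentiles, ASSD) operate on *boundary* voxels -- the standard
choice where the source is ambiguous -- scaled by the physical spacing
(default 0.5 × 0.5 × 5 mm), and raise a defined error when a surface is
empty; the aggregate report skips those cases and records the counts. SSIM
uses the standard 11×11 Gaussian window ($\sigma = 1.5$) and stabilisers
$C_1 = 0.01^2$, $C_2 = 0.03^2$ on the unit range. The trimap F-measure
restricts the F-score to pixels within a 5 px Euclidean band of the true
boundary.

## Numerical choices

* Reflect (symmetric) padding everywhere; the boundary convention is
  load-bearing only through the constant-preservation property.
* Bilinear resampling uses half-pixel-centred coordinates; window clipping
  before or after normalisation is mathematically identical here.
* Coordinates are row-major, origin top-left; slices are ordered by
  ascending index with filename tie-break.
* The 3×3 median is an exact order statistic (min/max selection network);
  no differentiable relaxation is needed since the filter is non-trainable.
* Softmax weights are computed with max-subtraction, exact to $10^{-9}$
  summation even at logits of $\pm 50$.
* Sharpness applies per-channel parameters even though the three channels
  are identical copies; with triplicated inputs the three $q$ values are
  expected to converge to a common value.

## Desk-scale problem sizes

The package's own experiments (tests and the reproduction script) use these
sizes, chosen so the full suite runs on a single CPU core:
20 phantoms at 256 px and 3 epochs for skip-U-Net pretraining; 240 paired
512 px phantoms (200 train / 40 validation), 5 epochs, at the 128 px
generator resolution for preprocessor pretraining (seed 1234); 50 uniform
phantoms at 128 px for the safety protocol; and, for the paired-seed
joint-training comparison, 48 training / 16 held-out phantoms at 64 px, 6
epochs, 10 seeds, with the pretrained preprocessor frozen in the
"with-preprocessor" arm -- co-adapting the preprocessor inside the
segmenter was reported ineffective in the source method, and freezing also
keeps the comparison a clean test of the enhanced input rather than of
extra trainable capacity. The directional claims these runs support are
unchanged by the scale; the absolute metric values are not comparable to
clinical-scale results.

## What the safety protocol does and does not show here

The artifact-safety protocol separates two claims. The *structural* claim
-- the pipeline cannot imprint features where none exist -- holds exactly:
uniform phantoms come out with standard deviation at floating-point zero,
and the safety flags stay clear for any generator, trained or random. The
*photometric* claim -- that the global corrections also stay small on
structureless inputs -- is a property of the trained weights, not of the
architecture. A brightness head trained on procedural phantoms, whose
per-slice mean intensities cluster tightly, learns a mean-reverting
response and extrapolates it to constant images far outside that manifold;
at desk scale the mean uniform-phantom SSIM can therefore fall short of
the in-distribution response (SSIM against enhanced clean slices is
noticeably higher). Training corpora with broader per-slice intensity
statistics, such as real windowed CT, can be expected to temper the
learned mean-reversion; the phantom generator is deliberately not adjusted
to engineer this outcome.

## Known limitations

* Volume I/O covers NIfTI and PNG; DICOM series are not read (no DICOM
  reader is available to the package), so DICOM data should be converted
  to NIfTI upstream.
* The phantom generator does not emulate scanner physics; distribution-
  shift statistics measured on clinical cohorts cannot be reproduced here.
* The registry implements the winning filter combination plus blur and
  median; the non-winning exotic filters (Laplacian, exposure, bilateral,
  "universal kernel") are not included, though the registry is extensible.
* Training is pure R on one core: suitable for the desk-scale experiments
  above, not for 512 px clinical training runs.
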