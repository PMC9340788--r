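---
title: "Disentangled representation fusion of multi-modal brain images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disentangled representation fusion of multi-modal brain images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(defusion)
```

## The model

Co-registered brain images from two modalities (say MRI and CT) carry two
kinds of information: *redundant* structure — the anatomy both modalities
see, outlines, shapes — and *complementary* content unique to each modality
— soft-tissue texture in MRI, dense bone in CT, metabolic signal in PET.
`defusion` fuses such pairs through a three-branch convolutional
auto-encoder that represents the two kinds separately:

* two complementary encoders `En_C1`, `En_C2`, one per modality;
* one **shared** redundant encoder `En_R` applied to both images;
* one **shared** decoder `De_S`.

Every branch is three 3×3 stride-1 convolution blocks (channel path
1 → 64 → 64 → 128 for the encoders, mirrored for the decoder). Encoder
blocks end in ReLU, with batch normalization on all but the first block;
the decoder ends in a sigmoid, so decoded images always lie in [0, 1].
Convolutions use padding 1: feature maps keep the image's spatial size,
which is what allows complementary and redundant features to be added
position-by-position and decoded back at full resolution, and lets the
fully convolutional network fuse whole images of any size without tiling.

For an input pair $(I_1, I_2)$ the encoders produce $C_* = En_{C*}(I_*)$
and $R_* = En_R(I_*)$, and the decoder must reproduce each image from its
own features, $\tilde I_* = De_S(C_* + R_*)$, and from *swapped* redundant
features, $\tilde I_{12} = De_S(C_1 + R_2)$, $\tilde I_{21} = De_S(C_2 +
R_1)$. The cross-reconstructions are compared against the image that
supplied the *complementary* features — that is the training signal that
makes $C$ determine an image's appearance while $R$ carries only what the
modalities share.

## The training objective

The total loss is

$$L = L_{rec} + \lambda_r L_r + \lambda_c L_c, \qquad
  L_{rec} = \lambda_{SSIM} L_{SSIM} + L_{MSE},$$

with defaults $\lambda_{SSIM} = 1000$, $\lambda_r = \lambda_c = 10$.

**Reconstruction.** $L_{MSE}$ and $L_{SSIM}$ sum the per-pixel mean squared
error and $1 - \mathrm{SSIM}$ over the four reconstruction pairs. We use
per-pixel *means* rather than sums so that the $\lambda$ balance does not
depend on image size (training runs on crops, inference on whole images).
SSIM uses the standard 11×11 Gaussian window, $\sigma = 1.5$, data range 1,
computed over valid windows; its analytic gradient is implemented alongside
and verified against finite differences in the test suite.

**Redundant consistency.** $L_r$ is the mean absolute difference between
the *decoded* redundant features, $|De_S(R_1) - De_S(R_2)|$. Constraining
decodings rather than the features themselves tolerates the unequal amount
of information the two modalities carry.

**Complementary group lasso.** The channel vector at each position $(x,y)$
of a complementary feature map is one group, and

$$L_c = \sum_{x,y}
  \big(\omega_1 \|C_1(x,y)\|_2 + \omega_2 \|C_2(x,y)\|_2\big).$$

The weights decide which modality's feature survives at each position.
Local importance $\phi_*$ is the channel-L1 norm averaged over a
$(2r+1)^2$ block ($r = 1$ by default, fixed denominator with zero padding,
so border positions are attenuated). The weights are a sigmoid of the
importance difference,

$$\omega_1 = \frac{1}{1 + e^{k(\phi_1 - \phi_2)}}, \qquad
  \omega_2 = 1 - \omega_1,$$

whose steepness $k = 1/\max(r_{\cos}^2, \varepsilon)$ grows as the cosine
similarity $r_{\cos}$ between $C_1(x,y)$ and $C_2(x,y)$ falls: dissimilar
(complementary) features get a nearly hard choose-max assignment, similar
(redundant) features are penalized evenly and thereby pushed out of the
complementary maps into the redundant ones.

Four numerical decisions matter here:

* **Sum, not mean.** $L_c$ accumulates over positions
  (`lcNormalization = "sum"`, the default). This matters: at
  $\lambda_c = 10$ the summed penalty exerts a per-position pull of order
  $\lambda_c \omega$ — comparable to the reconstruction gradients — which
  drives the locally unimportant group to *exact* zero, the filtering
  behaviour the penalty exists for. Normalizing by $HW$ (available as
  `"mean"`) weakens the pull by the pixel count; in our desk-scale
  ablations it then only shrinks norms uniformly, no position is ever
  filtered out, and the complementary maps of the two modalities stay as
  correlated as without the penalty.

* **Sign of the sigmoid.** The package implements the semantics "the more
  important feature receives the *smaller* penalty": $\phi_1 \gg \phi_2$
  drives $\omega_1 \to 0$, sparing $C_1$. A `flipSign` switch in
  `lossConfig()` flips the exponent for the opposite assignment.
* **Steepness floor.** At $r_{\cos} = 0$ the steepness is unbounded; we
  floor $r_{\cos}^2$ at `similarityEpsilon` ($10^{-4}$, so $k \le 10^4$),
  which keeps gradients finite while already being an effectively hard
  assignment. A zero-norm channel vector is given similarity 0 — an
  all-zero feature carries no redundancy.
* **Weight detachment.** By default ($\texttt{detachWeights} = TRUE$) the
  $\omega$ maps are recomputed every step but treated as constants in
  backpropagation: they act as adaptive penalty coefficients, and
  differentiating through them would make the objective self-referential.
  The exact non-detached gradient (chain rule through $\omega$, $\phi$ and
  $k$) is also implemented and selectable; both modes are verified against
  finite differences.

## Fusion strategies

At inference the redundant features are averaged, $R_f = (R_1 + R_2)/2$
(they live in one space — the encoder is shared), while the complementary
features are combined by one of three strategies before decoding
$I_f = De_S(C_f + R_f)$:

* `add` — $C_f = C_1 + C_2$: keeps everything, best texture retention;
* `max` — elementwise maximum. Encoder features are non-negative (final
  ReLU), so value-max equals magnitude-max; the elementwise reading
  follows the "preserve the higher magnitude" intent. A per-position
  vector-norm selection would be a possible variant;
* `l1` — activity-weighted average with $\mu_1 = A_1/(A_1 + A_2)$, where
  $A_*$ is the per-position channel-L1 activity; positions where both
  activities vanish fall back to $\mu_1 = \mu_2 = 1/2$ (both features are
  zero there, so any convex weight gives the same result and 0.5 avoids
  0/0).

Pseudo-color modalities (PET-like) are handled in full-range BT.601 YCbCr
(the JPEG convention): the luminance channel is fused through the network
and the chrominance of the color source is carried over unchanged — a
deliberate limitation; chrominance is not itself fused.

## Training protocol

`trainFusionModel()` follows the reference training protocol by default: random
120×120 crops with random flips and 90°-multiple rotations (the same
window and transform applied to both images of a pair, preserving
co-registration; 90° multiples avoid interpolation artifacts), batch 8,
Adam at learning rate $10^{-4}$. Only the learning rate is stated in the
protocol; Adam with default moments is the de-facto optimizer for this
family of fusion auto-encoders. Training length is a fixed iteration
count. Batch normalization uses batch statistics during training and
running statistics for all inference. k-fold verification is available
via `runFoldExperiment()` (standard k-fold cross-validation over pairs,
folds disjoint and covering every pair once).

With `useLc = FALSE` the group-lasso term is dropped from the objective —
the ablated model — but still logged, so penalty ablations run at matched
seeds and iteration counts.

## The synthetic data generator

Real paired brain atlases cannot ship with the package, so
`makePair()`/`makeDataset()` generate pairs with a *known* decomposition:
a smooth elliptical "brain slice" $S$ with internal substructures and a
darker ventricle-like cavity (the shared anatomy), band-limited stripe
texture $U_1$ (MRI-like soft-tissue detail) and bright convex blobs $U_2$
(CT-like dense structure), mixed as $I_* = \mathrm{clip}(a_* S + b_* U_*)$
with recorded coefficients (defaults $a_* = 0.6$, $b_* = 0.4$). $U_1$ and
$U_2$ occupy opposite sides of a random dividing direction, and the
realized support overlap is recorded. An optional RGB companion maps
$I_2$ through a fixed black–purple–red–yellow–white colormap, emulating a
pseudo-colored PET display. Everything is bit-reproducible from (seed,
params).

What the generator does *not* emulate: anatomical realism, modality-
specific noise statistics, partial-volume effects, or mis-registration.
Passing disentanglement tests on these images therefore shows that the
architecture and penalty separate shared from unique content under
controlled conditions — not that the trained desk-scale model transfers
to clinical data; training on a real atlas uses exactly the same code
path at full scale.

## Desk-scale study conditions

The package's own experiments (test suite and `scripts/acceptance.R`) run
on one CPU, so they use reduced problem sizes chosen once:

* **smoke run** — 8-channel networks, six 32×32 pairs, batch 8, 200
  iterations, learning rate $10^{-3}$; checks that the total loss falls
  below half its starting level.
* **disentanglement ablation** — 8-channel networks, twelve 64×64 pairs
  (8 training, 4 held out), batch 2, 2×2000 iterations (with and without
  $L_c$), learning rate $10^{-3}$ (`disentanglementExperiment()`). The
  raised learning rate and small batch are the desk-scale choice for tiny
  networks and short schedules; package defaults keep the reference
  protocol.

On the held-out pairs the ablation measures (a) the redundant consistency
$|De_S(R_1) - De_S(R_2)|$ before vs after training — the "before" model is
the same initialization with batch-norm running statistics calibrated by
forward passes (`calibrateBatchNorm()`); fresh running statistics were
never produced by data and would make the untrained decoder output
near-constant images — (b) the mean cosine
similarity between $C_1$ and $C_2$ with vs without the penalty, and
(c) cross-reconstruction fidelity $\mathrm{SSIM}(I_1, \tilde I_{12})$
against the inter-modality baseline $\mathrm{SSIM}(I_1, I_2)$. These are
the quantities the test suite asserts; the vignette states no numbers the
code does not compute there.

## Quality metrics

`evaluatePair()` computes seven standard fusion metrics from the source
pair and the fused image, on the 8-bit [0, 255] intensity scale customary
in this literature: SD (contrast), SF (spatial frequency),
$Q_{MI}$ (Hossny-normalized mutual information transfer, 256-bin joint
histograms, no smoothing), $Q_{NCIE}$ (nonlinear correlation information
entropy from the rank-grouped 256×256 joint histograms; constant images
get off-diagonal coefficients 0), $Q_G$ (Xydeas–Petrović edge
preservation with the standard sigmoid constants, recorded in the
report), MS-SSIM (5 scales, standard exponents, reflect padding so 32×32
images remain valid; negative contrast-structure means clamped at 0) and
SCD (sum of correlations of differences; zero-variance terms contribute
0). Four further metrics that appear in this literature ($Q_M$, $Q_S$,
$Q_{CB}$, VIFF) are defined in substantial third-party specifications and
are deliberately not implemented; their keys are absent from reports.

## Known limitations

* Chrominance is carried over, not fused, so color texture follows the
  color source only.
* VGG-19 initialization (`initFromVGG()`, channel-mean adaptation of the
  first kernel, mapping the first three convolutions onto the encoder
  path) requires the caller to supply the pretrained kernels; no
  downloader ships with the package, and the fallback is the Kaiming
  random initialization.
* Two modalities only; no resolution pyramid, no adversarial components,
  no DICOM/NIfTI readers (inputs are 2-D slice images; convert upstream).
* Training on one CPU is practical at desk scale; full-scale runs
  (128 channels, 120×120 crops, $10^4$ iterations) are supported by the
  same code but are compute-heavy.
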