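---
title: "Two-stage residual attention GAN for iris texture inpainting: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage residual attention GAN for iris texture inpainting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Iris recognition degrades sharply when eyelids and eyelashes occlude the
iris texture, the high-entropy radial pattern between pupil and sclera
that carries the biometric signal.  This package implements a
coarse-to-fine generative adversarial approach to *inpainting* those
occluded regions: a first-stage network restores the contour and rough
texture of the damaged area, and a second-stage network refines it into
texture that is consistent with the intact surroundings.  The package also
implements the preprocessing pipeline that standardizes eye images before
repair, a seeded synthetic-data generator so that every stage is testable
without any external iris database, and the usual evaluation metrics
(PSNR, Fréchet distance between embedded image sets, ROC/EER/TAR).

Everything — the network forward passes, a reverse-mode gradient tape, the
WGAN-GP double-backward, and Adam — is implemented natively on BLAS matrix
operations (with small C++ kernels for the convolution gather/scatter), so
the package has no deep-learning framework dependency.

## Model architecture

**Coarse repair network.**  A U-Net: a 4-layer encoder whose layers apply
two Conv3x3–BN–LReLU modules followed by 2x2 max pooling; a two-module
transition; and a 4-layer decoder that nearest-neighbour upsamples,
concatenates the same-resolution encoder features (a plain skip), and
applies two Conv3x3–BN–LReLU modules.  A final 1x1 convolution and the
output head (below) restrict the output to the input's size, channel
count and intensity range.  At 256x256 input the bottleneck is 16x16.

**Fine repair network.**  A 5-layer encoder: the first layer is a single
Conv3x3–BN–LReLU plus max pool; layers 2–5 are modified residual blocks
(MRBs) plus max pool.  The decoder mirrors it with five layers, each a 1x1
convolution combined with nearest-neighbour upsampling (which avoids
checkerboard artifacts of transposed convolutions; the 1x1 is a full
Conv1x1–BN–LReLU module, adding the nonlinearity the design calls for), a
skip merge, and one Conv3x3–BN–LReLU module, again closed by a 1x1
convolution and the output head.  At 256x256 input the bottleneck is 8x8.

**Output head.**  Both generators map their final features to [0,1]
through a configurable head.  The default is a clamped-linear head
(identity clipped to [0,1], unit gradient inside the interval) rather
than a sigmoid: iris targets are mostly exact-zero background, which a
sigmoid can only approach asymptotically while its gradient vanishes over
most of the output range.  In isolated experiments the clamped head fits
the reconstruction task about five times faster at miniature scale;
`out_act = "sigmoid"` restores the saturating head.

**MRB.**  The block deepens a standard residual unit into two
Conv1x1–BN–LReLU / Conv3x3–BN–LReLU module pairs.  The first pair produces
`y1`, the second pair — applied to `y1` — produces `y2`; an internal
shortcut reuses `y1` directly so the block output is
`Concat(y1, y2) + identity(input)`.  `y1` and `y2` each carry half the
output channels so the concatenation matches the identity branch, and a
1x1 projection is placed on the identity branch whenever input and output
channel counts differ (the block equations require equal channels for the
final addition; the bookkeeping is this implementation's choice).  The
published formulation of the second pair's composition references its
intermediate symbols inconsistently; we follow the textual module order
(modules 1–2 from the input, modules 3–4 from `y1`) and note the
discrepancy here rather than resolving it.

**DACC (dual attention computing connection).**  The fine network's skip
merge, fusing encoder and decoder features in both directions.  From the
encoder features `x_en` it computes spatial-attention gains

    Xsa = sigmoid(Conv7x7(Concat(mean_c(x_en), max_c(x_en))))

where the mean and max run over the *channel* axis (one gain per pixel);
this SA deliberately deviates from the standard module by *not*
multiplying the gains into `x_en`.  The channel branch is a standard
squeeze-and-excitation: `Xse` is the encoder feature map rescaled by its
per-channel gains,

    Xse = x_en * sigmoid(W2 lrelu(W1 GAP(x_en)))

with spatial global average pooling inside.  The decoder features `x_de`
are then fused as

    out = Concat( LReLU(BN(x_de * Xsa)),  Xse * sigmoid(BN(x_de)) )

doubling the channel count: the first branch spatially gates the decoder
reconstruction by where the encoder saw structure, and the second carries
channel-reweighted encoder content into the decoder, gated pixel-wise by
`sigmoid(BN(x_de))`.  Both products are elementwise feature-map
multiplications.  Batch normalization sits *after* the spatial-gain
product in the first branch, following the block equation (the
surrounding prose permits a BN-first reading).  The encoder content in
the second branch matters: without it every branch would merely gate
decoder features, the fine network would have no true skip path, and
reconstruction through the bottleneck alone measurably degrades; the
published description of the connection ("concatenate the features
extracted in the encoder and the features recovered in the decoder")
settles the reading.  Ablation variants are available through
`skip_mode`: `"concat"` replaces the DACC by a plain concatenation and
`"sa_only"` gates the encoder features by their spatial-attention gains
before concatenating.

**Discriminator.**  A WGAN-GP critic: six 5x5 stride-2 convolutions with
leaky ReLU and *no* batch normalization (BN interacts badly with a
per-sample gradient penalty), then Conv3x3–LReLU, global average pooling
to 1x1, and a linear fully connected layer producing one unbounded score.
At 256x256 the pre-pool feature map is 4x4.

## Losses and training

The coarse network minimizes the L1 distance to the unoccluded target.
Its output — detached, so no adversarial gradient reaches the coarse
stage — is the fine network's input.  The critic maximizes score
separation under the gradient penalty; for interpolates
`xhat = eps * real + (1 - eps) * fake`, `eps ~ U(0,1)` per sample,

    penalty = mean( (sqrt( sum(grad_xhat D(xhat))^2 + C ) - 1)^2 )

with smoothing constant `C = 1e-8`.  The smoothed norm keeps the penalty
differentiable when the critic's input gradient vanishes: with `C = 0`
the derivative contains `g / ||g||`, which is NaN on a zero-gradient
batch — the test suite demonstrates both behaviours on a zero-weight
critic.  The critic takes `gd_ratio = 5` updates per generator update,
our reading of the published 1:5 generator:discriminator training-weight
ratio (the standard WGAN practice of multiple critic iterations).

The fine generator minimizes `adv_weight * (-mean D(fake)) +
rec_weight * L1(fake, target)`.  The published description assigns only
the adversarial loss to the fine phase and leaves the weighting across the
two-stage stack open; we anchor the fine stage with an L1 term
(`rec_weight = 100`, the weighting popularized by image-to-image
translation GANs) because a purely adversarial fine stage cannot achieve
per-sample fidelity at the miniature scales this package targets on a
CPU.  The adversarial weight needs care under WGAN-GP: the penalty drives
the critic toward unit input-gradient norm *per image*, so the
adversarial per-pixel gradient is about `1/sqrt(H W)` — at 64x64 roughly
five times the L1 anchor's per-pixel gradient, independent of how the
critic is doing.  `adv_weight = 0.02` keeps the reconstruction gradient
dominant by roughly an order of magnitude, leaving the adversarial term
as a texture refiner.  `rec_weight = 0, adv_weight = 1` recovers the
literal reading.  All three optimizers are Adam with the published
settings: learning rates 5e-4, first-moment decay 0.5, batch size 8;
the second-moment decay (0.9) is a configurable choice of this package.
One *cycle* is 1 coarse update, `gd_ratio` critic updates, and 1 fine
update; `steps` counts cycles.

He initialization (fan-in scaled Gaussians) seeds all weights;
convolutions followed by BN carry no bias, since the batch-mean
subtraction makes such a bias an exactly-zero-gradient direction.

## Preprocessing

Acquired eye images are combined pixel-wise with their binary ground-truth
iris masks (interpreted as masking: intensity kept where the mask is 1,
zero elsewhere, matching the iris-on-black appearance of the published
pipeline), cropped to the mask's bounding box, measured, padded and
resized to 256x256.  The measurement walks the horizontal and vertical
rays through the centroid of the mask's interior hole (the pupil): `d_i`
counts mask pixels along ray `i` and `x_i` is the distance from the inner
iris border to the image border.  Ray-through-centroid is our documented
choice; the published description does not fix the detection algorithm,
and single rays realize its illustrated geometry.  Each side is padded
with `max(d) - x_i + c` background pixels (`c = 20` by default, negative
pads clamped to zero), which equalizes the inner-border-to-border
distances and centers the pupil up to rasterization; tests assert
centering within 2 px.  Padding with `c > 0` also raises the iris
foreground fraction, which on its own improves recognition.

## Synthetic data

The generator emulates ground-truth-segmented, preprocessed NIR iris
images: an annulus (default radii 40/100 at size 256, scaled
proportionally) filled with band-limited polar noise whose orientation
interpolates from radial spokes at the pupil boundary to circumferential
rings at the periphery — the documented biological arrangement of iris
fibres.  `radial_blend` scales the spoke component; at 0 the texture is
purely circumferential, which gives the testable orientation statistic
(variance along circles far below variance along rays).  Occlusions come
in the three kinds used for training-data construction: upper-eyelid and
lower-eyelid arcs entering from their image edge, and bundles of thin
curved eyelash strokes; a bisection on arc depth or stroke length drives
the realized coverage of the iris area into the requested range (default
10–30%).  The builder applies the 8 deterministic augmentation modes
(±10° rotations, horizontal flip, four shifts-with-crop at 10%, center
crop at 90% — the rotation angle and crop ratios are configurable
stand-ins, since the published expansion does not state them) and the 3
mask kinds, yielding exactly 24 triplets per base image.  Occluded pixels
are black; the occlusion mask itself is never fed to the networks.

What the synthetic data does *not* model: specular reflections, off-angle
gaze, motion blur, sensor noise, or the inter-subject texture statistics
of real iris databases.  Tests passing on this data therefore validate
the mechanics (geometry, losses, optimization, metrics) — not
dataset-level restoration quality, which requires the real databases and
GPU-scale training.

## Metrics

PSNR is computed between the preprocessed (unoccluded) reference and the
inpainted output, `10 log10(peak^2 / MSE)`.  The Fréchet distance between
Gaussian summaries of embedded image sets uses an eigendecomposition-based
matrix square root with small negative eigenvalues clipped at `-1e-8`
(numerical PSD drift); the embedding is pluggable, defaulting to a
fixed-seed random-projection convolution stack — adequate for relative
comparisons in tests, not calibrated to Inception-based FID values.
Verification metrics consume genuine/impostor similarity score sets
(higher = more likely genuine): the ROC sweeps all distinct thresholds,
and EER / TAR@FAR interpolate linearly *in (FAR, FRR) space*, which makes
them invariant under strictly monotone transforms of the scores.  EER and
TAR are reported in percent.

## Problem sizes and numerical choices

The standard demonstration configuration (`end_to_end_demo`, also used by
`scripts/acceptance.R`) trains on 64x64 synthetic triplets (6 base images
x 24 = 144 triplets), channel widths divided by 4, 200 cycles, batch 8,
and evaluates on 12 held-out triplets from an independent seed; this runs
in minutes on one CPU while exercising every component at full depth.
Checkpoints serialize via R's native format and round-trip bit-exactly.
Leaky-ReLU slope 0.2, SE reduction ratio 16 (bottleneck at least one
unit), maxpool 2x2 stride 2, same-padding everywhere, BN eps 1e-5 with
momentum 0.1 and running statistics in inference mode.  Batch-norm over a
batch uses population variance; gradient checks run in training mode and
filter finite-difference probes that cross activation kinks (leaky-ReLU
sign or pooling argmax switches), where central differences are undefined.

## Known limitations

- Published dataset-level numbers (PSNR ≈ 22–24 dB, FID 16–43,
  EER 0.038–1.4%, TAR 95–99% on CASIA/IITD/ND-IRIS) are out of reach at
  desk scale by design; nothing here downloads those databases.
- The CBAM skip variant of the published ablations is not implemented
  (external published module); `skip_mode` covers the plain-concat and
  SA-only ablations.
- The recognition classifier used for the published verification
  experiments is out of scope; `score_set` accepts scores from any
  embedding or classifier the user supplies.
- Training is single-CPU, double precision, single-process; there is no
  mixed precision or distributed support.
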