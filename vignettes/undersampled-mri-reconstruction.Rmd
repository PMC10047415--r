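---
title: "Under-sampled parallel MRI: simulation, learned reconstruction and the hybrid k-space loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Under-sampled parallel MRI: simulation, learned reconstruction and the hybrid k-space loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

MRI acquires data in k-space, the 2-D spatial-frequency domain; images are
obtained by inverse Fourier transform. Scanning time is proportional to the
number of phase-encode lines acquired, so accelerated (parallel) imaging
skips lines — at acceleration factor $R$ only every $R$-th phase-encode
column is measured. Sub-Nyquist sampling folds the object onto itself:
interleaved Cartesian under-sampling at $R = 2$ superimposes each pixel with
its half-field-of-view neighbour along phase-encode ("ghosting"). Classical
parallel imaging (SENSE) unfolds these replicas using the spatial
sensitivity profiles of the receiver coils, at the cost of noise
amplification. This package implements a learned alternative: a U-Net or an
image-conditional GAN maps the aliased sum-of-squares image directly to the
fully sampled reference, trained under a *hybrid* loss that penalizes the
L1 difference in the image domain and in k-space simultaneously, and
benchmarks it against SENSE with local-window SSIM/PSNR plus a rank-based
significance protocol.

## Transforms and retrospective under-sampling

All transforms are DC-centered with orthonormal $1/\sqrt{HW}$ scaling in
each direction, so `image_to_kspace()` / `kspace_to_image()` are unitary and
exact inverses; Parseval's identity holds to machine precision. The source
work never states its FFT normalization or centering — only relative
quantities depend on it, and the orthonormal centered convention makes the
energy checks exact and keeps the Fourier-loss weight comparable across
resolutions. Rows are frequency-encode, columns phase-encode;
`make_interleaved_mask(H, W, R)` keeps 0-based columns $j \equiv 0 \pmod R$,
matching the usual "every second column" slice notation.

A prepared training pair runs the retrospective chain on one fully sampled
multi-coil frame: per-coil inverse transform, bilinear complex resize to the
working resolution (real and imaginary channels resized with the same linear
interpolator, so the operation is linear and reproduces constants), then

* **ground truth**: sum-of-squares combination of the resized coil images;
* **aliased input**: forward transform per coil, interleaved mask, inverse
  transform, sum-of-squares.

Both images are mapped to $[0, 255]$ with a *shared* affine factor taken
from the ground-truth range. The source normalizes "all aliased images"
without saying whether the factor is shared within a pair; sharing preserves
the physical intensity deficit of the masked image, which is exactly the
signal the network must learn to restore, so it is the package default. A
constant (degenerate-range) image normalizes to zeros with a warning.

The published split fractions are contradictory (70/10/20 in one place,
30% testing in another, and per-split counts that do not sum to the stated
total); `split_spec()` therefore defaults to 70/10/20 and is configurable,
with floor rounding for validation/test and the remainder assigned to
training. Augmentation (`augment_pair()`) applies the sampled transform
identically to both images of a pair: random 90-degree rotations,
deterministic horizontal/vertical mirror flips, and a random 75-100% crop
resized back to frame size.

## The phantom simulator

Real multi-coil cine cardiac data require a large download and cannot ship
with a package; the simulator provides the statistical structure the
pipeline assumes so that every stage is testable offline:

* **Anatomy** (`generate_phantom()`): a large background ellipse filled with
  a base intensity plus a configurable number of interior ellipses with
  distinct intensities in $[0, 1]$ — piecewise-smooth magnitude, as in
  tissue — and a smooth random linear phase ramp (amplitude `phase_amp`,
  default $\pi/4$; B0-inhomogeneity-like phase at a realistic desk scale).
* **Coils** (`generate_coil_maps()`): one broad Gaussian magnitude profile
  per coil, centred at equally spaced border positions with a gentle linear
  phase, jointly normalized so the per-pixel sum of squared magnitudes is
  exactly 1 (the normalization SENSE assumes). Defaults: 16 coils at
  256 x 256, within the 15-35 coil range of the raw data the pipeline
  emulates; desk-scale tests use 4-8 coils at 64 x 64.
* **Acquisition** (`simulate_acquisition()`): per coil,
  $k_c = \mathcal{F}\{s_c \odot \rho\}$ plus circular complex Gaussian noise
  of SD `noise_sigma` per real/imaginary channel added *in k-space*
  (acquisition-domain noise). The default `noise_sigma = 0.01` against a
  unit-magnitude phantom gives a visually clean but non-trivial noise floor.

What the simulator does **not** model: cardiac motion, gradient-encoding
physics, coil coupling and noise covariance, non-Cartesian trajectories.
A green test therefore establishes algorithmic correctness of the pipeline
on data satisfying the parallel-imaging model assumptions — not clinical
performance on scanner data.

Fixtures are written as HDF5 with real/imaginary planes stored as separate
datasets (`kspace_real`/`kspace_imag`, optional `maps_real`/`maps_imag`,
scalar `seed` and `noise_sigma`): the available HDF5 binding has no complex
datatype.

## SENSE baseline

`estimate_sensitivities()` is a lowpass-normalized estimator standing in
for the unpublished estimation algorithm of the source's reference: each
fully sampled coil image is smoothed with a broad circular Gaussian and
divided by the sum-of-squares of the smoothed stack. The kernel "width" is
read as the kernel *footprint* — default one eighth of the image, with
Gaussian SD a quarter of the footprint (the usual $\pm 2\sigma$ truncation
convention). The wider reading (SD = size/8) blurs across the object
boundary strongly enough that map recovery degrades several-fold, which is
why the footprint convention was fixed once and kept. Pixels whose smoothed
sum-of-squares falls below 0.1 of its maximum are outside the object and
set to exactly zero. On a zero-phase phantom the estimator recovers the
simulator's ground-truth maps to a few percent; on a phased object the
object's smooth phase is absorbed into the maps, which leaves the magnitude
reconstruction unchanged — this identifiability limit is inherent to any
ratio estimator, not a defect.

`sense_reconstruct()` inverse-transforms the zero-filled under-sampled
k-space per coil and unfolds each group of $R$ half-FOV replicas by solving
the stacked per-pixel least-squares system built from the maps. The replica
weights (which absorb the $1/R$ amplitude scaling of the zero-filled
transform and any mask-offset phase) are read off the masked reconstruction
of a delta image — exact, because the masking operator is circularly
shift-invariant. The solve is Tikhonov-regularized with factor
$10^{-6}\,\lVert A\rVert$ so rank-deficient systems stay finite, and pixels
whose smallest singular value falls below $10^{-3}$ are flagged
ill-conditioned. For noise-free data with non-degenerate maps and
$R \le C$ the reconstruction equals the phantom magnitude to solver
tolerance; at $R = 1$ it reduces to the matched-filter combination
$\sum_c \bar{s}_c y_c / \sum_c |s_c|^2$.

## Losses

With $\hat{y}$ the network output and $y$ the reference, both on the
$[0,255]$ scale, the loss set is:

* spatial L1: per-pixel mean of $|\,y - \hat{y}\,|$, batch-averaged;
* Fourier (k-space) L1: per-bin mean complex modulus of
  $\mathcal{F}\{y\} - \mathcal{F}\{\hat{y}\}$ under the package's centered
  orthonormal transform, real images entering as zero-phase complex;
* hybrid U-Net objective: spatial + $\alpha\,\cdot$ Fourier +
  $\lambda \lVert\Theta\rVert^2$, with the published $\alpha = 0.1$ and
  $\lambda = 10^{-5}$ by default (the $\lambda\lVert\Theta^2\rVert$
  notation is read as standard squared-L2 weight decay);
* adversarial terms: binary cross-entropy for the discriminator; the
  generator uses the non-saturating surrogate $-\log D(x, G(x))$, the
  practical form for composite-model training with a frozen discriminator,
  plus $\sigma\,\cdot$ spatial L1 ($\sigma = 100$, the image-conditional
  GAN convention — the source only says $\sigma$ is chosen empirically) and,
  in the hybrid mode, the same $\alpha = 0.1$ Fourier term.

Norms are per-pixel *means* rather than sums: the source writes
$\lVert\cdot\rVert$ without pinning the scaling, and means keep the printed
$\alpha$ meaningful when the resolution changes. All components are
reported separately in a `loss_breakdown`, whose total always equals the
documented weighted sum.

## Networks and training

No deep-learning framework exists in this R environment, so the networks
and backpropagation are implemented in the package (convolutions as
compiled im2col + BLAS kernels; gradients verified against finite
differences in the test suite). Architectural facts fixed by the source:
3 x 3 zero-padded convolutions, 2 x 2 max pooling, LeakyReLU(0.2) encoder,
ReLU decoder, skip concatenation at every resolution, random-normal
initialization with SD 0.02, Adam at learning rate 0.0002, batch size 8;
discriminator of six consecutive convolutions with batch normalization on
stages 2-5, ReLU on 1-5 and a terminal sigmoid, consuming the
condition/candidate pair as one two-channel input. Choices the source
leaves open, fixed here as package defaults:

* channel widths and depth (the published parameter counts come with no
  architecture detail): depth 4 with base 16 at the 64 x 64 desk scale,
  depth 7 with base 64 for full-scale 256 x 256 work;
* generator output activation: tanh, with images scaled to $[-1, 1]$
  internally and mapped back to $[0, 255]$ at the boundary;
* Adam $\beta_1 = 0.5$ (the conditional-GAN heritage convention), one
  discriminator step per generator step, labels 1/0 without smoothing;
* the discriminator emits a spatial probability map averaged inside the
  cross-entropy (scalar-vs-patch output is unstated in the source);
* discriminator batch normalization uses batch statistics (it is only ever
  evaluated on training batches);
* augmentation is applied on-the-fly rather than materializing a fixed
  multiple of the training set.

CGAN training alternates a discriminator update (real pairs $(x, y)$
against generated pairs $(x, G(x))$, generator detached) with a generator
update taken through the composite model: the adversarial gradient flows
backward *through* the discriminator into the generated image, but only
generator parameters are stepped — the discriminator is frozen by
construction, and the test suite asserts its parameter checksum is
unchanged across such an update.

## Evaluation

PSNR uses $20\log_{10}(255/\sqrt{\mathrm{MSE}})$ with the fixed
normalization ceiling 255 as the maximum possible value (not the per-image
maximum); identical images return an `Inf` sentinel that is excluded from
means with a warning. SSIM follows the local windowed form with unweighted
8 x 8 windows at stride 1, population variance convention, and the standard
constants $c_1 = (0.01 \cdot 255)^2$, $c_2 = (0.03 \cdot 255)^2$ (the
source gives no constants). Although the source states SSIM in $[0, 1]$,
the measure's true range is $[-1, 1]$ and that is what the package
enforces. `evaluate_models()` keeps a strictly paired design — every method
scores the same images in the same order, and a method failure excludes the
image for all methods. `significance_compare()` mirrors the published
protocol: Shapiro-Wilk normality screen, then Mann-Whitney rank-sum against
the chosen baseline at the 0.05 threshold. The rank-sum uses the normal
approximation without continuity correction so that identical samples give
exactly $p = 1$; all-tied comparisons are flagged and reported as $p = 1$.
No multiple-testing correction is applied, matching the protocol.

## Numerical choices and degenerate inputs

* Tikhonov factor $10^{-6}\lVert A\rVert$ and singular-value flag threshold
  $10^{-3}$ in SENSE; rank-deficient pixels are flagged, never NaN.
* Discriminator probabilities are clipped to $(10^{-7}, 1 - 10^{-7})$
  before logs.
* Max-pooling routes gradient to the first maximal entry on exact ties.
* The Fourier-loss gradient uses the unitarity of the centered transform
  (adjoint = inverse); bins with zero modulus contribute zero subgradient.
* Constant images normalize to zeros with a warning; empty transform lists
  are the identity; `accel = 1` masks are all-ones and `prepare_pair` then
  yields aliased = truth.
* All randomness flows through explicit seeds; generators are pure
  functions of (configuration, seed), and training histories are exactly
  reproducible for a fixed configuration.

## Scaled-down testing regime

The published headline numbers were obtained from ~1400 real cine frames at
256 x 256 with ~60M-parameter networks trained 100 epochs on a GPU; that is
out of reach for a package test suite, so the suite works at a desk scale
the source's procedures are exercised at faithfully: 64 x 64 frames, 4-8
coils, depth-4/base-16 generator (~1M parameters), a few hundred simulated
pairs and a handful of epochs. At that scale the documented checks are
property-based: exact transform/aliasing/SENSE oracles, loss closed forms,
frozen-discriminator contract, at least 1 dB held-out PSNR improvement of
the trained U-Net over its aliased input in both the plain-L1 and hybrid
modes, and an overfit smoke test that halves the training loss within 200
steps. No claim is made that desk-scale metric values reproduce the
published table values.

## Known limitations

* Interleaved Cartesian masks only; no non-Cartesian trajectories,
  partial-Fourier or GRAPPA, no g-factor maps, no iterative/regularized
  SENSE variants.
* The under-sampled half of the workflow assumes the phase-encode width is
  divisible by $R$.
* Sensitivity estimation recovers maps only up to the object's smooth
  phase (see above).
* The CGAN at desk scale is adversarially unstable for very long runs, as
  small GANs are; the package reports per-component loss curves so this is
  visible in the history.
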