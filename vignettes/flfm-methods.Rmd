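---
title: "Fourier light-field microscopy with two-stage learned reconstruction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fourier light-field microscopy with two-stage learned reconstruction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(flfm)
```

## The imaging problem

Fourier light-field microscopy (FLFM) places a microlens array in a plane
conjugate to the objective's back pupil. Each lenslet then images the sample
from a distinct sub-aperture of the pupil, so a single camera exposure
records a handful of perspective *views*, and the axial position of an
emitter appears as lateral disparity (parallax) between them. One 2D frame
therefore encodes a 3D volume, which is what makes video-rate volumetric
imaging of living cells possible — at the cost of an ill-posed inverse
problem: the views are few, diffraction-limited, and, at the short exposures
live imaging demands, severely photon-starved.

This package implements the complete computational chain for a
three-lenslet FLFM instrument in which the microlens array is realised as a
diffractive optical element (DOE):

1. a wave-optics simulator of the instrument point-spread function (PSF),
2. the image-formation model `y = H*x + n + b` with a physical noise model,
3. view calibration and extraction geometry,
4. multi-view Richardson–Lucy (RL) deconvolution as the classical baseline,
5. seeded synthetic phantom generators and training-set assembly,
6. a two-stage deep reconstruction (view-attention denoiser + view-to-depth
   network) with its losses, pretraining, joint training and inference, and
7. quantitative evaluation (SNR, SSIM, NRMSE, spectral resolution).

## Optical model

The instrument is described by `optical_config()`: a 100×/1.4 NA
oil-immersion objective (n = 1.518), emission wavelength 510 nm (EGFP),
a 300 mm Fourier lens, and a DOE carrying three lenslets of pitch
d = 3.25 mm and focal length f_ML = 120 mm (f-number ≈ 37). The Fourier
pupil radius at the DOE plane is `R = f_FL · NA / M` (4.2 mm for the
defaults); the three lenslet apertures form an equilateral triangle at the
radius where they inscribe the pupil, maximising aperture use while
segmenting it into three perspective views. The sensor-referred lateral sampling is
`Δx = pixel / (M · f_ML / f_FL)` = 6.5 µm / 40 = 162.5 nm, and the
reconstruction depth grid defaults to 41 planes across ±3.5 µm (175 nm
z-step). All of these are configuration fields, not constants.

The PSF is computed by scalar diffraction. For an on-axis emitter at
defocus z the pupil field carries the high-NA defocus phase
`φ_z(ρ) = (2π/λ) z sqrt(n² − NA² ρ²)` on the normalised pupil radius ρ.
The DOE multiplies it by an amplitude mask (zero outside the lenslet
apertures) and, per lenslet, the wrapped thin-lens phase
`−π r² / (λ f_ML)` about the lenslet centre. Propagation over f_ML to the
sensor is a single-FFT Fresnel transform between conjugate planes: the
quadratic Fresnel kernel phase cancels the lens phase within each aperture,
leaving a linear ramp that lands each sub-PSF at its lenslet centre mapped
1:1 onto the sensor. Two numerical consequences are worth noting:

* **Sampling.** The DOE-plane sample spacing is tied to the sensor pixel
  pitch, `du = λ f_ML / (N Δpix)`. Before every depth the worst-case phase
  gradient (lens ramp + defocus) is checked against the π-per-sample limit
  and an informative error names the offending depth. Because the pupil
  field has unit modulus, per-depth energy on the FFT grid is conserved
  exactly; the `< 5%` energy-constancy invariant only measures view-window
  cropping.
* **Convergence, not padding.** In this conjugate-plane formulation the
  simulation window cannot be zero-padded independently of the sensor:
  doubling the grid refines the pupil sampling too. The test suite therefore
  asserts 1% stability of the per-view kernels under grid doubling, which
  bounds wrap-around and aperture-discretisation error together.

The geometric parallax oracle used in tests is the ray slope
`−NA² u f_ML / (R² sqrt(n² − NA² (|u|/R)²))` averaged over the (uniformly
filled) lenslet aperture; the aperture average, rather than the value at the
lenslet centre, is what the intensity centroid of a sub-PSF follows (the
ray slope is superlinear in pupil radius, so the two differ by ~15% at this
NA).

A desk-scale variant, `mini_optical_config()`, shrinks the Fourier optics
(f_FL = 75 mm, d = 0.8 mm, f_ML = 30 mm) so the full PSF fits a 320² grid
while keeping the objective, wavelength and 162.5 nm sampling of the full
instrument. All simulation studies and tests run on it; the default
configuration differs only in scale.

## Image formation and noise

`forward_project()` implements `y = Σ_z x_z ⊛ H_z` with zero-padded FFT
convolutions (one forward FFT per occupied depth plane plus a single
inverse). `corrupt_lf()` applies, in the physical shot-then-read order:
Poisson noise on the clean intensities (`Poisson(g·clean)/g`), additive
Gaussian read noise, then the constant background b, clipped at zero —
the clip mirrors a camera after offset subtraction, and is documented
because it slightly biases the realised SNR at very low SNR.

`fit_noise_to_target()` inverts this model for a requested SNR/SBR pair:
the background is solved in closed form from the SBR definition (foreground
= pixels above the Otsu threshold of the clean image; SBR = mean foreground
over mean background after adding b), the Poisson gain is set so shot noise
carries half of the noise-power budget `S / 10^(SNR/10)`, and the Gaussian
σ is refined by bisection against the seeded Monte-Carlo realised SNR,
which absorbs the clipping bias. SNR here and everywhere is the log power
ratio `10·log10( Σ(f−f̄)² / Σ(f̂−f)² )`.

## Richardson–Lucy baseline

`richardson_lucy()` is the standard multiplicative update
`x ← x · A^T(y/(Ax+ε)) / A^T 1` with `A` the per-view depthwise convolution
summed over depth, run for a fixed 30 iterations by default (the classical
FLFM reconstruction against which the learned method is compared; a fixed
iteration count is the package convention, exposed in the configuration). The forward/adjoint pair is built once per call as
padded-FFT operators and is exactly adjoint (verified by a dot-product test
at 1e−10), which is what guarantees the Poisson likelihood is non-decreasing
— also asserted per-iteration in the tests. ε is a ratio guard, not a
threshold, preserving the multiplicative structure; nonnegativity is
automatic.

## Synthetic phantoms and training data

Real training would use high-resolution confocal/Airyscan stacks of labelled
organelles; the package emulates them with three seeded generators:

* `beads` — Gaussian spots of configurable FWHM with enforced 3D and
  lateral minimum separation (for localisation oracles);
* `hollow_tubes` — smooth random-walk centrelines dressed with a Gaussian
  shell (outer diameter 400–1000 nm, wall 80–150 nm by default): the
  mitochondrial outer-membrane surrogate. The walls are chosen unresolvable
  in a single diffraction-limited view but resolvable at the ~180 nm
  reconstruction scale; the lumen is strictly darker than the wall by
  construction;
* `filament_network` — thin (100 nm) random-walk filaments, the ER
  surrogate.

`build_dataset()` assembles training triplets: the phantom on the FLFM grid
(HR stack, the reconstruction ground truth), its clean extracted views (the
denoising ground truth), and noise-corrupted views at an SNR drawn uniformly
from a configurable range — bit-reproducibly from one master seed.
What these phantoms deliberately do **not** model: organelle motion within
an exposure, spatially varying background, fixed-pattern camera noise, or
optical aberrations beyond defocus. A model that passes every test here has
been shown to invert *this* simulator, under matched PSF and noise
statistics — transfer to a real instrument additionally depends on
calibration quality and on how far the real PSF and noise depart from these
models. The training-set size and SNR distribution of the original study are
not public; the defaults (tens of triplets, SNR −2…+4 dB) are chosen to be
in the photon-starved regime the method targets.

Geometric flip/rotation augmentation is applied identically to all three
members of a triplet, in image space. Flips do not commute with the
three-view parallax geometry, so augmented triplets carry an `augmented`
flag and are excluded from physics-consistency tests.

## The two-stage network

Both stages are built on a small reverse-mode autodiff engine written for
this package (im2col convolutions over BLAS, exact gradients verified
against numerical differentiation at 1e−4 relative). Everything runs on one
CPU; widths and depths are configuration, with defaults sized for
desk-scale experiments.

**Stage 1 — denoiser.** A residual channel attention (RCAN-style) trunk on
the 3-view stack: residual groups of channel-attention blocks
(conv–LReLU–conv with a squeeze-excite gate), long skip connections, and a
final correction added to the input. On top of the channel attention sits a
*view-attention* branch: for a three-view stack processed with views as
channels, the dimension permutation (view, h, w, c) → (c, h, w, view) ahead
of the attention pooling reduces to pooling the view axis of the input;
the branch turns that pooled 3-vector into a sigmoid gate that reweights the
per-view correction, letting the network trust views with different SNR
differently. Disabling the branch reduces the model to plain RCAN exactly
(24 parameters fewer in the default width — a structural test asserts this).
The correction's final convolution is zero-initialised, so an untrained
denoiser is the identity map — the standard residual-denoising start.

**Stage 2 — reconstructor.** Three dilated convolution blocks (rates 1/2/4)
extract multi-scale features from the three views and are concatenated —
this is what compensates for having only three views to infer ~dozens of
depth planes from. After an optional sub-pixel (pixel-shuffle) upscale, a
two-level U-Net with residual blocks, instance normalisation and LeakyReLU
maps features to one output channel per depth plane. There is no final
activation; outputs are clamped at zero at inference only, so weak signals
are not truncated during optimisation.

**Losses and training.** The denoiser minimises a weighted L1–L2 loss
(`α·mean|e| + (1−α)·mean e²`, α = 0.5 by default: L1 for denoising strength,
L2 for convexity). The reconstructor minimises L2 plus a finite-difference
gradient term (pooled over every spatial axis) for high-frequency recovery.
Joint training optimises `0.2·denoise + 0.8·reconstruction` with both
sub-networks updated simultaneously, after separate pretraining of each
stage (the reconstructor pretrains on *clean* views — the interface on
which the two stages meet). Pretraining uses larger lateral patches
(160×160×3 by default) than joint optimisation (80×80×3). The optimiser is
Adam with a step-decayed learning rate (×0.5 every `lr_decay_every` steps;
the decay schedule itself is a design choice). A validation split is scored
every few steps and the best-validation weights are restored at the end.
Training is bit-reproducible under a fixed seed.

**Inference.** `fvcd_infer()` realigns a raw light field through the
calibration (rotate, then crop views — the order is a package convention),
runs both stages, and clamps at zero. Tiled inference with overlap is
provided for large frames; it is exact on tile interiors only for models
free of global statistics — instance normalisation and the pooled attention
gates tie activations to whole-image statistics, which is a real limitation
of tiling such networks, stated rather than hidden.

## Evaluation

`measure_snr()` is the log-power-ratio formula above, transcribed
symbol-for-symbol and unit-tested on a worked example (6.021 dB).
`ssim()` is the standard uniform-window (7², or 7³ for volumes) SSIM with
sample-covariance normalisation; `nrmse()` is RMSE over the reference's
dynamic range. Both are cross-checked against scikit-image's reference
implementations to 1e−6 on frozen deterministic fixtures. `error_map()`
normalises both volumes to the ground truth's [0, 1] range before taking
absolute differences (stated because it changes values).

`resolution_from_spectrum()` estimates resolution as the reciprocal of the
frequency at which the radially averaged power spectrum falls to its noise
floor. The floor is the median power in the highest-frequency decile of
radial bins; the crossing threshold is twice the floor, but never below
1e−4 of the low-frequency signal power (which guards the degenerate
noise-free case); a spectrum with no low-frequency excess over the floor is
flagged and reported at the sampling limit. The criterion is deliberately
isolated behind this one function so a decorrelation-based estimator can be
swapped in.

## Scale of the bundled studies

The test suite and the acceptance script run complete studies on the
desk-scale instrument: PSFs on 320² grids with 21 (or 13) depth planes,
49–65 px views, 32-triplet hollow-tube training sets, denoiser/reconstructor
widths of 8/12–16 channels, 250 pretraining and 450 joint steps. These sizes
are the package's chosen experiment scale for single-CPU reproducibility;
every one of them is a config parameter, and the architecture accepts the
full-instrument sizes (41 planes, 160/80-px patches) unchanged — structural
tests run the forward graphs at those sizes. At the bundled scale the
learned reconstruction beats 30-iteration Richardson–Lucy on held-out
volume SSIM and gains >3 dB of view SNR, on inputs down to −2 dB; headline
instrument-scale numbers (sub-200 nm resolution at 50 volumes/s) require
the real microscope and full-scale training and are outside what synthetic
desk-scale studies can demonstrate.

## Known limitations

* Scalar diffraction with a uniform pupil: no vectorial high-NA effects,
  apodisation, or aberrations; the DOE is modelled as its equivalent ideal
  microlens phase.
* The noise model is pixel-iid Poisson + Gaussian + constant background.
* Tiled inference is approximate for normalisation/gating networks (above).
* The spectral resolution criterion is a pragmatic noise-floor crossing,
  not a decorrelation analysis.
* Training at realistic instrument scale is out of reach of a pure-R CPU
  implementation; the engine is sized for method studies, not production
  training.
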