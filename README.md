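# flfm

Simulation, deconvolution and two-stage learned reconstruction for Fourier
light-field microscopy (FLFM) with a three-lenslet diffractive Fourier
microlens.

## The problem

FLFM puts a microlens array in a plane conjugate to the objective's back
pupil, so one camera exposure records three perspective views of the sample
and the depth of an emitter shows up as parallax between them: a single 2D
frame encodes a 3D volume, enabling video-rate volumetric imaging of living
cells. Recovering the volume is an ill-posed inverse problem — only three
diffraction-limited views, and very few photons at live-imaging exposures.
This package is for microscopists and methods developers who want to study
that inverse problem end to end on a desk: a physically grounded simulator
of the instrument, the classical deconvolution baseline, and a trainable
two-stage reconstruction network, all seeded and reproducible on one CPU.

## What is implemented

**Image formation.** The sensor image is `y = H*x + n + b`: the 3D sample
`x` projected depthwise through the instrument PSF `H`, plus Poisson shot
noise and Gaussian read noise `n` and a constant background `b`. `H` is
computed by scalar Fresnel diffraction: high-NA defocus phase
`(2π/λ) z sqrt(n² − NA²ρ²)` in the pupil, the DOE's wrapped per-lenslet
thin-lens phase `−π r²/(λ f_ML)`, and a single-FFT Fresnel transform to the
sensor. Defaults describe a 100×/1.4 NA system with a 300 mm Fourier lens
and a three-lenslet DOE (pitch 3.25 mm, f_ML = 120 mm, f/37), imaging 41
planes across ±3.5 µm at 162.5 nm sensor-referred sampling.

**Reconstruction.** (1) Multi-view Richardson–Lucy:
`x ← x · A^T(y/(Ax+ε)) / A^T 1`, the classical baseline, with an exactly
adjoint FFT operator pair so the Poisson likelihood is provably
non-decreasing. (2) A two-stage network: a residual channel-attention
denoiser with an added view-attention gate (noisy views → clean views),
followed by a dilated-convolution view-to-depth reconstructor (three views →
depth stack), trained with a weighted L1–L2 denoising loss and an
L2+gradient reconstruction loss combined 0.2/0.8, Adam with decaying
learning rate, stage-wise pretraining then joint optimisation. The layers,
reverse-mode autodiff and optimiser are implemented in the package, in R.

**Around them:** view calibration/extraction from a reference exposure,
seeded phantom generators (beads, hollow "mitochondria" tubes, "ER"
filament networks), training-set assembly with noise fitted to target
SNR/SBR, evaluation metrics (log-power SNR, SSIM, NRMSE, spectral
resolution), and an end-to-end pipeline with a checksummed run manifest.

## Worked example

Simulate a bead sample on the desk-scale instrument, corrupt it to the
photon-starved regime, and reconstruct:

```r
library(flfm)

cfg  <- mini_optical_config()             # desk-scale instrument, 21 planes
psf  <- compute_psf(cfg, view_size = 65)  # Fresnel PSF, 320x320 sensor

spec <- phantom_spec("beads", shape = c(cfg$depth_planes, 65, 65),
                     voxel_size_nm = c(350, 162.5, 162.5),
                     count = 3, seed = 5, margin_vox = 18,
                     min_separation_nm = 2000)
gt    <- make_phantom(spec)
lf    <- forward_project(gt, psf)                      # clean light field
cal   <- calibration_from_config(cfg, view_size = 65)
views <- extract_views(lf, cal)

np    <- fit_noise_to_target(views$data, target_snr_db = -1.62,
                             target_sbr = 3, seed = 7)
noisy <- corrupt_lf(views$data, np)
cat(sprintf("realised SNR: %.2f dB\n",
            measure_snr(views$data + np$background, noisy)))

rec <- richardson_lucy(views, psf_views(psf, cal),
                       deconv_config(iterations = 30))
nrm <- function(v) v / max(v)
cat(sprintf("RL vs ground truth: SSIM = %.3f, NRMSE = %.3f\n",
            ssim(nrm(gt$data), nrm(rec$data), data_range = 1),
            nrmse(nrm(gt$data), nrm(rec$data))))
```

Output:

```
realised SNR: -1.64 dB
RL vs ground truth: SSIM = 0.997, NRMSE = 0.003
```

The fitted noise here was `gain = 118.9` photons/unit, `σ = 0.0025`,
`b = 0.0090`: the requested −1.62 dB working point is realised within
0.02 dB, and on *noiseless* views RL localises all three beads to within a
voxel (that, not the SSIM of an easy bead volume, is the meaningful check —
the test suite asserts it). On noisy views RL degrades quickly, which is
the regime the learned two-stage reconstruction targets: in the bundled
32-triplet hollow-tube study the trained model denoises held-out views by
~15 dB and beats 30-iteration RL on volume SSIM on every held-out sample.
See `vignettes/flfm-methods.Rmd` for the models, parameters and the
reasoning behind every default.

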