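# cwflow

Fast single-shot 3D reconstruction of sparse fluorescent volumes from
Fourier light-field (XLFM) images, with exact-likelihood out-of-distribution
detection, in R.

An XLFM records spatial-angular information in one camera exposure: every
micro-lens forms its own perspective view of the sample. Recovering the 3D
volume from such an image is classically done with iterative Richardson-Lucy
(RL) deconvolution, which is accurate but far too slow for closed-loop
imaging of live samples (e.g. whole-brain calcium activity in immobilized
zebrafish larvae). `cwflow` implements a learned alternative: a hierarchy of
**conditional normalizing flows over an axial Haar wavelet pyramid**. The
volume density is factorized as

    log p(V0 | C) = log p(Vn | C) + sum_i log p(D_i | Omega_i(C))

where `D_i` are the orthonormal axial Haar detail coefficients at level `i`,
`Vn` is the coarsest volume (predicted by a deterministic low-resolution
network), and `C` are the conditions: per-lens crops of the measured image,
a structural prior (mean of the training volumes), and optionally a partial
deconvolution of the measurement. Each detail term is a conditional flow of
6 conditional affine transform (CAT) blocks whose elementwise scale and
translation come from small convolutional subnets, so the change-of-variables
log-determinant is exact and cheap. Reconstruction runs the hierarchy
backwards from a temperature-`T` latent sample; `T = 0` gives the modal,
fully deterministic reconstruction. Because the likelihood is exact, the
same model scores novel frames per level; frames whose negative
log-likelihood exceeds a calibrated threshold are flagged out-of-distribution
and the model can be fine-tuned on them.

The package includes a complete synthetic XLFM testbed (lenslet PSF
synthesis, linear forward projection with an exact adjoint, lens-center
detection, view cropping), Richardson-Lucy deconvolution, the flow hierarchy
with its trainer, likelihood-based OOD detection and fine-tuning,
reconstruction metrics (PSNR, masked MAPE, per-neuron temporal Pearson
correlation), and a command-line interface.

## Worked example

Simulate a recording, train, reconstruct a held-out frame, and score an
out-of-distribution sample:

```r
library(cwflow)

layout <- lens_layout(expand.grid(row = c(24, 48, 72),
                                  col = c(24, 48, 72)), crop_size = 32)
psf    <- synthesize_psf(layout, depth_count = 16, spot_sigma = 2,
                         parallax_per_depth = 1, image_shape = c(96, 96))

scene  <- generate_scene(seed = 1)            # 5 neurons, 40 frames
bundle <- render_dataset(scene, psf, layout, seed = 1)

model  <- build_model(cwfa_config(seed = 1))
model  <- train_model(model, bundle_pairs(bundle, "train"),
                      train_config(seed = 1))$model

fr  <- bundle$frames[[30]]                    # held-out frame
rec <- reconstruct(model, fr$cond, temperature = 0)
psnr(fr$v0, rec$volume)                       # ~58 dB
psnr(fr$v0, bundle$prior)                     # ~35 dB (static baseline)
mape_masked(fr$v0, rec$volume)                # ~0.2 (fraction)

beads <- generate_ood("beads", psf, layout, density = 1e-3, seed = 51)
likelihood_of(model, bundle$frames[[25]]$v0, bundle$frames[[25]]$cond)
#> per-level NLL around -5 per level (in distribution)
likelihood_of(model, beads$frames[[1]]$v0, beads$frames[[1]]$cond)
#> per-level NLL orders of magnitude higher -> flagged OOD
```

On a full run with these defaults (seed 1) the acceptance script below
prints: held-out reconstruction PSNR 57.6 dB against 36.3 dB for the
static-prior baseline and 37.9 dB for the LR-only (zero-details) baseline;
masked MAPE 0.19; zero-temperature reconstruction beats temperature-1
sampling (57.6 vs 50.6 dB); out-of-distribution AUC and F1 of 1.0 against
bead and non-sparse families; and fine-tuning on a new specimen raises its
PSNR by 4.8 dB while the append strategy keeps the original family within
0.02 dB.

A shell interface with the same functionality lives in `inst/cli/cwflow`
(`simulate`, `detect-lenses`, `crop-views`, `deconv`, `train`,
`reconstruct`, `ood`, `finetune`, `metrics`); every run writes a JSON
manifest with its configuration, seed and input digests.

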