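---
title: "Conditional wavelet flows for light-field reconstruction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional wavelet flows for light-field reconstruction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

An XLFM (Fourier light-field) microscope records, in a single camera
exposure, an array of perspective views of a fluorescent sample: every
micro-lens acts as a small camera, and a point source appears once behind
each lens, laterally displaced with depth by a lens-dependent parallax. The
classical route from such an image $m$ back to a 3D volume $v$ is iterative
Richardson–Lucy (RL) deconvolution of the linear model $m = A v$, where $A$
projects each depth plane through the matching PSF plane and sums. RL is
accurate but slow — far too slow for closed-loop experiments on live
animals, where thousands of frames of calcium activity need to be
reconstructed as they are acquired.

`cwflow` implements a learned alternative: a hierarchy of conditional
normalizing flows over an axial Haar wavelet pyramid. It reconstructs in a
single forward pass, and — because a normalizing flow has an exact,
tractable likelihood — it can also *score* each incoming frame and flag
samples the model was never trained on (out-of-distribution detection, OOD),
then adapt to them by fine-tuning. (With the default partial-deconvolution
conditioning the desk-scale pipeline spends most of its inference time in
that conditioning step; the configuration exercises the mechanics of the
method — exact likelihoods, hierarchical conditioning, OOD detection — not
the full-scale speed claims.)

## The model

Let $V_0$ be the full-resolution volume ($H \times W \times D$). The
orthonormal axial Haar transform maps a volume to an approximation at half
axial resolution and detail coefficients of the same size:
$A = (a+b)/\sqrt2$, $D = (a-b)/\sqrt2$ for consecutive depth planes
$(a, b)$. Applying it $n$ times gives a pyramid
$V_0 \to (V_1, D_1) \to \dots \to (V_n, D_n)$. Because the transform is an
isometry, it is exactly invertible and contributes nothing to a
log-likelihood.

The joint density is factorized over the pyramid:
$$\log p(V_0 \mid C) = \log p(V_n \mid C) + \sum_{i=1}^{n} \log p(D_i \mid \Omega_i(C)),$$
where $C$ is the set of conditions. Each detail term is modelled by a
conditional normalizing flow built from conditional affine transform (CAT)
blocks: a small convolutional subnet maps condition features to an
elementwise scale $s(c)$ and translation $t(c)$, and the block applies
$y = s(c) \odot x + t(c)$. Since $s, t$ do not depend on $x$, the Jacobian
is diagonal and $\log|\det J| = \sum \log s$ is exact. The scale is
parameterized as $s = \exp(\gamma \tanh(r/\gamma))$ with soft clamp
$\gamma = 2$, so every block is invertible by construction. Each level uses
6 CAT blocks with 14 hidden channels, with a fixed seeded channel
permutation before each block after the first. The final subnet layers are
zero-initialized, so an untrained flow is the identity.

The coarse term $p(V_n \mid C)$ is replaced by a deterministic
low-resolution network (LR-NN) that regresses $C \to V_n$. A deterministic
map defines no density, so the LR-NN never enters likelihood scores; OOD
uses the flow levels only.

### Conditions

Three conditioning pathways are concatenated (each axially reduced to the
level's scale through the Haar approximation):

1. **Cropped lens views.** The raw image is cut into one window per lens
   (centers detected from the central PSF plane) and stacked along
   channels.
2. **Structural prior.** The voxelwise mean of the training volumes. With
   an immobilized animal the anatomy is static and only activity changes,
   so the prior tells the model *where* signal can occur.
3. **Partial deconvolution** (package extension, `use_deconv = TRUE`). A
   partial RL reconstruction of the measurement (default 60 iterations, far
   short of convergence). This pathway exists because of a representation
   mismatch we measured during development: depth is encoded in the views
   only as parallax shifts of up to several pixels, which the local
   $3\times3$ receptive fields of the conditioning subnets cannot resolve —
   with views and prior alone the flows could not fit the detail
   coefficients even on their own training frames. A volume-space summary
   of the measurement (aligned with the voxel grid) removes the mismatch.
   Set `use_deconv = FALSE` for the views-plus-prior-only model.

When the deconvolution condition is present it also *recenters* the model:
each level's flow acts on the residual between the true detail coefficients
and the deconvolution's own level-$i$ detail coefficients (a fixed
conditional translation — structurally a frozen CAT block with unit scale,
so its log-determinant is zero and the likelihood stays exact), and the
LR-NN predicts a residual on the deconvolved coarse volume rather than on
the static prior. Both choices came out of the same measurement: the
deconvolution-derived coefficients are an excellent frame-specific estimate
(residual RMS roughly a quarter of the signal), but networks fed them
merely as input channels never learned to pass them through; making them
the additive center lets every learned component start from that estimate
and only model the correction. The static prior remains the residual base
when `use_deconv = FALSE`.

### Training

Each level is trained independently (the factorization makes the loss a
sum), which keeps memory bounded. The per-sample objective of level $i$
combines the exact negative log-likelihood of $D_i$ with a spatial term:
$$L_i = \tfrac12\lVert f_\Theta(D_i, \Omega_i(C))\rVert^2 - \log|\det J|
      + \alpha \lVert V_{i-1} - \tilde V_{i-1} \rVert^2 + \rho\lVert\Theta\rVert^2,$$
with $\alpha = 0.48$ and $\tilde V_{i-1}$ the *modal* reconstruction: the
inverse flow evaluated at latent zero, assembled with the true
next-coarser volume so that levels stay independent. Using the mode matches
the zero-temperature inference regime. Both terms are kept at the ratio the
summed objective implies. The parameter prior $\rho\lVert\Theta\rVert^2$
is implemented as decoupled weight decay in AdamW.

The learning rate follows a cosine schedule annealed to zero. This is
load-bearing, not cosmetic: at a constant rate the likelihood term
oscillates by a few nats, and its gradient noise (latents of order 1)
drowns the spatial term's much smaller gradients, leaving the modal
reconstruction stuck at its zero-details baseline. We observed exactly this
during development; annealing resolves it.

### Reconstruction and temperature

Inference runs the hierarchy backwards: $\tilde V_n = \mathrm{LRNN}(C)$;
then for each level, draw $z_i = T\varepsilon$, invert the flow into
details $\tilde D_i$, and up-sample with the inverse Haar transform.
$T = 0$ uses the latent mode, draws no random numbers, and is bitwise
deterministic. Since the training target is itself the output of a
maximum-likelihood deconvolution, the mode is the natural reconstruction
and $T = 0$ is the default.

Two final steps shape the output: negative values are clipped to zero, and
voxels outside the structural prior's support are zeroed
(`support = "prior"`). The second step is part of the immobilized-sample
model: neuron positions are fixed, the prior's support is exactly the set
of voxels that can ever carry signal, and the sparse ground truth is
identically zero elsewhere. It also matters for the masked error metric
(below): an estimator that leaks even tiny intensities into truly empty
voxels is penalized by factors of $10^5$ there, which is why the
unrestricted output (`support = "none"`) is provided but not the default.

## Out-of-distribution detection

For a novel frame, the volume (deconvolved from the measurement, or known
directly for synthetic data) is pushed *forward* through the pyramid and
each level's flow, giving an exact per-element negative log-likelihood per
level (normalized by element count and including the Gaussian constant, so
thresholds are comparable across levels and sizes). Calibration pools NLL
scores of in-distribution and OOD samples, lays 1000 candidate thresholds
linearly over their range, and picks the one maximizing the F1-score; AUC
is computed threshold-free from the ranking (it equals the Mann–Whitney
statistic over the score pairs). The monitored level defaults to the
finest-but-one scale, which separates best in practice. A sample whose NLL
exceeds the threshold strictly is flagged OOD; the two adaptation routes
are `finetune(strategy = "replace")` (train on the new pairs only) and
`strategy = "append"` (train on old and new pairs together, retaining the
original family).

Two behaviors of fine-tuning are worth knowing. First, resumed training
needs a gentler, longer schedule than pretraining: short anneals from a
fresh optimizer state disturb the converged likelihood calibration before
recovering it, so the default adaptation budget is 120 epochs at half the
pretraining peak rate. Second, how far adaptation can go depends on how far
the new family is from the training distribution: a new specimen of the
same kind (new source positions) adapts and, with `append`, retains the
original family almost exactly, whereas appending a radically different
family (dense bead fields) makes the joint optimum measurably worse on the
original family at this model size — adaptation across such gaps trades
capacity. The deconvolution-centered conditioning also makes the model
generalize across moderate family shifts without any fine-tuning, so
mild shifts may already score in-distribution.

## The synthetic testbed

The generator emulates the statistical structure of activity-extracted
recordings of immobilized larval zebrafish, at a desk scale chosen so the
whole pipeline (data, training, evaluation) runs in minutes on one CPU:
volumes $32 \times 32 \times 16$, a $3\times3$ lenslet array on a
$96\times96$ camera, crops of $32$, two flow levels, 10 training frames of
a 40-frame recording.

* **Scenes.** Neuron positions are uniform with a minimum separation of
  $2\sigma$ and fixed across frames (immobilization). Blobs are isotropic
  Gaussians with $\sigma = 1.1$ voxels, truncated at $3\sigma$ — compact
  support keeps the volumes sparse (under 5% of voxels non-zero) with
  exactly-zero background, as activity-extracted data have.
* **Activity.** Per-frame Bernoulli onsets (rate 0.3) convolved with a
  causal exponential kernel ($\tau = 3$ frames), computed exactly via the
  AR(1) recursion $a_t = o_t + e^{-1/\tau} a_{t-1}$. The process is
  simulated for 20 burn-in frames before frame 1 so the recording joins
  ongoing activity in steady state — without burn-in the first frames of
  every scene would be unrealistically silent and the training prior could
  miss neurons entirely.
* **Imaging.** The synthetic PSF places one Gaussian spot per lens and
  depth, displaced radially by 1 pixel per depth plane of parallax; images
  form by per-depth convolution, exactly the operator RL inverts. Noise is
  off by default (the ground-truth path in the emulated pipeline is itself
  denoised); a Poisson option exists for robustness experiments.
* **OOD families.** `beads`: isolated sub-voxel spots with Poisson counts
  spanning a dilution series; `non_sparse`: an in-distribution scene plus
  a smooth strictly-positive background (emulating autofluorescence of
  unprocessed data). Both rendered through the same optics.

What passing tests on this testbed do **not** show: performance on real
acquisitions (aberrated PSFs, sensor noise, motion, overlapping somata,
hundreds of neurons), scalability of training to $512^2\times96$ volumes,
or wall-clock speed-ups over RL at that scale. The testbed checks the
*mechanics* — exact likelihoods, invertibility, factorization, conditional
learning, likelihood-based OOD separation, adaptation — not the field
performance of the full-scale system.

## Numerical choices and degenerate inputs

* Convolution centering: the kernel center is the fixed pixel
  `dim %/% 2 + 1` (1-based), making the delta-voxel identity exact; the
  projector runs in a zero-padded Fourier domain and its adjoint is the
  exact matrix transpose (dot-product-tested to $10^{-8}$).
* RL guards both divisions with $\varepsilon = 10^{-12}$; all-zero PSFs and
  negative images are rejected; FFT round-off negatives are clipped each
  iteration.
* The Haar transform requires even depth (no implicit padding); an
  $n$-level pyramid requires depth divisible by $2^n$.
* Flow scales are bounded in $[e^{-2}, e^{2}]$ per block by the soft clamp;
  ties in peak detection and threshold selection break deterministically
  (row-major / lowest threshold).
* Network widths (conditioning hidden 22, feature channels 18, LR-NN hidden
  24) are sized so that appending a second family during fine-tuning does
  not contend for capacity; narrower nets reconstruct a single family
  equally well but lose ~1.5 dB on it after joint fine-tuning.
* Threshold calibration candidates are the 1000-point linear grid over the
  pooled score range *plus* the observed scores (ROC operating points):
  exact likelihoods give extremely OOD samples NLLs orders of magnitude
  above the in-distribution range, and a purely linear grid then has no
  candidate inside the separation gap.
* The deconvolution condition uses 60 RL iterations by default: enough that
  its detail coefficients are a usable recentering estimate, far short of
  RL convergence.
* Masked MAPE guards its denominator with $10^{-6}$ of the reference
  maximum; the mask is the union of non-zero voxels of reference and
  estimate.
* TIFF I/O scales stacks to $[0,1]$ (the writer's domain) and records the
  scale in a JSON sidecar; values restore exactly to 32-bit float
  precision.

## Known limitations

* The conditional flows are affine in the data given the conditions, so
  each level's conditional law is Gaussian given $\Omega_i(C)$; multimodal
  detail distributions would need nonlinear (e.g. spline) blocks behind the
  same interface.
* The channel permutations between CAT blocks are kept for structural
  fidelity but are expressively inert for condition-only affine blocks.
* Desk-scale training uses full-batch gradients over 10 frames; the
  training loop is deliberately simple (no mini-batching, no early
  stopping).
* The prior-support gate assumes immobilized samples; for freely moving
  samples use `support = "none"` and expect the masked error metric to
  degrade accordingly.
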