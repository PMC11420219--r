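---
title: "Self-supervised denoising and missing-wedge filling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-supervised denoising and missing-wedge filling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The reconstruction problem

A single-axis cryo-ET tilt series is a stack of 2D projections
$t = (t_{-K}, \dots, t_K)$ of an unknown 3D density $v^*$, recorded while
rotating the sample about the microscope tilt axis (here: the y axis, with
the beam along z).  By the Fourier slice theorem each projection measures a
noisy central slice of $F v^*$ at its tilt angle.  Two problems limit
filtered back-projection (FBP) reconstructions: the electron dose must be
kept low, so the projections are extremely noisy; and tilt angles beyond
roughly $\pm 60^\circ$ are unusable, so a wedge-shaped region of the Fourier
transform, $\{\,|k_z| > \tan(\alpha_{\max})\,|k_x|\,\}$, is never measured
at all.  `wedgefill` estimates a denoised tomogram with a filled-in wedge by
fitting a 3D U-Net on the measured data themselves — no ground truth and no
external training set.

## The three steps

**Step 1 — data preparation.**  The tilt series is split into two halves
with independent noise: either even/odd projections by acquisition order
(`split_even_odd()`), or, when per-tilt movie frames exist, even/odd frame
averages at every tilt (`split_frames()`).  Both halves are reconstructed
with per-y-slice 2D FBP (`fbp()`; ramp or Hamming-windowed ramp filter,
normalization $\pi/K$), and overlapping cubic sub-tomogram pairs
$(v^0_i, v^1_i)$ are extracted on a clamped sliding grid (`plan_grid()`,
`extract_pairs()`), optionally restricted to cubes containing enough sample
(`content_mask()`, `filter_positions()`).

**Step 2 — model fitting** (`fit()`).  Every epoch, each pair is rotated by
a fresh Haar-uniform rotation $R_{\varphi_i}$ and the model input gets an
*artificial* missing wedge:
$\tilde v^0_{i,\varphi_i} = F^{-1} M F R_{\varphi_i} v^0_i$,
with target $v^1_{i,\varphi_i} = R_{\varphi_i} v^1_i$.  The per-sample loss
is evaluated in the Fourier domain with a unitary transform,

$$\ell(\theta, i) = \bigl\| (M M_{\varphi_i} + 2\,M^C M_{\varphi_i})\,
F(f_\theta(\tilde v^0_{i,\varphi_i}) - v^1_{i,\varphi_i}) \bigr\|_2^2 ,$$

where $M_{\varphi_i}$ is the rotated wedge mask and $M^C = I - M$.  The two
mask products are orthogonal, so the loss splits into a Noise2Noise term on
frequencies measured in both volumes (denoising: the target's noise is
independent of the input's) and a quadruple-weighted Noisier2Noise term on
the artificially removed wedge (inpainting: the network must restore
content it can no longer see).  One Adam pass over all pairs (constant
learning rate $4\cdot10^{-4}$, mini-batches, shuffled) is followed by the
wedge update

$$v^0_i \leftarrow F^{-1}\!\left( M F v^0_i + M^C F f_\theta(v^0_i) \right),$$

which keeps the measured region bit-for-bit and replaces only the wedge
with the current prediction, so that as fitting proceeds the inputs
resemble volumes with a single (the artificial) wedge.  The targets are
never updated; their wedge is masked out of the loss.

**Step 3 — refinement** (`refine_tomogram()`).  The fitted network is
applied to the *original*, non-updated sub-tomograms of both half
reconstructions over a full covering grid, each half is reassembled by
uniform overlap averaging, and the two refined halves are averaged.

A Monte-Carlo harness in the test suite verifies the theoretical
motivation: for a linear one-parameter model, non-overlapping random wedge
pairs from a symmetric joint distribution, and independent noise, the
self-supervised loss differs from the supervised risk only by a constant —
loss differences over $\theta$ agree within Monte-Carlo error.

## The network

`build_unet()` constructs a volumetric U-Net with channel doubling and no
normalization layers (inputs are standardized per cube instead).  The
block layout is frozen:

* encoder: two 3×3×3 conv + ReLU per level, channels $c\,2^n$, 2× max-pool
  between levels;
* bottleneck: three convs, $c_{d-1} \to 2c_{d-1} \to 2c_{d-1} \to c_{d-1}$;
* decoder: nearest-neighbour 2× upsampling, skip concatenation, then three
  conv + ReLU per level (two at the finest level);
* output: a 1×1×1 convolution.

With the default 64 first-level channels and three downsampling levels
this layout has 27,321,473 trainable parameters (27.3 M).  The published
description of the reference architecture fixes the channel count, the
number of downsampling levels and the parameter count but not the
block-by-block layout; the layout above is this package's frozen
reconstruction, chosen so that all three published figures are reproduced,
and it is asserted in the test suite.  Dropout (probability configurable,
default 0) is available after every hidden ReLU but off by default: the
Noise2Noise-style target makes the usual overfitting regularization
unnecessary.  Weights are He-initialized; initialization, rotation
sampling and batch shuffling all derive from one seed.  Convolutions run
in single precision (the customary precision for this kind of model) via
BLAS GEMMs on a zero-padded voxel layout; everything else is double.

## The simulator

`make_phantom()` draws bright spheres, rods and spherical shells —
stand-ins for globular particles, filaments and membranes — on a zero
background, placed inside a central cylinder so that nothing leaves the
field of view at tilts up to ~70°.  `project()` implements the
parallel-beam forward model (line integrals after rotating about the tilt
axis, trilinear interpolation, CTF-free), and `add_noise()` adds
pixel-wise i.i.d. zero-mean Gaussian noise.  SNR is defined as the pooled
variance of the clean projection stack divided by the noise variance; the
noise level, not its definition, is standard in the field, and this
convention is recorded here because published descriptions often leave it
implicit.  `simulate_frames()` emits per-tilt frame stacks whose average
attains the requested SNR, for exercising the frame-based split.

What the simulator does *not* emulate: CTF effects and defocus, shot
(Poisson) noise, detector MTF, tilt-dependent dose and alignment errors.
Passing tests on these phantoms therefore demonstrates the correctness of
the algorithmic machinery — splitting, masking, loss, updates, metrics —
not performance on real micrographs, which additionally depends on CTF
correction and alignment done upstream.

## Numerical choices

* **Wedge geometry.**  Tilting about y sweeps slice normals in the
  $(k_x, k_z)$ plane, so the unmeasured set is
  $|k_z| > \tan(\alpha_{\max}) |k_x|$, independent of $k_y$; boundary
  points count as measured.  Masks are binary, fftshift-centered, DC
  always measured.
* **Rotated masks** are evaluated analytically at $R^{-1}k$ — a binary
  field is never interpolated.  On even-sized grids the Nyquist planes are
  their own point-inversion partners, where an analytically rotated wedge
  need not be symmetric; masks are therefore symmetrized (a frequency
  counts as measured only if its conjugate partner is), which keeps masked
  real volumes exactly real.  Without this the self-supervised loss
  acquires a small systematic bias, visible in the Monte-Carlo harness.
* **FBP.**  Per-row frequency filtering along x (`|f|` ramp, or
  Hamming-windowed ramp $|f|(0.54 + 0.46\cos(\pi f/f_{\mathrm{Nyq}}))$ —
  the windowed-ramp definition is this package's choice), uniform angular
  weights, normalization $\pi/K$ so a dense $180^\circ$ scheme
  approximately restores the input scale.
* **Normalization.**  Model inputs are standardized per cube with the
  half-0 statistics (both cubes of a pair share them, keeping the
  Noise2Noise target unbiased); refinement standardizes each cube with its
  own statistics and inverts the transform afterwards, so the output stays
  on the input intensity scale.  This stands in for the reference
  pipeline's normalization, whose details are not published.
* **Rotation fill.**  Cube rotations fill out-of-cube samples with the
  cube mean (≈ 0 after standardization); corner artifacts are accepted
  because the loss masks down-weight exactly the affected regions.
* **Reassembly** uses uniform averaging of covering cubes, the simplest
  rule satisfying the extract→reassemble identity.
* **FSC.**  Shells of width one frequency voxel indexed by rounded radius;
  no curve smoothing; 0.143 resolution by first crossing; shells without
  (wedge) voxels or without power are reported missing.  The zero fraction
  of a wedge mask equals the angular fraction $(180 - 2\alpha_{\max})/180$
  inside the Nyquist ball; over the full cube the corners inflate the
  measured region, which is why tests evaluate it ball-restricted.
* **Batching.**  Mini-batch size defaults to 8 (4 in the desk preset);
  gradients are averaged within a batch.  Epoch counts are fixed by
  configuration; optional validation loss on a held-out fraction of pairs
  supports manual early stopping.

## Desk-scale study conditions

The end-to-end check fits a 16-channel, two-level network on 18
non-overlapping 32³ sub-tomogram pairs from a 64×96×96 phantom projected
over ±60° at 2° increments with tilt-series SNR 1/4, for 30 epochs — sizes
chosen so the whole suite runs on a single CPU while still showing the
method's two effects: higher correlation with the ground truth than FBP,
and non-trivial correlation inside the missing wedge where FBP has
essentially none.  The full-scale defaults (64 channels, three levels, 96³
cubes, hundreds to thousands of epochs) follow the published experimental
setup and are what `unet_config()` and `fit_config()` produce out of the
box.

## Limitations

* CTF correction, tilt alignment and frame alignment are upstream
  responsibilities; the package consumes aligned, CTF-corrected series.
* Information inside the wedge is genuinely lost at acquisition; the
  filled-in content is a learned prior, and objects almost entirely
  supported in the wedge (thin horizontal membranes, elongated particles
  perpendicular to the beam) cannot be recovered reliably.  Comparing
  against a plain FBP reconstruction is the recommended sanity check.
* Sub-tomogram-sized context bounds what the network can restore: objects
  larger than a cube are filled in less faithfully.
* Training on a CPU limits practical problem sizes; the implementation is
  exact but not GPU-accelerated.
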