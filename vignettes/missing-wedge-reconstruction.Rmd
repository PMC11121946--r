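---
title: "Unsupervised missing-wedge reconstruction with coordinate networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised missing-wedge reconstruction with coordinate networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Cryo-electron tomography acquires a *tilt series*: `l` parallel-beam
projection images of a specimen taken at tilt angles spaced every
\(\alpha\) degrees across \([-\beta, +\beta]\) about a fixed axis (here
the volume y-axis; the standard preset is \(\alpha = 2\),
\(\beta = 60\), so `l = 61`). Because the stage cannot tilt to
\(\pm 90^\circ\), a wedge-shaped region of Fourier space is never
measured. Reconstructions computed by weighted back projection (WBP)
show the signature artifacts of this *missing wedge*: objects elongate
along z and fine features smear in the xz-plane.

`cryocn` implements an unsupervised route around this: instead of
inverting the projections directly, it fits a continuous *coordinate
network* \(G_\theta : \mathbb{R}^3 \to \mathbb{R}\) so that the
network's own reprojections match the measured tilt series,

\[
\theta^\* \;=\; \arg\min_\theta \; \lVert p - P\,G_\theta(C) \rVert
\;+\; \lambda\, R(G_\theta(C)),
\]

where \(C\) is the voxel-center coordinate grid, \(P\) the parallel-beam
projection operator, \(p\) the normalized tilt series, and \(R\) an
optional regularizer with strength \(\lambda\) (0 by default, with
total variation available). No pretraining and no ground truth are
involved; the only data the optimization sees are the projections
themselves. The network's smoothness bias fills the missing wedge with
plausible low-frequency structure, which is exactly where WBP fails.

## Forward model

`project()` implements \(P\) by sampling the volume at unit steps along
the rotated beam direction with bilinear interpolation (samples outside
the grid contribute zero). The conventions, fixed once and used
everywhere:

* volumes are `(x, y, z)` arrays, voxel centers at integer indices,
  volume center at `((x-1)/2, (y-1)/2, (z-1)/2)`;
* the tilt axis is y; the beam at angle \(\theta\) travels along
  \(n(\theta) = (\sin\theta, 0, \cos\theta)\), i.e. a positive angle
  tips the beam from +z toward +x;
* at \(0^\circ\) the projection is exactly the sum of the volume along
  z.

Because each ray stays inside one y-slice, the 3D operator factorizes
into a single 2D `(x, z) -> x` operator applied slice by slice. That
operator is materialized as a sparse matrix (`projector_matrix()`), so
the forward projection and its exact adjoint (`backproject()`) are
plain sparse-dense products and the adjoint identity
\(\langle Pv, q\rangle = \langle v, P^{\mathsf T} q\rangle\) holds to
machine precision. The same decoupling is what makes the subvolume
scheme below exact rather than an approximation: the projections of a
y-interval of the volume are precisely the corresponding y-interval of
the projection images.

Angles at exactly \(\pm 90^\circ\) are accepted (the parallel-beam ray
integral is perfectly well defined there — the ray simply runs along
x); only angles beyond \(90^\circ\) in magnitude are rejected.

## The network

`network_spec()` describes \(G_\theta\): positional encoding followed
by sinusoidal-activation fully connected layers. Both ingredients are
used together — the encoded vector, not the raw coordinate, feeds the
first sine layer. Choices and defaults:

* **Positional encoding** with `L` octaves maps a coordinate component
  \(c\) to \(\sin(2^k \pi c), \cos(2^k \pi c)\), \(k = 0 \dots L-1\)
  (octave spacing). The default `L = 6` reaches the voxel Nyquist
  frequency of the subvolume grids the planner produces at desk scale;
  fewer octaves underfit fine structure and more slow the optimization
  without improving it; coordinates are normalized per axis to \([-1, 1]\),
  which keeps the sinusoids well conditioned.
* **Sine layers** use the scale factor `omega0 = 30` inside every
  activation, with the matching uniform initialization: first layer
  \(U(\pm 1/\mathrm{fan_{in}})\), later layers
  \(U(\pm\sqrt{6/\mathrm{fan_{in}}}/\omega_0)\), biases
  \(U(\pm 1/\sqrt{\mathrm{fan_{in}}})\).
* **Capacity accounting**: `nominal_param_count()` is
  `hidden_layers * features^2` — the counting convention used by the
  subvolume planner (square hidden matrices only). The exact trainable
  count, including input/output layers and biases, is
  `trainable_param_count()`.

## Subvolume partitioning and learned initialization

One network per tomogram does not scale, so `plan_subvolumes()` splits
the y-axis into width-`j` subslices, choosing `j` as the largest power
of two that keeps at least `target_ratio` (default 1/8) nominal
parameters per subvolume voxel. For a 1024×1024×256 volume with the
default 4×256 architecture (262,144 nominal parameters) this yields
`j = 8`: 128 networks, each responsible for a 1024×8×256 subvolume.
The last interval may be narrower when `y` is not a multiple of `j`.

Subvolumes are fitted in y-order (`reconstruct_volume()`):

* the first from a fresh initialization, 2000 Adam iterations, learning
  rate decayed logarithmically from 1e-3 to 1e-4;
* every later one warm-started from its neighbour's fitted weights
  (*learned initialization*), 400 iterations from 1e-4 to 1e-5.

The warm start both cuts iterations five-fold and improves continuity
along y. Estimated subvolumes are stitched by hard concatenation — no
blending — which deliberately reproduces the y-seam behaviour of the
partitioned model; an overlap-blend variant was considered and
rejected because it would hide exactly the artifact the partition is
known to cause.

The loss norm is the mean squared reprojection error (matching the
PSNR-oriented evaluation); the optimizer is Adam with
\(\beta_1 = 0.9, \beta_2 = 0.99\). The faster-adapting second moment
matters: within the fixed 2000-iteration budget it reaches the
reconstruction quality that the textbook \(\beta_2 = 0.999\) only
attains after roughly three times as many iterations — with schedules
this short and aggressively decayed, the second-moment estimate must
track the loss landscape quickly or the step sizes never grow into the
signal. The training core runs in
float32 — the precision coordinate networks are conventionally trained
at — with gradients derived analytically through the sine layers and
the projector; `evaluate_network()` reproduces the same forward pass in
double precision. At subvolume scale the sparse projector is only
~70% sparse, so the core applies it as a dense float matrix (falling
back to sparse loops for operators above ~3·10⁸ entries).
`coords_per_step` defaults to `"all"` (full-grid gradients); stochastic
batches are drawn as whole y-slices so each batch's projection loss
stays exact.

## Synthetic data

`phantom_config()` + `simulate_phantom()` generate the ground-truth
volumes every test runs against:

* **spheres**: binarized hollow shells, diameters uniform in 16–64
  voxels at full scale, in a slab geometry (z smaller than x, y)
  mimicking objects in a thin ice layer. Shell thickness defaults to
  10% of the diameter (minimum 2 voxels); centers are
  rejection-sampled so shells lie fully inside; overlap is allowed.
* **shapes**: at least one instance each of full spheres, ellipsoids,
  pyramids, cubes, rectangular prisms, circular discs, and 4- and
  6-pointed 3D crosses; placement is non-overlapping by default so
  each object stays a distinct connected component.
* both are low-pass filtered (Gaussian Fourier window, half-amplitude
  at the cutoff, default 0.25 Nyquist — the filter strength is a
  package choice; only "smooth the surfaces" is prescribed) and then
  clamped to non-negative densities;
* the projected tilt series is normalized to \([0,1]\) by one global
  affine map (per-image normalization would destroy the inter-tilt
  consistency the loss depends on).

What the generator does *not* emulate: electron-optical image formation
(CTF, dose, detector noise), alignment errors, or crowded cellular
content. Passing tests therefore demonstrate correct geometry,
optimization and evaluation machinery on clean limited-angle data —
not robustness to real micrographs, which the method itself (not just
this implementation) leaves to future work.

## Evaluation

`evaluate_volumes()` compares a reconstruction against the reference
with PSNR, 3D SSIM (Gaussian window \(\sigma = 1.5\) truncated at
11³, \(K_1 = 0.01\), \(K_2 = 0.03\), dynamic range from the
reference), pixel-domain multiscale VIF (4 dyadic scales, dropping
scales that no longer fit the grid; computed in 3D — slice-wise 2D
averaging gives similar values and is used as a cross-check in the
tests), and Fourier shell correlation.

FSC is the per-shell normalized correlation of the two Fourier
transforms *without mean subtraction*, unit-width shells with a
coefficient assigned to shell `round(|k|)` (in Fourier voxels of the
largest dimension), from shell 1 to Nyquist.

The **directional FSC** restricts each shell to the *present* or
*missing* region of Fourier space. A grid point is present iff it lies
within `half_width` (default 0.5 Fourier voxels) of some central
section plane — `min over angles of |k . n(theta)| <= 0.5` — and
missing otherwise (`wedge_masks()`). Membership is a hard
nearest-plane test with no interpolation across the slab boundary; the
FSC profile is smooth enough that softer membership rules give
practically identical curves. The missing-region curve is the direct
readout of how much wedge information a method has restored: for WBP
it hovers near zero by construction, so any unsupervised gain shows up
immediately.

**Intensity calibration.** Reconstructions from a normalized tilt
series live on arbitrary linear scales (the network estimate in
normalized-projection units — roughly the ground truth divided by the
stack maximum — and WBP in ramp-filtered-sum units). Before voxel
metrics, `calibrate_volume()` fits the least-squares gain/offset
against the reference. The map is the same for every method and cannot
manufacture correlation, so comparisons are about structure, not
units. FSC is scale-invariant and unaffected.

`elongation_anisotropy()` quantifies the hallmark z-stretch: threshold
at half maximum, label 6-connected components, and average each
component's z-extent over x-extent (size-weighted). Isotropic objects
score ≈ 1; missing-wedge streaking pushes WBP well above it.

## Problem sizes and numerical choices

The test suite exercises the full protocol at desk scale, chosen so the
whole suite runs on one CPU core in well under half an hour:

* method validation uses a 64×64×32 hollow-sphere slab (5 shells,
  diameters 10–18) at \(\alpha = 2, \beta = 60\) with a reduced
  2-layer × 64-feature network — the planner gives two width-32
  subvolumes, so the 2000/400 learned-initialization protocol runs
  exactly as at full scale;
* operator correctness is proven against a dense-matrix oracle at 8³,
  where exhaustive comparison is exact;
* degenerate inputs are defined, not avoided: constant tilt series
  normalize to zero with a warning, empty FSC shells are omitted,
  a constant reference makes VIF error out (its scene statistics are
  undefined), non-finite training losses abort with the iteration
  number.

Known limitations: runtime grows linearly with volume size and
projection count (minutes at desk scale, GPU-class work at
1024³-class scale); hard stitching can leave faint y-seams; the
method's advantage concentrates at low and mid frequencies — at high
frequencies ramp-filtered WBP retains an edge (visible in VIF), which
is a property of the approach, not a defect of the implementation.
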