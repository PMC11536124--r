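---
title: "Methods: droplet-rotation tomography and SPHARM concavity morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: droplet-rotation tomography and SPHARM concavity morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droptomo)
```

# The measurement this package models

A single suspended cell encapsulated in a water-in-oil droplet rotates at
constant angular velocity when oil perfusion shears the droplet interface
and drives an internal recirculation vortex. A fixed epifluorescence camera
watching that cell therefore collects a time-lapse series of 2D projections
covering 360 degrees — exactly the geometry of parallel-beam computed
tomography with the image vertical as the rotation axis. `droptomo`
implements the full computational chain around that idea:

1. **dynamics** — closed-form calculators linking oil flow rate, rotation
   rate, acquisition timing and shear stress;
2. **phantoms** — synthetic nuclear shapes and their simulated rotation
   series, so every downstream stage is testable without data downloads;
3. **denoise** — pixel-wise zero-phase temporal filtering of the rotation
   footage;
4. **tomo** — row-wise ramp-filtered backprojection into an isotropic
   volume;
5. **morphometry** — spherical-harmonic (SPHARM) shape analysis with
   analytic Gaussian-curvature concavity spectra;
6. **tracking** — centroid drift statistics separating freely drifting
   cells from bounded, periodically orbiting ones.

# Rotation dynamics

The recirculation timescale of a tracer on the closed streamlines of a
Hadamard–Rybczynski vortex inside a sheared droplet is

$$\tau = \frac{2 R_0}{U_0}\left(1 + \frac{\eta_i}{\eta_o}\right),$$

with droplet radius $R_0$, bulk flow velocity $U_0$ and inner/outer
viscosities $\eta_i, \eta_o$. Taking the cell rotation period as $T \sim
\tau$ and the bulk velocity proportional to the applied flow rate,
$U_0 = \alpha Q$, gives a rotation rate linear in flow:

$$\omega(Q) = \frac{\alpha \pi Q}{R_0 (1 + \eta_i/\eta_o)}.$$

Defaults: $R_0 = 35\,\mu m$ (70 µm droplets), $\eta_i = 8.9\times10^{-4}$
Pa·s (water), $\eta_o = 1.24\times10^{-3}$ Pa·s (HFE-7500, manufacturer
value, overridable because no measured value is available), and $\alpha$
calibrated from the one printed operating point pairing flow and angular
velocity (1 µL/min → 0.44 rad/s). The linear model is an upper envelope:
measured rotation rises ~9-fold over a 10-fold flow increase, so
predictions far from the calibration point carry that documented bias.
Shear stress is estimated as $\tau_s \sim \eta\,\omega$ and reported in
mPa; at $T = 5{-}8$ s this is ~1 mPa, orders below flow-cytometry nozzle
stress, which is the gentle-handling argument the calculators quantify.

`plan_acquisition()` propagates one rotation rate into the mutually
consistent period, per-slice exposure ($1000\,T/N$ ms) and angular step
($360/N$ degrees); `rayleigh_resolution()` is the diffraction limit
$0.61\lambda/\mathrm{NA}$.

# Synthetic phantoms

All genus-zero phantom classes (spherical, bean, ellipsoid, multilobed,
grooved, amorphous) are defined by a single-valued radial function
$r(\theta,\phi)$ about the centroid, so they are star-shaped by
construction — the precondition of the radial SPHARM parameterization.
Band-limited roughness is added as a real spherical-harmonic series with
independent standard-normal coefficients on a degree interval, rescaled so
the field RMS equals `perturbation_amplitude_frac` × radius. The
`dispersed` class (disjoint blobs) is deliberately **not** star-shaped or
genus-zero: it exists to exercise the exclusion path that mirrors how
dispersed nuclei are left out of SPHARM analysis.

Voxelization uses a Gaussian-CDF radial edge profile of width 2 voxels
(~0.3 µm at the default 0.158 µm voxel, the scale of the optical band
limit) rather than a binary mask: this is the analytic form of smoothing a
binary interior with a small Gaussian shell and removes voxel staircase
artifacts, keeping projections band-limited. With this profile the
projections of a sphere agree across angles to relative L2 < 1e-3 under
bilinear rotation sampling, and the voxel sum matches the analytic volume
to ~1%.

Acquisition simulation assumes constant angular velocity (the rotation is
flow-driven), records ground-truth angles, and supports an isotropic
Gaussian PSF, sub-pixel translational drift along a fixed random direction,
and a CMOS noise model: Poisson shot noise (`photon_scale`, default 50
e⁻/intensity unit) + Gaussian read noise (default 2 e⁻) + offset, clipped
at zero. The sensor's noise is described only qualitatively in the source
material, so these defaults are package choices exposed in the model
object. A second, calibrated mode adds white Gaussian noise with variance
solved so the foreground SNR (μ/σ over the clean frame's Otsu mask) equals
a requested value; this mode does **not** clip at zero, because clipping
would bias the calibrated moments — the mode exists to produce stacks with
exactly known input SNR.

What the generator does *not* emulate: depth-dependent PSF, refraction at
the droplet interface, photobleaching, rotation-axis wobble, and intensity
texture inside the nucleus (interiors are uniform). Tests passing on these
phantoms therefore validate geometry, filtering and reconstruction
machinery — not robustness to those physical effects.

# Temporal denoising

Because the camera records each pixel continuously during rotation, each
pixel's time series can be low-pass filtered without touching spatial
structure. The filter is a third-order Butterworth, cutoff 5 Hz by default
(sampling = frame rate, 150 fps), applied forward–backward so the net
phase is zero and the effective magnitude response is $|H(f)|^2$ (hence
amplitude 1/2 exactly at $f_c$). Edge handling: odd-reflection padding of
length 3(order+1) with steady-state initialization of the recursion —
implemented by filtering the edge-level-subtracted series and restoring the
level, exact because the DC gain is 1. Output intensities are clipped at
zero (physical photon counts); this is the one deliberate break of strict
linearity and is applied after filtering.

The 5 Hz default is the balance point between noise-bandwidth reduction
(output SNR falls monotonically as the cutoff rises, for white input
noise) and preservation of true temporal signal; the package's
`snr_improvement_map()` reproduces that characterization on synthetic
stacks. SNR is always μ/σ of a slice: whole-frame by default (matching
per-slice profiling of full stacks), Otsu-foreground optionally for sparse
single-cell frames — which of the two the original measurements used is
not stated, so both are provided.

# Reconstruction

The rotation axis is the image vertical, so each image row is an
independent 2D parallel-beam problem; `reconstruct_volume()` runs
ramp-filtered backprojection per row and stacks the slices, giving an
isotropic volume with voxel size equal to the pixel size. Numerical
choices:

* **Ramp filter.** Frequency response = DFT of the closed-form band-limited
  Ram–Lak kernel ($h(0) = 1/4d^2$, odd lags $-1/(n\pi d)^2$), not a raw
  $|f|$ ramp — the standard discretization. Profiles are edge-replication
  padded to the next power of two ≥ 4× the detector length: edge padding
  makes the (DC-zeroed) filter annihilate constant profiles exactly, and
  the 4× length brings the wrapped kernel's response within ~0.1% of the
  ideal band-limited ramp at the lowest frequencies. An optional Hamming
  window apodizes high frequencies for noisy data.
* **Backprojection scale.** Accumulation is scaled by the angular step (in
  radians), halved for full-turn coverage where every direction is measured
  twice. This makes a disk of unit density reconstruct at unit amplitude
  (checked against the analytic chord-length sinogram within 5%).
* **Rotation centre.** Assumed at the detector midpoint; a sub-pixel offset
  can be supplied or estimated from 180°-opposed projection pairs by
  cross-correlation with parabolic refinement (`center_offset = "auto"`),
  because real droplet footage is rarely perfectly centred.
* **Angles.** Ground truth for synthetic stacks; for real footage
  `estimate_rotation_period()` finds the rotation period as the dominant
  peak (above lag fps/4, sub-frame parabolic refinement) of the unbiased
  mean pixel autocorrelation, and refuses footage without a significant
  peak. Requires more than one full rotation.

This is plain shadow-projection FBP: no PSF-aware deconvolution and no
focal-plane-scanning variant — both are explicit non-goals, and the
reconstruction inherits the corresponding artifacts far from the rotation
centre.

# SPHARM morphometry

Surfaces come from marching tetrahedra at an isovalue expressed as a
fraction of the volume maximum (0.32 is the convention for these
reconstructions). The tetrahedral decomposition has no ambiguous sign
cases, so extracted surfaces are always closed and consistently oriented,
and vertices are deduplicated per grid edge, making the Euler
characteristic exact: V − E + F = 2 identifies genus-zero surfaces, and
anything else (or multiple components) is flagged dispersed and excluded.

Parameterization is radial: each vertex maps to the spherical angles of
its centroid-to-vertex direction. This is exact, fast and
rotation-equivariant for star-shaped surfaces, which all reconstructable
phantom classes are; strongly non-star shapes are rejected with an
explicit error (ray-casting check). The trade against area-preserving
parameterizations is deliberate: no optimization, no flipped triangles, at
the cost of a restricted shape domain.

Each coordinate function $x,y,z$ on the sphere is least-squares fitted
against real orthonormal spherical harmonics up to $L_{max}$
($(L_{max}+1)^2$ coefficients per coordinate; a real basis keeps
magnitude spectra real — multiply the $m \neq 0$ coefficients by
$1/\sqrt{2}$ and attach phases to convert to the complex convention).
Normal equations are accumulated in chunks; meshes beyond 20 000 vertices
are deterministically strided down to that cap, which changes fitted
coefficients negligibly for the mesh densities produced here. Degree-0 of
this scheme is the area-weighted mean-radius sphere about the centroid.

Curvature is computed **analytically from the truncated series**: the
normalized associated Legendre recurrences give exact θ-derivatives (the
second derivative via the Legendre ODE), the first and second fundamental
forms follow on a Gauss–Legendre (in cos θ) × uniform-φ grid, and
$K = \kappa_1 \kappa_2$ comes from the shape operator with principal
curvatures signed w.r.t. the inward normal (sphere ⇒ $+1/R$). Mesh-based
discrete curvature is used only as a sign-agreement oracle in the tests —
at high degrees it is too noisy, which is why the analytic route was
chosen. Area weights use the metric determinant of the degree-L surface
itself, so "fraction of surface area that is concave" is measured on the
shape, not on the parameter sphere. "Concave" means strictly $K < 0$;
$K = 0$ counts as non-concave (the conservative tie-break). Degenerate
metric samples raise an error naming the (θ, φ) location.

Default quadrature is 128×256. The Gauss–Bonnet identity
$\int K\,dA = 4\pi$ is the global correctness check of curvature +
quadrature together; 128×256 holds it to <0.1% for $L \lesssim 16$ but
only ~1.6% at $L = 25$, so high-degree integral checks use 256×512.
Concave-area *fractions* are insensitive to this choice (<0.001 shift),
because the error sits in the integrand's extreme values, not in the sign
pattern.

## The high-degree concavity asymptote

For a sphere carrying isotropic band-limited Gaussian roughness, the
concave-area fraction rises from 0 (convex) toward a high-degree plateau.
A symmetry argument suggests 50% — locally, concave and convex detail
should be equally likely. The exact limit is different: where roughness
dominates, the sign of $K$ follows the sign of $\det$ of the perturbation
Hessian, and for any isotropic Gaussian field the Hessian moments are in
the fixed ratio $\mathrm{var}(h_{xx}) = 3\,\mathrm{cov}(h_{xx},h_{yy}) =
3\,\mathrm{var}(h_{xy})$, independent of the radial spectrum, which puts
$P(\det H < 0)$ near 0.58 rather than 0.50. The package's rough-sphere
fixture (degrees 15–25, RMS amplitude 5% of radius) measures ≈0.57 at
$l = 25$, consistent with that limit; fractions near 0.50 occur only at
much weaker roughness, where the sphere's own positive curvature still
suppresses part of the concave area. Reported asymptotes of ~50% on real
nuclear surfaces are therefore best read as approximate: real high-degree
detail is neither Gaussian nor isotropic, and measurement noise sits on
top. The acceptance script reports the measured value without adjustment.

## Orientation independence and features

`orientation_invariance_check()` re-runs parameterize → fit → concave
fraction under uniformly random rotations (quaternion sampling, fixed
seed). Because truncation at finite $L$ is not exactly equivariant for
non-band-limited shapes, the spread is small but nonzero — about 0.001
absolute for the grooved phantom at $L = 10$, far inside the 0.02
tolerance asserted in the tests. `shape_features()` distils the model into
sphericity, degree-1 elongation, mean concavity over degrees 3–8 (the band
where coarse morphologies differ most), and a lobe proxy counting
connected $K<0$ regions; the attached class label is a heuristic
convenience, not a validated classifier.

# Tracking

Segmentation is a threshold (Otsu by default) plus connected components;
centroids are intensity-weighted (sub-pixel); linking is nearest-neighbour
within 5 µm per frame, with ambiguous links splitting the track rather
than guessing, and only tracks persisting ≥80% of frames are kept.
Displacement is $r_c = \sqrt{x_c^2+y_c^2}$ measured from each track's
first position (the coordinate origin of the source data is unstated, so
a per-track origin that makes $r_c$ start at 0 is used). Drift statistics
report the mean ± SD displacement at a horizon plus two flags: monotone
growth (Spearman ρ > 0.9 of the mean curve — substrate-free drifting) and
periodicity (dominant autocorrelation peak of the linearly detrended
$r_c$ — droplet-rotated orbiting). Both the time-averaged $r_c$ and its
amplitude are reported for bounded motion, since either reading matches a
"bounded average displacement" summary.

# Problem sizes

The shipped tests and the acceptance script run at desk scale by choice:
96³ voxel grids (0.158 µm voxels) with 800-frame series for the
reconstruction checks, 64³/600-frame stacks for filtering studies, 128×256
surface grids with $L_{max} = 25$ for the roughness asymptote, and 50
random orientations for the invariance check. These sizes hold every
tolerance asserted in the tests; larger grids sharpen nothing but
runtime.

# Known limitations

* Parallel-beam shadow projections only; no pseudoprojection /
  focal-plane-scanning mode, no PSF-informed inversion.
* Radial parameterization fails (by design, with an error) on strongly
  non-star-shaped surfaces; no remeshing fallback is provided.
* The flow→rotation model is linear by construction and calibrated at one
  operating point.
* No registration or alignment across cells, and no statistical testing of
  population morphology distributions — the features are the output.
* The tracker has no appearance model and does not handle merges or
  divisions.
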