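# droptomo

Optical projection tomography and spherical-harmonic morphometry for
droplet-rotated single cells.

Suspended cells — lymphocytes, myeloid lines, anything that will not sit
still on a coverslip — drift too much for systematic 3D imaging unless they
are fixed or glued down. One way around this is to encapsulate each cell in
a water-in-oil droplet held in a trap array: perfusing oil shears the
droplet interface, drives an internal recirculation vortex, and spins the
cell at a constant angular velocity set by the flow rate. A fixed
epifluorescence camera then records a full 360° time-lapse of projections,
which is exactly parallel-beam computed tomography with the image vertical
as the rotation axis. `droptomo` implements the computational side of this
measurement end to end:

* **Rotation dynamics** — the recirculation timescale of the intradroplet
  Hadamard–Rybczynski vortex, τ = (2R₀/U₀)(1 + ηᵢ/ηₒ), the linear
  flow-to-rotation law ω(Q) = απQ / [R₀(1 + ηᵢ/ηₒ)], shear stress
  τₛ ~ ηω, acquisition planning (exposure per slice, degrees per slice)
  and the Rayleigh limit 0.61λ/NA.
* **Synthetic phantoms** — the six nuclear morphology classes (spherical,
  bean, ellipsoid, multilobed, grooved, amorphous, plus a non-genus-zero
  "dispersed" class), voxelized and pushed through a simulated acquisition
  with Poisson+Gaussian camera noise, optional PSF and translational drift.
* **Temporal denoising** — each pixel's time series filtered with a
  third-order zero-phase low-pass Butterworth (default cutoff 5 Hz at
  150 fps), plus the SNR (μ/σ) metric and output-SNR maps over input noise
  level and cutoff.
* **Reconstruction** — row-wise ramp-filtered backprojection (Ram–Lak,
  optional Hamming apodization, sub-pixel rotation-centre search, rotation
  period estimation from footage) into an isotropic volume.
* **SPHARM morphometry** — marching-tetrahedra isosurfaces, radial
  spherical parameterization, least-squares expansion of x, y, z in real
  orthonormal harmonics Y_lm up to L_max ((L_max+1)² coefficients per
  coordinate), degree-truncated surfaces, analytic Gaussian curvature
  K = κ₁κ₂ from the fundamental forms of the truncated series, and the
  concave-area-fraction spectrum (share of surface area with K < 0 at each
  degree) — an orientation-independent shape fingerprint.
* **Tracking** — threshold/centroid/nearest-neighbour tracking with drift
  statistics r_c = √(x_c² + y_c²), separating monotone substrate-free
  drift from bounded periodic orbiting.

## Worked example

```r
library(droptomo)

# plan an acquisition at the droplet-array operating point
p <- droplet_params()
omega <- angular_velocity(1, p)        # 1 uL/min oil flow
plan <- plan_acquisition(omega = omega, n_slices = 800)

# simulate a grooved nucleus, reconstruct it, quantify the groove
ph <- make_phantom(shape_spec("grooved", radius = 4, groove_depth_frac = 0.35),
                   grid_size = 96, voxel_size = 0.158)
stack <- simulate_rotation_series(ph, n_frames = 400, fps = 150)
vol <- reconstruct_volume(stack, normalize = "unit-max")
mesh <- extract_isosurface(vol, isovalue = 0.32)
model <- fit_spharm(mesh, lmax = 12)
spec <- concavity_spectrum(model, 12)
```

This prints:

```
flow 1 uL/min -> omega 0.44 rad/s (4.2 rpm), shear 0.39 mPa
800 slices/turn: 0.45 deg/slice, 17.8 ms exposure budget
reconstruction/ground-truth correlation: 0.999
surface_mesh: 37610 vertices, 75216 faces, 1 component(s), Euler chi = 2
    1     2     3     4     5     6     7     8     9    10    11    12
0.000 0.000 0.000 0.042 0.070 0.076 0.075 0.074 0.070 0.069 0.064 0.063
sphericity 0.98, low-frequency concavity 0.056
```

Reading it: at 1 µL/min the cell turns at 0.44 rad/s (4.2 rpm) under
~0.4 mPa of shear — gentle handling; an 800-slice turn gives 0.45° per
slice. The reconstructed volume correlates 0.999 with the ground-truth
phantom; its 0.32-isovalue surface is a single closed genus-zero mesh
(Euler characteristic 2). The concavity spectrum is zero through degree 3
(the shape is convex at coarse scale), then jumps once the harmonics are
fine enough to resolve the groove — the 4–8 band is where grooved and
spherical nuclei separate, and `shape_features()` condenses this into
sphericity ≈ 0.98 with low-frequency concavity 0.056 (a sphere gives
exactly 0).

A thin command-line wrapper over the same functions ships at
`inst/cli/droptomo` (subcommands `simulate`, `plan`, `dynamics`,
`denoise`, `snr-map`, `reconstruct`, `morpho`, `track`), e.g.

```sh
Rscript inst/cli/droptomo plan --rpm 21 --slices 1200
Rscript inst/cli/droptomo simulate --frames 800 --fps 150 --seed 7 --out stack.tif
Rscript inst/cli/droptomo reconstruct --in stack.tif --out vol.tif
Rscript inst/cli/droptomo morpho --in vol.tif --isovalue 0.32 --lmax 20 --out cellA/
```

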