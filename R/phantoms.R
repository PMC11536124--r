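#' Shape specification for synthetic nuclear phantoms
#'
#' Describes one of the six nuclear morphology classes observed in droplet-
#' rotated T cells and K562 cells -- spherical, bean-shaped, ellipsoid,
#' multilobed, grooved (enlarged nuclear groove) and amorphous -- plus a
#' `dispersed` class of disjoint blobs used only to exercise the
#' non-genus-zero exclusion path. All star-shaped classes are defined by a
#' single-valued radial function r(theta, phi) about the centroid, optionally
#' carrying band-limited isotropic radial roughness.
#'
#' @param category one of `"spherical"`, `"bean"`, `"ellipsoid"`,
#'   `"multilobed"`, `"grooved"`, `"amorphous"`, `"dispersed"`.
#' @param radius nominal radius, um (> 0).
#' @param axis_ratios length-3 positive ratios (ellipsoid semi-axes
#'   relative to `radius`).
#' @param lobe_count number of lobes for `multilobed`/`dispersed`.
#' @param lobe_separation_frac centre-to-centre lobe distance as a fraction
#'   of the lobe radius.
#' @param groove_depth_frac indentation depth as a fraction of the radius,
#'   in \[0, 1) so the surface stays star-shaped.
#' @param perturbation_degrees integer interval `c(lo, hi)` of spherical-
#'   harmonic degrees carrying radial roughness, or `NULL` for none.
#' @param perturbation_amplitude_frac RMS roughness amplitude as a fraction
#'   of `radius`.
#' @param seed RNG seed; identical (spec, seed) pairs give bit-identical
#'   phantoms.
#' @return an object of class `shape_spec`.
#' @export
#' @examples
#' shape_spec("grooved", radius = 4, groove_depth_frac = 0.35)
shape_spec <- function(category = c("spherical", "bean", "ellipsoid",
                                    "multilobed", "grooved", "amorphous",
                                    "dispersed"),
                       radius = 5, axis_ratios = c(1, 1, 1),
                       lobe_count = 2L, lobe_separation_frac = 1.2,
                       groove_depth_frac = 0.35,
                       perturbation_degrees = NULL,
                       perturbation_amplitude_frac = 0,
                       seed = 1L) {
  category <- match.arg(category)
  if (!is.finite(radius) || radius <= 0) .dt_stop("shape_spec: radius must be > 0")
  if (length(axis_ratios) != 3 || any(axis_ratios <= 0))
    .dt_stop("shape_spec: axis_ratios must be 3 positive numbers")
  if (groove_depth_frac < 0 || groove_depth_frac >= 1)
    .dt_stop("shape_spec: groove_depth_frac must be in [0, 1)")
  if (category == "amorphous" && is.null(perturbation_degrees))
    perturbation_degrees <- c(2L, 6L)
  if (category == "amorphous" && perturbation_amplitude_frac == 0)
    perturbation_amplitude_frac <- 0.12
  if (!is.null(perturbation_degrees)) {
    perturbation_degrees <- as.integer(round(perturbation_degrees))
    if (length(perturbation_degrees) != 2 || perturbation_degrees[1] < 1 ||
        perturbation_degrees[2] < perturbation_degrees[1])
      .dt_stop("shape_spec: perturbation_degrees must be c(lo, hi), 1 <= lo <= hi")
  }
  structure(list(category = category, radius = radius,
                 axis_ratios = axis_ratios, lobe_count = as.integer(lobe_count),
                 lobe_separation_frac = lobe_separation_frac,
                 groove_depth_frac = groove_depth_frac,
                 perturbation_degrees = perturbation_degrees,
                 perturbation_amplitude_frac = perturbation_amplitude_frac,
                 seed = as.integer(seed)),
            class = "shape_spec")
}

# Random real-harmonic coefficients for band-limited radial roughness,
# normalized so the field RMS over the sphere equals `amplitude`.
rough_coef <- function(degrees, amplitude, seed) {
  lo <- degrees[1]; hi <- degrees[2]
  nc <- spharm_n_coef(hi)
  coef <- numeric(nc)
  idx <- unlist(lapply(lo:hi, function(l) sph_col(l, -l:l)))
  coef[idx] <- with_seed(seed, rnorm(length(idx)))
  rms <- sqrt(sum(coef^2) / (4 * pi))
  coef * amplitude / rms
}

# union-of-spheres radial function (ray cast from the origin)
.lobe_radial <- function(theta, phi, centers, rho) {
  d <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  r <- numeric(length(theta))
  for (i in seq_len(nrow(centers))) {
    b <- d %*% centers[i, ]
    disc <- b^2 - sum(centers[i, ]^2) + rho^2
    ri <- ifelse(disc >= 0, b + sqrt(pmax(disc, 0)), 0)
    r <- pmax(r, ri)
  }
  r
}

.lobe_centers <- function(n, dist) {
  if (n <= 1) return(matrix(0, 1, 3))
  if (n == 2) return(rbind(c(-dist / 2, 0, 0), c(dist / 2, 0, 0)))
  ang <- 2 * pi * (seq_len(n) - 1) / n  # ring in the xz-plane
  cbind(cos(ang), 0, sin(ang)) * dist / (2 * sin(pi / n))
}

#' Radial surface function of a shape specification
#'
#' Returns the single-valued radius r(theta, phi) (um) about the centroid
#' that defines a star-shaped phantom surface. Not available for the
#' `dispersed` class, which is not star-shaped by construction.
#'
#' @param spec a [shape_spec()].
#' @return a vectorized `function(theta, phi)`.
#' @export
shape_radial_function <- function(spec) {
  stopifnot(inherits(spec, "shape_spec"))
  if (spec$category == "dispersed")
    .dt_stop("shape_radial_function: dispersed shapes are not star-shaped")
  R <- spec$radius
  base <- switch(spec$category,
    spherical = function(theta, phi) rep(R, length(theta)),
    ellipsoid = function(theta, phi) {
      a <- spec$axis_ratios
      dx <- sin(theta) * cos(phi); dy <- sin(theta) * sin(phi); dz <- cos(theta)
      R / sqrt((dx / a[1])^2 + (dy / a[2])^2 + (dz / a[3])^2)
    },
    bean = function(theta, phi) {
      # smooth indentation pressed along +x
      dx <- sin(theta) * cos(phi)
      psi <- acos(pmin(pmax(dx, -1), 1))
      R * (1 - spec$groove_depth_frac * exp(-(psi / 0.7)^2))
    },
    grooved = function(theta, phi) {
      # crescent channel: half-equatorial band of depth groove_depth_frac
      dphi <- atan2(sin(phi - pi / 2), cos(phi - pi / 2))
      R * (1 - spec$groove_depth_frac *
             exp(-((theta - pi / 2) / 0.35)^2) * exp(-(dphi / 1.1)^4))
    },
    multilobed = function(theta, phi) {
      rho <- R / (1 + 0.3 * (spec$lobe_count - 1))
      centers <- .lobe_centers(spec$lobe_count,
                               spec$lobe_separation_frac * rho)
      .lobe_radial(theta, phi, centers, rho)
    },
    amorphous = function(theta, phi) rep(R, length(theta))
  )
  if (is.null(spec$perturbation_degrees) ||
      spec$perturbation_amplitude_frac == 0)
    return(function(theta, phi) pmax(base(theta, phi), 0.05 * R))
  coef <- matrix(rough_coef(spec$perturbation_degrees,
                            spec$perturbation_amplitude_frac * R, spec$seed),
                 ncol = 1)
  hi <- spec$perturbation_degrees[2]
  function(theta, phi) {
    r <- base(theta, phi)
    n <- length(theta)
    delta <- numeric(n)
    for (ii in split(seq_len(n), ceiling(seq_len(n) / 8192))) {
      delta[ii] <- sph_basis(theta[ii], phi[ii], hi) %*% coef
    }
    pmax(r + delta, 0.05 * R)
  }
}

#' Exact triangle mesh of a star-shaped phantom surface
#'
#' Analytic (grid-sampled) counterpart of voxelizing [make_phantom()] and
#' extracting an isosurface; used for morphometry fixtures where voxel
#' discretization noise is unwanted.
#'
#' @param spec a [shape_spec()] (any category except `dispersed`).
#' @param n_theta,n_phi surface grid resolution.
#' @return a [surface_mesh()].
#' @export
make_shape_mesh <- function(spec, n_theta = 128L, n_phi = 256L) {
  radial_mesh(shape_radial_function(spec), n_theta, n_phi)
}

#' Voxelized phantom volume
#'
#' Rasterizes the shape onto an isotropic `grid_size`^3 voxel grid as a
#' unit-intensity interior with a Gaussian-CDF radial edge profile of width
#' `edge_sigma` voxels -- the analytic form of a binary interior smoothed by
#' a small Gaussian shell -- so projections are band-limited and free of
#' voxel staircase artifacts. The rotation axis centre is the grid midpoint
#' and the support must fit with a margin of at least 20 percent of the
#' phantom radius, preventing clipping under rotation.
#'
#' @param spec a [shape_spec()].
#' @param grid_size cubic grid side, voxels.
#' @param voxel_size isotropic voxel size, um; default 0.158 um (2 x 79 nm
#'   camera pixels).
#' @param edge_sigma edge profile width in voxels; the default 2 voxels
#'   (~0.3 um at the default pixel size) mirrors the diffraction-limited
#'   optical band limit.
#' @return an object of class `volume_phantom` with fields `intensity`
#'   (grid_size^3 array), `voxel_size`, `origin` (grid midpoint index) and
#'   `spec`.
#' @export
#' @examples
#' ph <- make_phantom(shape_spec("spherical", radius = 3), 64, 0.158)
#' sum(ph$intensity) * 0.158^3  # ~ (4/3) pi 3^3
make_phantom <- function(spec, grid_size = 128L, voxel_size = 0.158,
                         edge_sigma = 2) {
  stopifnot(inherits(spec, "shape_spec"))
  grid_size <- as.integer(grid_size)
  if (voxel_size <= 0) .dt_stop("make_phantom: voxel_size must be > 0")
  if (spec$category == "dispersed")
    return(.make_dispersed(spec, grid_size, voxel_size, edge_sigma))
  rfun <- shape_radial_function(spec)
  probe <- sph_quad_grid(32, 64)
  probe_r <- rfun(rep(probe$theta, 64), rep(probe$phi, each = 32))
  rmax <- max(probe_r)
  need <- ceiling(2 * rmax * 1.2 / voxel_size) + 2
  if (grid_size < need)
    .dt_stop("make_phantom: grid too small for support margin; need grid_size >= %d",
             need)
  ctr <- (grid_size + 1) / 2
  ax <- (seq_len(grid_size) - ctr) * voxel_size
  X <- array(ax, rep(grid_size, 3))
  Y <- aperm(X, c(2, 1, 3))
  Z <- aperm(X, c(3, 2, 1))
  rho <- sqrt(X^2 + Y^2 + Z^2)
  w <- edge_sigma * voxel_size
  intensity <- array(0, rep(grid_size, 3))
  intensity[rho <= min(probe_r) - 4 * w] <- 1
  shell <- which(rho > min(probe_r) - 4 * w & rho <= rmax + 4 * w)
  if (length(shell)) {
    th <- acos(pmin(pmax(Z[shell] / pmax(rho[shell], 1e-12), -1), 1))
    phv <- atan2(Y[shell], X[shell])
    intensity[shell] <- stats::pnorm((rfun(th, phv) - rho[shell]) / w)
  }
  structure(list(intensity = intensity, voxel_size = voxel_size,
                 origin = rep(ctr, 3), spec = spec),
            class = "volume_phantom")
}

.make_dispersed <- function(spec, grid_size, voxel_size, edge_sigma = 2) {
  R <- spec$radius
  n <- max(spec$lobe_count, 2L)
  rho <- 0.45 * R
  centers <- .lobe_centers(n, 3.2 * rho)   # disjoint blobs
  ctr <- (grid_size + 1) / 2
  need <- ceiling(2 * (max(sqrt(rowSums(centers^2))) + rho) * 1.2 / voxel_size) + 2
  if (grid_size < need)
    .dt_stop("make_phantom: grid too small for support margin; need grid_size >= %d",
             need)
  ax <- (seq_len(grid_size) - ctr) * voxel_size
  X <- array(ax, rep(grid_size, 3))
  Y <- aperm(X, c(2, 1, 3))
  Z <- aperm(X, c(3, 2, 1))
  w <- edge_sigma * voxel_size
  intensity <- array(0, rep(grid_size, 3))
  for (i in seq_len(n)) {
    d <- sqrt((X - centers[i, 1])^2 + (Y - centers[i, 2])^2 +
                (Z - centers[i, 3])^2)
    intensity <- pmax(intensity, stats::pnorm((rho - d) / w))
  }
  structure(list(intensity = intensity, voxel_size = voxel_size,
                 origin = rep(ctr, 3), spec = spec),
            class = "volume_phantom")
}

#' Parallel-beam projection of a phantom
#'
#' Rotates the volume by `angle` about the vertical in-plane (y) axis with
#' bilinear interpolation, integrates intensity along the optical (z) axis
#' and optionally blurs with an isotropic Gaussian point-spread function.
#' Pixel values are line integrals (intensity x um).
#'
#' @param phantom a [make_phantom()] volume.
#' @param angle rotation angle, degrees (counterclockwise viewed from +y).
#' @param psf_sigma Gaussian PSF sigma in um, or `NULL` for none.
#' @return an H x W projection image (rows = rotation axis).
#' @export
project <- function(phantom, angle, psf_sigma = NULL) {
  stopifnot(inherits(phantom, "volume_phantom") ||
              inherits(phantom, "recon_volume"))
  if (!is.finite(angle)) .dt_stop("project: angle must be finite")
  dm <- dim(phantom$intensity)
  img <- cpp_project(as.numeric(phantom$intensity), dm[1], dm[2], dm[3],
                     deg_to_rad(angle)) * phantom$voxel_size
  if (!is.null(psf_sigma)) {
    if (psf_sigma < 0) .dt_stop("project: psf_sigma must be >= 0")
    if (psf_sigma > 0)
      img <- as.matrix(EBImage::gblur(img, sigma = psf_sigma / phantom$voxel_size))
  }
  img
}

#' Camera noise model
#'
#' Poisson shot noise plus zero-mean Gaussian read noise plus a constant
#' offset, the parametric form of a CMOS sensor: counts =
#' Poisson(photon_scale x intensity) + N(0, read_noise_sd) + offset, clipped
#' at zero. Defaults: 50 electrons per intensity unit, 2 electrons read
#' noise. A degenerate model (both zero) leaves frames unchanged.
#'
#' @param photon_scale electrons per intensity unit (>= 0).
#' @param read_noise_sd read-noise standard deviation, electrons (>= 0).
#' @param offset constant sensor offset, counts.
#' @param seed RNG seed; the same seed gives a bit-identical realization.
#' @return an object of class `camera_noise_model`.
#' @export
camera_noise_model <- function(photon_scale = 50, read_noise_sd = 2,
                               offset = 0, seed = 1L) {
  if (photon_scale < 0 || read_noise_sd < 0)
    .dt_stop("camera_noise_model: photon_scale and read_noise_sd must be >= 0")
  structure(list(photon_scale = photon_scale, read_noise_sd = read_noise_sd,
                 offset = offset, seed = as.integer(seed)),
            class = "camera_noise_model")
}

#' Apply camera noise to a frame
#'
#' @param frame non-negative intensity image.
#' @param model a [camera_noise_model()].
#' @return noisy frame in count units (clipped at 0). With
#'   `photon_scale = 0` and `read_noise_sd = 0` the frame is returned
#'   unchanged (plus offset).
#' @export
add_camera_noise <- function(frame, model) {
  stopifnot(inherits(model, "camera_noise_model"))
  if (any(frame < 0)) .dt_stop("add_camera_noise: frame must be non-negative")
  with_seed(model$seed, .add_noise_once(frame, model))
}

.add_noise_once <- function(frame, model) {
  out <- if (model$photon_scale > 0)
    matrix(rpois(length(frame), model$photon_scale * frame), nrow(frame))
  else model$photon_scale * frame
  if (model$read_noise_sd > 0)
    out <- out + matrix(rnorm(length(frame), 0, model$read_noise_sd), nrow(frame))
  if (model$photon_scale == 0 && model$read_noise_sd == 0 && model$offset == 0)
    return(frame)
  pmax(out + model$offset, 0)
}

#' Add Gaussian noise calibrated to a target foreground SNR
#'
#' Convenience mode for controlled degradation studies: adds zero-mean white
#' Gaussian noise with the variance chosen so that the foreground SNR
#' (mean/SD, see [snr()]) of the output equals `target_snr`. The required
#' noise SD is sqrt((mu/target)^2 - sigma_clean^2) over the foreground mask
#' of the clean frame. No clipping is applied, since clipping would bias the
#' calibrated moments.
#'
#' @param frame clean intensity image.
#' @param target_snr requested output SNR (> 0, and below the clean SNR).
#' @param mask_rule `"otsu"` (foreground of the clean frame, the default --
#'   sparse single-cell frames have meaningless whole-frame statistics) or
#'   `"all"`.
#' @param seed RNG seed.
#' @return list with `frame` (noisy image), `noise_sd`, and `mask` (logical
#'   matrix used for the calibration).
#' @export
add_noise_snr <- function(frame, target_snr, mask_rule = c("otsu", "all"),
                          seed = 1L) {
  mask_rule <- match.arg(mask_rule)
  if (!is.finite(target_snr) || target_snr <= 0)
    .dt_stop("add_noise_snr: target_snr must be > 0")
  mask <- snr_mask(frame, mask_rule)
  mu <- mean(frame[mask]); s2 <- var(as.numeric(frame[mask]))
  need <- (mu / target_snr)^2 - s2
  if (need <= 0)
    .dt_stop("add_noise_snr: clean frame SNR (%.3f) already below target %.3f",
             mu / sqrt(s2), target_snr)
  nsd <- sqrt(need)
  noisy <- frame + with_seed(seed, matrix(rnorm(length(frame), 0, nsd),
                                          nrow(frame)))
  list(frame = noisy, noise_sd = nsd, mask = mask)
}

#' Time-lapse rotation series of a phantom
#'
#' Simulates one full 360-degree rotation at constant angular velocity:
#' frame k (k = 0..n_frames-1) is the projection at k * 360 / n_frames
#' degrees, optionally blurred, translated by an accumulating drift, and
#' corrupted by camera noise. Ground-truth angles are recorded.
#'
#' @param phantom a [make_phantom()] volume.
#' @param n_frames number of frames per turn (>= 2); 800-1200 matches one
#'   full-turn acquisition at 4-8 rpm and 150 fps.
#' @param fps frame rate, frames/s.
#' @param noise optional [camera_noise_model()].
#' @param drift_rate optional translational drift speed, um/s; the direction
#'   is a fixed random unit vector in the image plane drawn from
#'   `drift_seed`.
#' @param psf_sigma optional Gaussian PSF sigma, um.
#' @param drift_seed seed for the drift direction.
#' @return a [frame_stack()].
#' @export
simulate_rotation_series <- function(phantom, n_frames, fps = 150,
                                     noise = NULL, drift_rate = NULL,
                                     psf_sigma = NULL, drift_seed = 1L) {
  n_frames <- as.integer(n_frames)
  if (n_frames < 2) .dt_stop("simulate_rotation_series: n_frames must be >= 2")
  angles <- (seq_len(n_frames) - 1) * 360 / n_frames
  dm <- dim(phantom$intensity)
  frames <- array(0, c(dm[2], dm[1], n_frames))
  dir2 <- if (!is.null(drift_rate))
    with_seed(drift_seed, { a <- runif(1, 0, 2 * pi); c(cos(a), sin(a)) })
  for (k in seq_len(n_frames)) {
    img <- project(phantom, angles[k], psf_sigma)
    if (!is.null(drift_rate) && drift_rate > 0) {
      disp <- drift_rate * (k - 1) / fps / phantom$voxel_size
      img <- cpp_translate(img, disp * dir2[1], disp * dir2[2])
    }
    frames[, , k] <- img
  }
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "camera_noise_model"))
    frames <- with_seed(noise$seed, {
      for (k in seq_len(n_frames))
        frames[, , k] <- .add_noise_once(frames[, , k], noise)
      frames
    })
  }
  frame_stack(frames, fps = fps, pixel_size = phantom$voxel_size,
              angles = angles)
}

#' Time-ordered projection frame stack
#'
#' @param frames H x W x T non-negative array (rows = rotation axis).
#' @param fps frame rate, frames/s (> 0).
#' @param pixel_size pixel pitch, um (> 0).
#' @param angles per-frame rotation angle, degrees; strictly increasing,
#'   spanning at most 360 degrees. Ground truth for synthetic stacks,
#'   estimated (e.g. by [estimate_rotation_period()]) otherwise.
#' @param axis rotation-axis convention tag.
#' @return an object of class `frame_stack`.
#' @export
frame_stack <- function(frames, fps, pixel_size, angles,
                        axis = "vertical-ccw") {
  frames <- as.array(frames)
  if (length(dim(frames)) != 3 || dim(frames)[3] < 2)
    .dt_stop("frame_stack: frames must be H x W x T with T >= 2")
  if (any(frames < -1e-9) || any(!is.finite(frames)))
    .dt_stop("frame_stack: frames must be finite and non-negative")
  if (fps <= 0 || pixel_size <= 0)
    .dt_stop("frame_stack: fps and pixel_size must be > 0")
  if (length(angles) != dim(frames)[3] || any(diff(angles) <= 0) ||
      (max(angles) - min(angles)) > 360)
    .dt_stop("frame_stack: angles must be strictly increasing, span <= 360 deg")
  structure(list(frames = frames, fps = fps, pixel_size = pixel_size,
                 angles = angles, axis = axis), class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("frame_stack: %d frames of %dx%d px, %.0f fps, %.3f um/px, %.2f-%.2f deg\n",
              d[3], d[1], d[2], x$fps, x$pixel_size,
              min(x$angles), max(x$angles)))
  invisible(x)
}

#' Simulate a cell centroid drift track
#'
#' `directed` mode moves at constant speed along a fixed random direction
#' (the monotone drift of substrate-free T cells); `random_walk` takes
#' Gaussian steps with a per-second RMS displacement equal to `rate`.
#'
#' @param rate drift speed / RMS rate, um/s (>= 0).
#' @param duration track length, s (> 0).
#' @param fps sampling rate, frames/s.
#' @param mode `"directed"` or `"random_walk"`.
#' @param seed RNG seed.
#' @return data.frame with columns `t`, `x`, `y` (um).
#' @export
#' @examples
#' tr <- simulate_drift_track(0.2, 3.8, 50)
#' sqrt(sum(tr[nrow(tr), c("x", "y")]^2))  # ~0.76 um
simulate_drift_track <- function(rate, duration, fps = 50,
                                 mode = c("directed", "random_walk"),
                                 seed = 1L) {
  mode <- match.arg(mode)
  if (rate < 0 || duration <= 0 || fps <= 0)
    .dt_stop("simulate_drift_track: need rate >= 0, duration > 0, fps > 0")
  tt <- seq(0, duration, by = 1 / fps)
  n <- length(tt)
  if (mode == "directed") {
    a <- with_seed(seed, runif(1, 0, 2 * pi))
    data.frame(t = tt, x = rate * tt * cos(a), y = rate * tt * sin(a))
  } else {
    dt <- 1 / fps
    steps <- with_seed(seed, matrix(rnorm(2 * (n - 1), 0, rate * sqrt(dt / 2)),
                                    ncol = 2))
    data.frame(t = tt, x = c(0, cumsum(steps[, 1])),
               y = c(0, cumsum(steps[, 2])))
  }
}
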