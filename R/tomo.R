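# Row-wise ramp-filtered backprojection of single-axis rotation stacks.
#
# The rotation axis is the image vertical, so every image row is an
# independent 2D parallel-beam tomography problem; stacking the per-row
# reconstructions gives an isotropic volume with voxel size equal to the
# camera pixel size.

#' Sinogram for one image row
#'
#' @param values n_angles x n_detector matrix of projection values.
#' @param angles acquisition angles, degrees.
#' @param detector_spacing detector pitch, um (= pixel size).
#' @return a `sinogram` object.
#' @export
sinogram <- function(values, angles, detector_spacing = 1) {
  values <- as.matrix(values)
  if (nrow(values) != length(angles))
    .dt_stop("sinogram: need one angle per row of values")
  structure(list(values = values, angles = angles,
                 detector_spacing = detector_spacing), class = "sinogram")
}

#' Re-index a frame stack into per-row sinograms
#'
#' Sinogram r collects row r of every frame: values\[k, \] = frame k, row r.
#' Requires at least 180 degrees of angular coverage for a complete
#' tomographic problem.
#'
#' @param stack a [frame_stack()].
#' @return list of [sinogram()] objects, one per image row.
#' @export
frames_to_sinograms <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  span <- max(stack$angles) - min(stack$angles)
  if (span < 180)
    .dt_stop("frames_to_sinograms: angles span %.1f deg < 180 deg coverage", span)
  d <- dim(stack$frames)
  lapply(seq_len(d[1]), function(r)
    sinogram(t(stack$frames[r, , ]), stack$angles, stack$pixel_size))
}

#' Rebuild a frame stack from per-row sinograms
#'
#' Inverse of [frames_to_sinograms()] (exact round trip).
#'
#' @param sinos list of [sinogram()] objects.
#' @param fps frame rate for the rebuilt stack.
#' @return a [frame_stack()].
#' @export
sinograms_to_stack <- function(sinos, fps = 150) {
  H <- length(sinos)
  na <- nrow(sinos[[1]]$values); W <- ncol(sinos[[1]]$values)
  frames <- array(0, c(H, W, na))
  for (r in seq_len(H)) frames[r, , ] <- t(sinos[[r]]$values)
  frame_stack(frames, fps = fps, pixel_size = sinos[[1]]$detector_spacing,
              angles = sinos[[1]]$angles)
}

# frequency response of the discrete Ram-Lak kernel at padded length L,
# optionally Hamming-apodized; DC forced to zero.
.ramp_response <- function(ndet, spacing, window) {
  # 4x padding: the wrapped kernel's DFT then matches the ideal band-limited
  # |f| response to ~1e-3 at the lowest frequencies
  L <- 2^ceiling(log2(max(4 * ndet, 8)))
  h <- numeric(L)
  h[1] <- 1 / (4 * spacing^2)
  n <- seq_len(L / 2)
  odd <- n[n %% 2 == 1]
  h[1 + odd] <- -1 / (odd * pi * spacing)^2
  h[L + 1 - odd] <- -1 / (odd * pi * spacing)^2
  H <- Re(fft(h))
  H[1] <- 0
  if (window == "hamming") {
    f <- c(seq(0, L / 2), seq(L / 2 - 1, 1)) / (L / 2)   # |f|/f_Nyquist
    H <- H * (0.54 + 0.46 * cos(pi * f))
  }
  list(H = H, L = L)
}

#' Ramp (Ram-Lak) filtering of a detector profile
#'
#' Multiplies the profile's spectrum by the frequency response of the
#' band-limited Ram-Lak kernel (center sample 1/(4 d^2), odd offsets n
#' -1/(n pi d)^2, even offsets 0, d = detector spacing), edge-padded to the
#' next power of two >= 4 x length to suppress circular-convolution wrap.
#' The DC bin is zeroed, so constant profiles map to (numerically) zero.
#' Optional Hamming apodization tempers high-frequency noise.
#'
#' @param projection numeric detector profile (length >= 8), or a matrix
#'   with one profile per column.
#' @param spacing detector spacing d, um.
#' @param window `"ramp"` (pure Ram-Lak) or `"hamming"`.
#' @return filtered profile(s), same shape, units of projection / um^2
#'   scaled by the spacing (ready for backprojection).
#' @export
ramp_filter <- function(projection, spacing = 1, window = c("ramp", "hamming")) {
  window <- match.arg(window)
  vec <- is.null(dim(projection))
  P <- if (vec) matrix(projection, ncol = 1) else as.matrix(projection)
  ndet <- nrow(P)
  if (ndet < 8) .dt_stop("ramp_filter: profile length %d < 8", ndet)
  rr <- .ramp_response(ndet, spacing, window)
  # pad by edge replication (not zeros): a constant profile then lives on a
  # constant circle and is annihilated exactly by the DC-free ramp
  npad <- rr$L - ndet
  n_hi <- ceiling(npad / 2); n_lo <- npad - n_hi
  Pp <- rbind(P,
              matrix(rep(P[ndet, ], each = n_hi), n_hi, ncol(P)),
              matrix(rep(P[1, ], each = n_lo), n_lo, ncol(P)))
  Fq <- mvfft(Pp) * rr$H
  out <- Re(mvfft(Fq, inverse = TRUE))[seq_len(ndet), , drop = FALSE] / rr$L
  out <- out * spacing
  if (vec) out[, 1] else out
}

#' Filtered backprojection of one sinogram
#'
#' Ramp-filters every projection and smears it back along its acquisition
#' direction with linear interpolation, scaled by the angular step (and
#' halved for full-turn coverage, where every direction is measured twice).
#' The rotation centre is the detector midpoint plus `center_offset`
#' (sub-pixel, detector samples).
#'
#' @param sino a [sinogram()] (>= 8 angles).
#' @param window ramp window, see [ramp_filter()].
#' @param center_offset rotation-centre offset in detector samples, or
#'   `"auto"` to estimate it from 180-degree consistency.
#' @param filter set `FALSE` for plain (unfiltered) backprojection.
#' @return n_detector x n_detector reconstructed slice.
#' @export
backproject <- function(sino, window = "ramp", center_offset = 0,
                        filter = TRUE) {
  stopifnot(inherits(sino, "sinogram"))
  na <- nrow(sino$values)
  if (na < 8) .dt_stop("backproject: need >= 8 angles, got %d", na)
  if (identical(center_offset, "auto"))
    center_offset <- estimate_center_offset(sino)
  Q <- if (filter)
    t(ramp_filter(t(sino$values), sino$detector_spacing, window))
  else sino$values
  ang <- deg_to_rad(sino$angles)
  dtheta <- mean(diff(ang))
  span <- max(ang) - min(ang) + dtheta
  mult <- if (span > 1.5 * pi) 2 else 1
  cpp_backproject(Q, ang, center_offset) * dtheta / mult
}

#' Estimate the rotation-centre offset from 180-degree consistency
#'
#' A projection at angle theta + 180 is the mirror image of the one at
#' theta; any rotation-centre offset shifts the mirrored pair by twice the
#' offset. Cross-correlates the most nearly opposed pair of projections
#' with sub-sample (parabolic) peak refinement.
#'
#' @param sino a [sinogram()] spanning at least 180 degrees.
#' @return centre offset in detector samples.
#' @export
estimate_center_offset <- function(sino) {
  ang <- sino$angles
  j <- which.min(abs((ang - ang[1]) - 180))
  if (abs(ang[j] - ang[1] - 180) > 5)
    .dt_stop("estimate_center_offset: no projection near 180 deg apart")
  a <- sino$values[1, ]; b <- rev(sino$values[j, ])
  n <- length(a)
  L <- 2^ceiling(log2(2 * n))
  fa <- fft(c(a - mean(a), numeric(L - n)))
  fb <- fft(c(b - mean(b), numeric(L - n)))
  cc <- Re(fft(fa * Conj(fb), inverse = TRUE)) / L
  lags <- c(0:(L / 2 - 1), -(L / 2):-1)
  keep <- abs(lags) <= n / 4
  cck <- cc[keep]; lk <- lags[keep]
  i <- which.max(cck)
  shift <- lk[i]
  # parabolic sub-sample refinement
  im <- which(lags == shift - 1); ip <- which(lags == shift + 1)
  if (length(im) && length(ip)) {
    y1 <- cc[im]; y2 <- cck[i]; y3 <- cc[ip]
    den <- y1 - 2 * y2 + y3
    if (abs(den) > 1e-12) shift <- shift + 0.5 * (y1 - y3) / den
  }
  shift / 2
}

#' Reconstruct an isotropic volume from a rotation stack
#'
#' Treats every image row as an independent sinogram, applies ramp-filtered
#' backprojection, and stacks the resulting slices into an N^3 volume with
#' isotropic voxel spacing equal to the camera pixel size. Denoising
#' ([denoise_stack()]) is optional and upstream.
#'
#' @param stack a [frame_stack()] with square frames spanning >= 180 deg.
#' @param window ramp window; `"hamming"` is recommended for noisy stacks.
#' @param center_offset rotation-centre offset in pixels, or `"auto"`.
#' @param normalize `"raw"` or `"unit-max"` (divide by the volume maximum,
#'   the convention used for isosurface work).
#' @return a `recon_volume` with fields `intensity` (N^3 array, axes
#'   x, y = rotation axis, z), `voxel_size`, `normalization`.
#' @export
reconstruct_volume <- function(stack, window = "ramp", center_offset = 0,
                               normalize = c("raw", "unit-max")) {
  stopifnot(inherits(stack, "frame_stack"))
  normalize <- match.arg(normalize)
  d <- dim(stack$frames)
  if (d[1] != d[2])
    .dt_stop("reconstruct_volume: frames must be square (got %dx%d)", d[1], d[2])
  span <- max(stack$angles) - min(stack$angles)
  if (span < 180)
    .dt_stop("reconstruct_volume: angles span %.1f deg < 180 deg", span)
  W <- d[2]
  ang <- deg_to_rad(stack$angles)
  dtheta <- mean(diff(ang))
  mult <- if ((span * pi / 180 + dtheta) > 1.5 * pi) 2 else 1
  if (identical(center_offset, "auto")) {
    midrow <- sinogram(t(stack$frames[round(d[1] / 2), , ]), stack$angles,
                       stack$pixel_size)
    center_offset <- estimate_center_offset(midrow)
  }
  vol <- array(0, c(W, d[1], W))
  for (r in seq_len(d[1])) {
    Q <- t(ramp_filter(stack$frames[r, , ], stack$pixel_size, window))
    vol[, r, ] <- cpp_backproject(Q, ang, center_offset) * dtheta / mult
  }
  if (normalize == "unit-max" && max(vol) > 0) vol <- vol / max(vol)
  structure(list(intensity = vol, voxel_size = stack$pixel_size,
                 normalization = normalize), class = "recon_volume")
}

#' Estimate the rotation period from footage
#'
#' Cell rotation is periodic, so the mean temporal autocorrelation of the
#' pixel time series peaks at the rotation period. The peak is searched at
#' lags above fps/4 (a quarter second), refined to sub-frame precision by
#' parabolic interpolation, and must stand out by more than 3 baseline SDs,
#' otherwise a "period not found" error is raised (e.g. static footage).
#' Requires footage covering more than one full rotation.
#'
#' @param frames a [frame_stack()] or H x W x T array (T frames).
#' @param fps frame rate, frames/s (taken from the stack if given one).
#' @param max_pixels number of highest-variance pixel series to average.
#' @return list with `period` (s), `period_frames`, `angles` (per-frame
#'   degrees, 360 t / period), `prominence`.
#' @export
estimate_rotation_period <- function(frames, fps = NULL, max_pixels = 400L) {
  if (inherits(frames, "frame_stack")) {
    if (is.null(fps)) fps <- frames$fps
    frames <- frames$frames
  }
  if (is.null(fps)) .dt_stop("estimate_rotation_period: fps required")
  d <- dim(frames)
  Tn <- d[3]
  m <- matrix(frames, d[1] * d[2], Tn)
  vr <- apply(m, 1, var)
  use <- which(vr > 0)
  if (!length(use))
    .dt_stop("estimate_rotation_period: period not found (no time-varying pixels)")
  use <- use[order(vr[use], decreasing = TRUE)][seq_len(min(max_pixels, length(use)))]
  x <- m[use, , drop = FALSE]
  x <- x - rowMeans(x)
  L <- 2^ceiling(log2(2 * Tn))
  ac <- numeric(Tn)
  overlap <- Tn - (seq_len(Tn) - 1)      # unbiased normalization per lag
  for (i in seq_len(nrow(x))) {
    fx <- fft(c(x[i, ], numeric(L - Tn)))
    a <- Re(fft(fx * Conj(fx), inverse = TRUE))[seq_len(Tn)]
    ac <- ac + (a / overlap) / (a[1] / Tn)
  }
  ac <- ac / nrow(x)
  lo <- ceiling(fps / 4) + 1L
  hi <- floor(0.75 * Tn)                 # keep >= 25% overlap in the estimate
  if (lo >= hi)
    .dt_stop("estimate_rotation_period: footage too short for the lag search")
  seg <- ac[lo:hi]
  i <- which.max(seg)
  peak_lag <- lo + i - 1L
  prominence <- seg[i] - median(seg)
  if (!is.finite(prominence) || seg[i] < 0.25 ||
      prominence < 3 * stats::mad(seg))
    .dt_stop("estimate_rotation_period: period not found (peak prominence %.3g below 3 x baseline SD)",
             prominence)
  lag <- peak_lag
  if (peak_lag > lo && peak_lag < hi) {
    y1 <- ac[peak_lag - 1]; y2 <- ac[peak_lag]; y3 <- ac[peak_lag + 1]
    den <- y1 - 2 * y2 + y3
    if (abs(den) > 1e-15) lag <- peak_lag + 0.5 * (y1 - y3) / den
  }
  lag <- lag - 1            # ac[1] is lag 0
  period <- lag / fps
  tt <- (seq_len(Tn) - 1) / fps
  list(period = period, period_frames = lag,
       angles = 360 * tt / period, prominence = prominence)
}
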