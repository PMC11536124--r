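# Shared fixtures (built once per test run) and independent oracles.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

sphere_phantom_96 <- function()
  fixture("sphere96", function()
    make_phantom(shape_spec("spherical", radius = 5), 96, 0.158))

# one slow rotation (4 s at 150 fps) of a smooth bean: the pixel signal
# bandwidth stays well below the 5 Hz filter cutoff
bean_stack_slow <- function()
  fixture("bean_stack", function() {
    ph <- make_phantom(shape_spec("bean", radius = 4), 64, 0.25)
    simulate_rotation_series(ph, 600, fps = 150)
  })

grooved_mesh <- function()
  fixture("grooved_mesh", function()
    make_shape_mesh(shape_spec("grooved", radius = 4, groove_depth_frac = 0.35),
                    96, 192))

sphere_mesh_fix <- function()
  fixture("sphere_mesh", function()
    make_shape_mesh(shape_spec("spherical", radius = 4), 96, 192))

# --- independent textbook inverse-Radon oracle ---
# Frequency-domain |f| ramp (DC-free) applied on a long zero-padded grid,
# followed by a per-pixel backprojection loop; independent of the package's
# kernel-derived response, padding scheme and vectorized geometry.
naive_iradon <- function(sino, angles_deg, spacing = 1) {
  na <- nrow(sino); nd <- ncol(sino)
  L <- 8 * nd
  fr <- c(0:(L / 2), (L / 2 - 1):1) / (L * spacing)   # |f| cycles per um
  Q <- matrix(0, na, nd)
  for (a in seq_len(na)) {
    p <- c(sino[a, ], numeric(L - nd))
    q <- Re(fft(fft(p) * fr, inverse = TRUE)) / L
    Q[a, ] <- q[seq_len(nd)]
  }
  c0 <- (nd + 1) / 2
  out <- matrix(0, nd, nd)
  ang <- angles_deg * pi / 180
  dth <- mean(diff(ang))
  mult <- if ((max(ang) - min(ang) + dth) > 1.5 * pi) 2 else 1
  for (ix in seq_len(nd)) for (iz in seq_len(nd)) {
    tpos <- c0 + (ix - c0) * cos(ang) - (iz - c0) * sin(ang)
    t0 <- floor(tpos)
    ft <- tpos - t0
    ok <- t0 >= 1 & t0 <= nd - 1
    vals <- numeric(na)
    idx <- cbind(seq_len(na)[ok], t0[ok])
    vals[ok] <- (1 - ft[ok]) * Q[idx] + ft[ok] * Q[cbind(idx[, 1], idx[, 2] + 1)]
    out[ix, iz] <- sum(vals) * dth / mult
  }
  out
}

# --- angle-deficit discrete Gaussian curvature oracle ---
# K_v ~ (2 pi - sum of incident triangle angles at v) / (A_v / 3-ish);
# only the SIGN is used, so the area normalization is irrelevant.
angle_deficit_sign <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  deficit <- rep(2 * pi, nrow(v))
  corner_angle <- function(a, b, cc) {
    u <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
    w <- v[cc, , drop = FALSE] - v[a, , drop = FALSE]
    cosang <- rowSums(u * w) /
      pmax(sqrt(rowSums(u^2)) * sqrt(rowSums(w^2)), 1e-300)
    acos(pmin(pmax(cosang, -1), 1))
  }
  for (j in 1:3) {
    a <- f[, j]; b <- f[, (j %% 3) + 1]; cc <- f[, ((j + 1) %% 3) + 1]
    acc <- rowsum(corner_angle(a, b, cc), a)
    ids <- as.integer(rownames(acc))
    deficit[ids] <- deficit[ids] - acc[, 1]
  }
  sign(deficit)
}

# build a mesh whose interior vertices sit exactly on the curvature
# quadrature nodes of a fitted model (GL theta x uniform phi)
model_grid_mesh <- function(model, L, n_theta, n_phi) {
  g <- droptomo:::sph_quad_grid(n_theta, n_phi)
  cf <- droptomo:::.model_coef_L(model, L)
  sy <- droptomo:::sph_synth_grid(cf, L, g$theta, g$phi)
  pol <- droptomo:::sph_synth_grid(cf, L, c(1e-5, pi - 1e-5), 0)
  np <- n_theta * n_phi
  verts <- cbind(as.vector(sy$f[, , 1]), as.vector(sy$f[, , 2]),
                 as.vector(sy$f[, , 3]))
  verts <- rbind(verts, pol$f[1, 1, ], pol$f[2, 1, ])
  vid <- function(i, j) (j - 1L) * n_theta + i
  jj <- seq_len(n_phi); jn <- c(jj[-1], 1L)
  quads <- NULL
  for (i in seq_len(n_theta - 1L)) {
    a <- vid(i, jj); b <- vid(i + 1L, jj); cc <- vid(i, jn); d <- vid(i + 1L, jn)
    quads <- rbind(quads, cbind(a, b, cc), cbind(cc, b, d))
  }
  capN <- cbind(rep(np + 1L, n_phi), vid(1L, jj), vid(1L, jn))
  capS <- cbind(rep(np + 2L, n_phi), vid(n_theta, jn), vid(n_theta, jj))
  surface_mesh(verts, rbind(quads, capN, capS))
}
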