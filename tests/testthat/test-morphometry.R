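test_that("isosurface extraction recovers the sphere with Euler characteristic 2", {
  ph <- make_phantom(shape_spec("spherical", radius = 4), 80, 0.158)
  mesh <- extract_isosurface(ph, 0.32)
  r <- sqrt(rowSums(sweep(mesh$vertices, 2, mesh$centroid)^2))
  expect_lt(abs(mean(r) - 4), ph$voxel_size)        # within one voxel
  expect_equal(attr(mesh, "euler"), 2)
  expect_true(attr(mesh, "genus_zero"))
  # high isovalue shrinks to a small blob near the maximum
  small <- extract_isosurface(ph, 0.99)
  expect_lt(mean(sqrt(rowSums(sweep(small$vertices, 2,
                                    small$centroid)^2))), 4)
  expect_error(extract_isosurface(ph, 1.2), "isovalue")
})

test_that("disjoint lobes trigger the largest-component rule and dispersed flag", {
  ph <- make_phantom(shape_spec("dispersed", radius = 4, lobe_count = 2),
                     104, 0.158)
  mesh <- extract_isosurface(ph, 0.32)
  expect_equal(attr(mesh, "component_count"), 2)
  expect_true(attr(mesh, "dispersed"))
  expect_equal(mesh_topology(mesh)$component_count, 1)  # largest kept
})

test_that("radial parameterization is exact for spheres and ellipsoids", {
  sm <- sphere_mesh_fix()
  par <- spherical_parameterize(sm)
  expect_lt(diff(range(par$r)), 1e-6 * 4)
  # ellipsoid radius maxima along the long axis
  em <- make_shape_mesh(shape_spec("ellipsoid", radius = 3,
                                   axis_ratios = c(2, 1, 1)), 64, 128)
  pe <- spherical_parameterize(em)
  long_axis <- abs(sin(pe$theta) * cos(pe$phi)) > 0.99
  expect_gt(min(pe$r[long_axis]), max(pe$r[!long_axis & abs(sin(pe$theta) *
                                                             cos(pe$phi)) < 0.5]))
  # analytic radial function agreement
  a <- c(2, 1, 1)
  dx <- sin(pe$theta) * cos(pe$phi); dy <- sin(pe$theta) * sin(pe$phi)
  dz <- cos(pe$theta)
  r_true <- 3 / sqrt((dx / a[1])^2 + (dy / a[2])^2 + (dz / a[3])^2)
  expect_equal(pe$r, r_true, tolerance = 1e-6)
  # non-star meshes are refused
  two <- make_phantom(shape_spec("dispersed", radius = 3, lobe_count = 2),
                      88, 0.2)
  dm <- extract_isosurface(two, 0.32)   # largest lobe only: off-centroid ok
  mm <- dm; mm$vertices <- rbind(dm$vertices, dm$vertices + 10)
  mm$faces <- rbind(dm$faces, dm$faces + nrow(dm$vertices))
  mm <- surface_mesh(mm$vertices, mm$faces)
  expect_error(spherical_parameterize(mm), "unsupported")
})

test_that("SPHARM fit is exact at low degree and nests monotonically", {
  sm <- sphere_mesh_fix()
  fit <- fit_spharm(sm, 10)
  expect_lt(fit$residual_rms, 1e-3 * 4)
  # a centered sphere lives entirely in degrees {0, 1}
  hi <- fit$coefficients[(spharm_n_coef(1) + 1):spharm_n_coef(10), ]
  expect_lt(max(abs(hi)), 1e-6 * max(abs(fit$coefficients)))
  expect_equal(spharm_n_coef(1), 4)
  expect_equal(nrow(fit$coefficients), 121)
  # grooved phantom carries far more degree 3-8 energy than the sphere fit
  fg <- fit_spharm(grooved_mesh(), 10)
  idx <- unlist(lapply(3:8, function(l) droptomo:::sph_col(l, -l:l)))
  expect_gt(sum(fg$coefficients[idx, ]^2), 10 * sum(fit$coefficients[idx, ]^2))
  # least-squares nesting: vertex reconstruction RMS non-increasing in L
  gm <- grooved_mesh()
  par <- spherical_parameterize(gm, check_star = FALSE)
  rms <- vapply(c(2, 4, 6, 8, 10), function(L) {
    B <- droptomo:::sph_basis(par$theta, par$phi, L)
    pred <- B %*% fg$coefficients[seq_len(spharm_n_coef(L)), ]
    sqrt(mean((pred - gm$vertices)^2))
  }, numeric(1))
  expect_true(all(diff(rms) <= 1e-9))
  expect_error(fit_spharm(sm, 120), "underdetermined")
})

test_that("truncated-surface evaluation converges to the input mesh", {
  fg <- fit_spharm(grooved_mesh(), 12)
  m0 <- evaluate_surface(fg, 0)
  r0 <- sqrt(rowSums(sweep(m0$vertices, 2, fg$centroid)^2))
  expect_lt(diff(range(r0)), 1e-9)                   # L = 0 is a sphere
  mfull <- evaluate_surface(fg, 12, 96, 192)
  # Hausdorff-style bound: evaluated vertices stray no further from the true
  # surface than the worst pointwise fit residual (plus grid slack)
  gm <- grooved_mesh()
  par <- spherical_parameterize(gm, check_star = FALSE)
  pred <- droptomo:::sph_basis(par$theta, par$phi, 12) %*% fg$coefficients
  max_vertex_res <- max(sqrt(rowSums((pred - gm$vertices)^2)))
  rf <- shape_radial_function(shape_spec("grooved", radius = 4,
                                         groove_depth_frac = 0.35))
  # radii about the origin, the centre of the generating radial function
  v <- mfull$vertices
  r <- sqrt(rowSums(v^2))
  th <- acos(pmin(pmax(v[, 3] / r, -1), 1))
  phv <- atan2(v[, 2], v[, 1]) %% (2 * pi)
  expect_lt(max(abs(r - rf(th, phv))), 1.5 * max_vertex_res + 0.02)
})

test_that("analytic curvature: sphere closed form, Gauss-Bonnet, rotation and scale laws", {
  sm <- sphere_mesh_fix()
  fit <- fit_spharm(sm, 10)
  cf <- gaussian_curvature(fit, 10)
  expect_equal(max(abs(cf$K * 16 - 1)), 0, tolerance = 1e-5)
  expect_equal(cf$total_area, 4 * pi * 16, tolerance = 1e-3)
  expect_equal(sum(cf$K * cf$area_w), 4 * pi, tolerance = 0.005)
  # ellipsoid total curvature = 4 pi within 0.5%
  ef <- fit_spharm(make_shape_mesh(shape_spec("ellipsoid", radius = 3,
                                              axis_ratios = c(2, 1, 1)),
                                   96, 192), 12)
  ec <- gaussian_curvature(ef, 12)
  expect_equal(sum(ec$K * ec$area_w), 4 * pi, tolerance = 0.005)
  # rigid rotation of the model (coordinates transform linearly, so the
  # coefficient block rotates) leaves the K multiset unchanged
  gm <- grooved_mesh()
  f1 <- fit_spharm(gm, 10, check_star = FALSE)
  R <- random_rotations(1, seed = 3)[[1]]
  f2 <- f1
  f2$coefficients <- f1$coefficients %*% t(R)
  f2$centroid <- as.vector(R %*% f1$centroid)
  q1 <- quantile(gaussian_curvature(f1, 10)$K, c(0.05, 0.25, 0.5, 0.75, 0.95))
  q2 <- quantile(gaussian_curvature(f2, 10)$K, c(0.05, 0.25, 0.5, 0.75, 0.95))
  expect_equal(q1, q2, tolerance = 1e-6)
  # uniform scaling by s: K -> K / s^2, concave fraction unchanged
  gs <- gm; gs$vertices <- gs$vertices * 2.5
  gs <- surface_mesh(gs$vertices, gs$faces)
  f3 <- fit_spharm(gs, 10, check_star = FALSE)
  expect_equal(median(gaussian_curvature(f3, 10)$K),
               median(gaussian_curvature(f1, 10)$K) / 2.5^2,
               tolerance = 1e-3)
  expect_equal(concave_fraction(f3, 10), concave_fraction(f1, 10),
               tolerance = 1e-3)
})

test_that("concave fraction separates convex, grooved and lobed shapes", {
  sm_fit <- fit_spharm(sphere_mesh_fix(), 12)
  expect_equal(vapply(c(1, 4, 8, 12), function(l)
    concave_fraction(sm_fit, l), numeric(1)), rep(0, 4))
  ef <- fit_spharm(make_shape_mesh(shape_spec("ellipsoid", radius = 3,
                                              axis_ratios = c(1.5, 1, 0.8)),
                                   64, 128), 10)
  expect_equal(concave_fraction(ef, 10), 0, tolerance = 1e-6)
  # dumbbell neck is concave at moderate degree
  df <- fit_spharm(make_shape_mesh(shape_spec("multilobed", radius = 4,
                                              lobe_count = 2), 96, 192), 10)
  expect_gt(concave_fraction(df, 8), 0.05)
  # spectrum: entries within [0, 1]; grooved vs sphere gap peaks in 3..8
  spg <- concavity_spectrum(fit_spharm(grooved_mesh(), 12), 12)
  expect_true(all(spg$concave_fraction >= 0 & spg$concave_fraction <= 1))
  sps <- concavity_spectrum(sm_fit, 12)
  gap <- spg$concave_fraction - sps$concave_fraction
  expect_true(which.max(gap) %in% 3:8)
})

test_that("texture map is centered and signs follow the geometry", {
  tex_s <- texture_map(sphere_mesh_fix())
  expect_lt(max(abs(tex_s)), 1e-6)
  em <- make_shape_mesh(shape_spec("ellipsoid", radius = 3,
                                   axis_ratios = c(2, 1, 1)), 64, 128)
  tex <- texture_map(em)
  pe <- spherical_parameterize(em, check_star = FALSE)
  poles <- abs(sin(pe$theta) * cos(pe$phi)) > 0.95
  belt <- abs(sin(pe$theta) * cos(pe$phi)) < 0.3
  expect_true(all(tex[poles] > 0))
  expect_true(all(tex[belt] < 0))
  # area-weighted mean deviation is zero by construction
  va <- droptomo:::mesh_vertex_areas(em)
  expect_equal(sum(tex * va) / sum(va), 0, tolerance = 1e-9)
})

test_that("concavity measurements are orientation independent", {
  gm <- grooved_mesh()
  oi <- orientation_invariance_check(gm, n_rotations = 8, L = 10, seed = 5)
  expect_lt(oi$max_abs_dev, 0.02)
  # identity rotation reproduces the baseline exactly
  ident <- concave_fraction(fit_spharm(rotate_mesh(gm, diag(3)),
                                       10, check_star = FALSE), 10)
  expect_equal(ident, oi$baseline, tolerance = 1e-12)
})

test_that("angle-deficit discrete curvature agrees in sign with analytic K", {
  fg <- fit_spharm(grooved_mesh(), 10, check_star = FALSE)
  nt <- 96; np <- 192
  mesh <- model_grid_mesh(fg, 10, nt, np)
  sgn_disc <- angle_deficit_sign(mesh)[seq_len(nt * np)]
  K <- gaussian_curvature(fg, 10, nt, np)$K
  agree <- mean(sgn_disc == sign(as.vector(K)))
  expect_gte(agree, 0.98)
})

test_that("shape features distinguish the phantom classes", {
  fs <- shape_features(fit_spharm(sphere_mesh_fix(), 10))
  expect_equal(fs$sphericity, 1, tolerance = 0.01)
  expect_equal(fs$low_freq_concavity, 0, tolerance = 1e-6)
  expect_equal(fs$lobe_regions, 0)
  ef <- shape_features(fit_spharm(make_shape_mesh(
    shape_spec("ellipsoid", radius = 3, axis_ratios = c(2, 1, 1)),
    64, 128), 10))
  expect_gt(ef$elongation, fs$elongation)
  # truncating a rational radial function at low degrees leaves mild
  # Gibbs undulations, so "~0" here means small, not machine zero
  expect_lt(ef$low_freq_concavity, 0.05)
  df <- shape_features(fit_spharm(make_shape_mesh(
    shape_spec("multilobed", radius = 4, lobe_count = 2), 96, 192), 10))
  expect_gte(df$lobe_regions, 1)
})
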