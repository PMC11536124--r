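test_that("sphere phantom integrates to the analytic volume", {
  ph <- sphere_phantom_96()
  expect_equal(sum(ph$intensity) * 0.158^3, 4 / 3 * pi * 5^3, tolerance = 0.02)
  expect_true(all(ph$intensity >= 0) && all(is.finite(ph$intensity)))
})

test_that("ellipsoid with unit axis ratios is voxelwise a sphere", {
  s1 <- make_phantom(shape_spec("spherical", radius = 3), 56, 0.158)
  s2 <- make_phantom(shape_spec("ellipsoid", radius = 3,
                                axis_ratios = c(1, 1, 1)), 56, 0.158)
  expect_equal(s1$intensity, s2$intensity, tolerance = 1e-12)
})

test_that("two-lobe phantom has radial maxima along the lobe axis", {
  sp <- shape_spec("multilobed", radius = 4, lobe_count = 2,
                   lobe_separation_frac = 1.2)
  rfun <- shape_radial_function(sp)
  # brute-force scan of surface radius around a great circle through the axis
  ang <- seq(0, 2 * pi, length.out = 721)[-721]
  r <- rfun(rep(pi / 2, length(ang)), ang)
  locmax <- which(r > c(r[-1], r[1]) & r > c(r[length(r)], r[-length(r)]))
  expect_equal(length(locmax), 2)
  expect_equal(sort(ang[locmax]), c(0, pi), tolerance = 0.02)
})

test_that("phantom generation is deterministic and star-shaped", {
  sp <- shape_spec("amorphous", radius = 4, seed = 9)
  expect_identical(make_phantom(sp, 72, 0.2)$intensity,
                   make_phantom(sp, 72, 0.2)$intensity)
  # single-valued radius in 500 random directions for each class
  for (cat in c("spherical", "bean", "ellipsoid", "multilobed", "grooved",
                "amorphous")) {
    m <- make_shape_mesh(shape_spec(cat, radius = 4, seed = 2), 48, 96)
    expect_true(is_star_shaped(m, 500)$star_shaped, label = cat)
  }
})

test_that("undersized grids are rejected with the required minimum", {
  expect_error(make_phantom(shape_spec("spherical", radius = 5), 32, 0.158),
               "grid_size >= [0-9]+")
})

test_that("projection conserves mass and respects symmetry", {
  ph <- sphere_phantom_96()
  vox_line_integral <- sum(ph$intensity) * ph$voxel_size
  for (a in c(0, 17.3, 45, 121.7)) {
    expect_equal(sum(project(ph, a)), vox_line_integral, tolerance = 0.005)
  }
  # spherical phantom: projections identical at any angle
  p0 <- project(ph, 0); p1 <- project(ph, 38.2)
  expect_lt(sqrt(sum((p1 - p0)^2) / sum(p0^2)), 1e-3)
  # identity rotation equals plain axis summation
  direct <- t(apply(ph$intensity, c(1, 2), sum)) * ph$voxel_size
  expect_equal(project(ph, 0), direct, tolerance = 1e-12)
})

test_that("rotation series carries ground-truth angles and determinism", {
  ph <- make_phantom(shape_spec("spherical", radius = 3), 48, 0.25)
  st <- simulate_rotation_series(ph, 800, fps = 150)
  expect_equal(diff(st$angles)[1], 0.45)
  expect_equal(dim(st$frames)[3], 800)
  # noise-free spherical stack: frames identical up to the coarse-grid
  # interpolation tolerance
  expect_lt(sqrt(sum((st$frames[, , 5] - st$frames[, , 1])^2) /
                   sum(st$frames[, , 1]^2)), 2e-3)
  # same noise seed => bit-identical stacks
  nm <- camera_noise_model(photon_scale = 30, read_noise_sd = 2, seed = 11)
  s1 <- simulate_rotation_series(ph, 12, noise = nm)
  s2 <- simulate_rotation_series(ph, 12, noise = nm)
  expect_identical(s1$frames, s2$frames)
})

test_that("camera noise matches its moment model and degenerate limit", {
  fr <- matrix(10, 320, 320)   # flat bright region, 102400 px
  nm <- camera_noise_model(photon_scale = 50, read_noise_sd = 2, seed = 5)
  noisy <- add_camera_noise(fr, nm)
  expect_equal(var(as.vector(noisy - 50 * fr)), 50 * 10 + 2^2,
               tolerance = 0.05)
  nm0 <- camera_noise_model(0, 0, 0)
  expect_identical(add_camera_noise(fr, nm0), fr)
})

test_that("calibrated Gaussian noise hits the requested foreground SNR", {
  st <- bean_stack_slow()
  fr <- st$frames[, , 1]
  cal <- add_noise_snr(fr, 1.2580, seed = 3)
  got <- snr(cal$frame, mask = cal$mask)$snr
  expect_equal(got, 1.2580, tolerance = 0.02)
  expect_error(add_noise_snr(fr, -1), "> 0")
  expect_error(add_noise_snr(fr, 1e6), "below target")
})

test_that("drift tracks reproduce directed and diffusive motion", {
  tr <- simulate_drift_track(0.2, 3.8, 50, "directed", seed = 2)
  disp <- sqrt(tr$x[nrow(tr)]^2 + tr$y[nrow(tr)]^2)
  expect_equal(disp, 0.76, tolerance = 1e-9)
  expect_equal(round(disp, 1), 0.8)
  z <- simulate_drift_track(0, 2, 50)
  expect_true(all(z$x == 0 & z$y == 0))
  # ensemble MSD grows linearly with slope rate^2
  msd <- vapply(1:400, function(s) {
    t2 <- simulate_drift_track(0.3, 4, 25, "random_walk", seed = s)
    t2$x[101]^2 + t2$y[101]^2
  }, numeric(1))
  expect_equal(mean(msd), 0.3^2 * 4, tolerance = 0.1)
})
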